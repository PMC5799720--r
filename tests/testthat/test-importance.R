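test_that("extract_candidates matches a naive two-pass recount", {
  ct <- concept_table(data.frame(
    surface_form = c("amyloid", "pulmonary collapse"),
    concept_id = c("C1", "C2"),
    preferred_name = c("Amyloid", "Pulmonary Collapse"),
    semantic_types = "Disease or Syndrome", stringsAsFactors = FALSE))
  corpus <- c("amyloid deposits; amyloid again with pulmonary collapse",
              "no amyloid today", "nothing to see")
  cands <- extract_candidates(corpus, ct)
  expect_equal(cands$terms, c("amyloid", "pulmonary collapse"))
  f <- cands$features
  expect_equal(unname(f[, "tf"]), c(3, 1))
  expect_equal(unname(f[, "df"]), c(2, 1))
  expect_equal(unname(f[, "word_count"]), c(1, 2))
  expect_equal(unname(f[, "char_length"]), c(7, 18))
  expect_equal(unname(f[, "mean_word_length"]), c(7, 8.5))

  # single-note corpus with a repeated term: forced counts
  one <- extract_candidates("amyloid then amyloid", ct)
  expect_equal(unname(one$features[, c("tf", "df")]), c(2, 1))

  # empty concept table -> no candidates
  empty_ct <- concept_table(data.frame(
    surface_form = character(), concept_id = character(),
    preferred_name = character(), semantic_types = character(),
    stringsAsFactors = FALSE))
  expect_length(extract_candidates(corpus, empty_ct)$terms, 0L)

  # naive recount oracle over a random fixture corpus
  withr::local_seed(9)
  case <- random_recognizer_case(n_vocab = 8L, n_tokens = 60L)
  corpus2 <- replicate(5, random_recognizer_case(n_vocab = 8L,
                                                 n_tokens = 60L)$text)
  got <- extract_candidates(corpus2, case$concepts)
  tf2 <- list(); df2 <- list()
  for (note in corpus2) {
    surfs <- vapply(recognize(note, case$concepts),
                    function(m) normalize_surface(m$surface), character(1))
    for (s in surfs) tf2[[s]] <- (tf2[[s]] %||% 0) + 1
    for (s in unique(surfs)) df2[[s]] <- (df2[[s]] %||% 0) + 1
  }
  expect_equal(got$terms, sort(names(tf2)))
  expect_equal(unname(got$features[, "tf"]),
               unlist(tf2[got$terms], use.names = FALSE))
  expect_equal(unname(got$features[, "df"]),
               unlist(df2[got$terms], use.names = FALSE))
})

test_that("distant labeling conserves candidates and follows the vocab", {
  cands <- candidate_set(c("amyloid", "hypercholesterolemia", "fainting",
                           "lumbar"))
  vocab <- c("amyloid", "hypercholesterolemia")
  lab <- distant_label(cands, vocab)
  expect_length(lab$label, length(cands$terms))
  expect_equal(lab$label[match(vocab, lab$terms)], c(1L, 1L))
  expect_equal(lab$label[lab$terms == "fainting"], 0L)
  expect_equal(sum(lab$label), length(intersect(cands$terms, vocab)))
  expect_true(all(lab$origin == "DISTANT"))
  # empty vocab -> all negative
  expect_equal(sum(distant_label(cands, character())$label), 0L)
})

test_that("base training is deterministic, separable toys reach accuracy 1", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  cands <- candidate_set(sprintf("t%02d", 1:40))
  cands$features <- x
  colnames(cands$features) <- c("f1", "f2")
  lab <- labeled_set(cands, rep(c(0L, 1L), each = 20), "DISTANT")
  m1 <- train_base(lab)
  m2 <- train_base(lab)
  expect_equal(m1$base$weights, m2$base$weights)
  pred <- as.integer(score_candidates(m1, cands) > 0.5)
  expect_equal(pred, lab$label)
  expect_true(all(score_candidates(m1, cands) >= 0 &
                    score_candidates(m1, cands) <= 1))

  # single class -> training error
  lab0 <- labeled_set(cands, rep(0L, 40), "DISTANT")
  expect_error(train_base(lab0), "both classes")
})

test_that("adaptation requires a two-class manual set and stacks the base score", {
  w <- gen_importance_world(n = 400, rho = 1, seed = 4)
  ev <- eval_importance_world(w)
  expect_true(ev$auc_base > 0.8)
  # no-noise world: adaptation does no harm beyond small-sample wiggle
  expect_true(abs(ev$auc_adapted - ev$auc_base) < 0.05)
  expect_length(ev$model$adapted$weights, ncol(w$features) + 1L)

  cands <- candidate_set(c("a", "b"))
  expect_error(adapt(ev$model, labeled_set(cands, c(0L, 0L), "MANUAL")),
               "both classes")
  expect_error(adapt(ev$model, labeled_set(cands, c(0L, 1L), "DISTANT")),
               "no MANUAL items")
})

test_that("rank_terms sorts by probability with lexicographic ties", {
  w <- gen_importance_world(n = 300, rho = 1, seed = 6)
  model <- train_base(distant_label(w$candidates, w$consumer_vocab))
  ranked <- rank_terms(model, w$candidates)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$probability) <= 0))
  expect_true(all(ranked$probability >= 0 & ranked$probability <= 1))

  # identical features -> identical probabilities, lexicographic order
  twins <- candidate_set(c("zeta", "alpha"))
  twins$features[] <- 1
  r2 <- rank_terms(model, twins)
  expect_equal(r2$probability[1], r2$probability[2])
  expect_equal(r2$term, c("alpha", "zeta"))
})

test_that("top of the ranking is enriched in truly important terms", {
  w <- gen_importance_world(n = 1000, rho = 0.8, seed = 8)
  ev <- eval_importance_world(w)
  te <- w$test_idx
  ranked_scores <- score_candidates(ev$model, {
    cs <- candidate_set(w$candidates$terms[te])
    cs$features <- w$features[te, , drop = FALSE]
    cs
  })
  ord <- order(-ranked_scores)
  top <- ord[seq_len(ceiling(length(ord) / 10))]
  enrich <- mean(w$true_label[te][top]) / mean(w$true_label[te])
  expect_gte(enrich, 3)
})

test_that("manual-label files parse and reject bad labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tlabel", "Lumbar\t1", "continued pain\t0"), f)
  man <- load_manual_labels(f)
  expect_equal(man$term, c("lumbar", "continued pain"))
  expect_equal(man$label, c(1L, 0L))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tlabel", "x\t2"), f2)
  expect_error(load_manual_labels(f2), "label")
})
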