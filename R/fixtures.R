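#' @title Seeded synthetic-data generators
#' @description
#' Every input the test suite needs is generated by code: mini lexicons,
#' concept tables and jargon-planted notes with gold annotations
#' ([gen_bundle()]); a distant-supervision simulation world with a known
#' generative model and controllable vocabulary recall
#' ([gen_importance_world()]); and clustered embedding spaces with known
#' synonym sets ([gen_embedding_world()]). All generators are pure
#' functions of their parameters and seed. Note text is template-based so
#' gold spans are exact by construction, and gold stages are re-derived at
#' generation time by an independent slow evaluator.
#' @name laylink_fixtures
NULL

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# pronounceable nonsense words, deterministic under the active RNG
nonsense_words <- function(n, n_syllables = 3L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "th", "dr", "pl", "st")
  vow <- c("a", "e", "i", "o", "u", "ae", "io")
  out <- character(0)
  while (length(out) < n) {
    w <- paste(paste0(sample(cons, n_syllables, replace = TRUE),
                      sample(vow, n_syllables, replace = TRUE)),
               collapse = "")
    if (!(w %in% out)) out <- c(out, w)
  }
  out
}

# ---- linked-note bundle ----------------------------------------------------

# term archetypes cycled by gen_bundle; each fixes policy and expected stage
BUNDLE_ARCHETYPES <- c("stage1_full", "stage2_full", "stage3_full",
                       "stage4_full", "miss_full", "stage1_shallow",
                       "stage3_shallow_miss", "skip", "acronym_full",
                       "drugclass_full")

#' Generate a linked-note fixture bundle
#'
#' Builds a lexicon, concept table, semantic config and modifier list, then
#' plants recognizable terms into template notes and records gold
#' annotations (span, stage, partial flag). The terms cycle through
#' archetypes so every lookup stage and every gating policy (FULL, SHALLOW,
#' SKIP) is exercised, including terms that must produce no annotation.
#' A handful of real worked examples (bacteremia, Hecoria, AC,
#' community acquired pneumonia, normal sinus rhythm) are always included
#' so the documented micro-behaviors are runnable verbatim.
#'
#' @param n_terms number of synthetic planted terms (>= 1; at least one per
#'   archetype is generated regardless).
#' @param n_notes number of notes.
#' @param jargon_density fraction of sentences per note that carry a
#'   planted term, in (0, 1].
#' @param seed integer seed.
#' @return a `laylink_bundle`: list with `lexicon`, `concepts`, `config`,
#'   `modifiers`, `terms` (the plan), `notes` (each `text` + `gold`
#'   data.frame with `start`, `end`, `stage`, `partial`), `seed`.
#' @export
gen_bundle <- function(n_terms = 30L, n_notes = 20L, jargon_density = 0.4,
                       seed = 1L) {
  stopifnot(n_terms >= 1L, n_notes >= 1L)
  if (jargon_density <= 0 || jargon_density > 1) {
    stop("parameter error: jargon_density must be in (0, 1]", call. = FALSE)
  }
  with_seed(seed, gen_bundle_impl(n_terms, n_notes, jargon_density, seed))
}

gen_bundle_impl <- function(n_terms, n_notes, jargon_density, seed) {
  n_arch <- max(n_terms, length(BUNDLE_ARCHETYPES))
  arch <- rep_len(BUNDLE_ARCHETYPES, n_arch)
  pool <- nonsense_words(4L * n_arch + 40L)
  take <- local({
    i <- 0L
    function(n = 1L) {
      w <- pool[(i + 1L):(i + n)]
      i <<- i + n
      w
    }
  })

  pri <- "Disease or Syndrome"
  neutral <- "Research Activity"      # neither prioritized nor deprioritized
  dep <- "Temporal Concept"

  lex_rows <- list()
  dc <- c("calcineurin inhibitors" = "A drug used to reduce immune response.")
  concept_rows <- list()
  plan <- list()

  add_lex <- function(key, class, defs, dck = "") {
    for (i in seq_along(defs)) {
      lex_rows[[length(lex_rows) + 1L]] <<- data.frame(
        term_key = key, entry_class = class, sense_rank = as.character(i),
        definition_text = defs[i], source_tag = "fixture",
        drug_class_key = dck, stringsAsFactors = FALSE)
    }
    if (!length(defs)) {
      lex_rows[[length(lex_rows) + 1L]] <<- data.frame(
        term_key = key, entry_class = class, sense_rank = "",
        definition_text = "", source_tag = "", drug_class_key = dck,
        stringsAsFactors = FALSE)
    }
  }
  add_concept <- function(surface, id, preferred, types) {
    concept_rows[[length(concept_rows) + 1L]] <<- data.frame(
      surface_form = surface, concept_id = id, preferred_name = preferred,
      semantic_types = paste(types, collapse = "|"),
      stringsAsFactors = FALSE)
  }
  add_plan <- function(surface, stage, partial) {
    plan[[length(plan) + 1L]] <<- data.frame(
      surface = surface, stage = if (is.na(stage)) NA_integer_ else
        as.integer(stage), partial = partial, stringsAsFactors = FALSE)
  }

  for (idx in seq_len(n_arch)) {
    a <- arch[idx]
    id <- sprintf("C%04d", idx)
    def <- function(w) paste0("A lay explanation of ", w, ".")
    if (a == "stage1_full") {
      w <- take()
      add_lex(w, "TERM", def(w))
      add_concept(w, id, w, pri)
      add_plan(w, 1L, FALSE)
    } else if (a == "stage2_full") {
      surf <- take(); pref <- take()
      add_lex(pref, "TERM", def(pref))
      add_concept(surf, id, pref, pri)
      add_plan(surf, 2L, FALSE)
    } else if (a == "stage3_full") {
      base <- take()
      surf <- paste("chronic", base)
      add_lex(base, "TERM", def(base))
      add_concept(surf, id, surf, pri)
      add_plan(surf, 3L, FALSE)
    } else if (a == "stage4_full") {
      w1 <- take(); w2 <- take()
      surf <- paste(w1, w2)
      add_lex(w2, "TERM", def(w2))
      add_concept(surf, id, surf, pri)
      add_plan(surf, 4L, TRUE)
    } else if (a == "miss_full") {
      w <- take()
      add_concept(w, id, w, pri)
      add_plan(w, NA, FALSE)
    } else if (a == "stage1_shallow") {
      w <- take()
      add_lex(w, "TERM", def(w))
      add_concept(w, id, w, neutral)
      add_plan(w, 1L, FALSE)
    } else if (a == "stage3_shallow_miss") {
      base <- take()
      surf <- paste("severe", base)
      add_lex(base, "TERM", def(base))
      add_concept(surf, id, surf, neutral)
      add_plan(surf, NA, FALSE)
    } else if (a == "skip") {
      w <- take()
      add_lex(w, "TERM", def(w))
      add_concept(w, id, w, dep)
      add_plan(w, NA, FALSE)
    } else if (a == "acronym_full") {
      w <- take()
      acro <- toupper(substr(w, 1, 3))
      key <- tolower(acro)
      if (is.null_or_absent(lex_rows, key)) {
        add_lex(key, "ACRONYM",
                c(paste0("Short for ", w, "."), "A less common reading."))
        add_concept(key, id, w, pri)
        add_plan(key, 1L, FALSE)
      }
    } else if (a == "drugclass_full") {
      w <- take()
      add_lex(w, "DRUG", character(0), dck = "calcineurin inhibitors")
      add_concept(w, id, w, "Pharmacologic Substance")
      add_plan(w, 1L, FALSE)
    }
  }

  # real worked examples, always present
  add_lex("bacteremia", "TERM",
          "The presence of bacteria, a type of germ, in the blood")
  add_concept("bacteremia", "CREAL01", "Bacteremia", pri)
  add_plan("bacteremia", 1L, FALSE)

  add_lex("hecoria", "DRUG", character(0), dck = "calcineurin inhibitors")
  add_concept("hecoria", "CREAL02", "Hecoria", "Pharmacologic Substance")
  add_plan("hecoria", 1L, FALSE)

  add_lex("ac", "ACRONYM",
          c(paste("a short-hand name for a chemotherapy combination",
                  "used to treat breast cancer"),
            "assist control, a ventilator mode"))
  add_concept("ac", "CREAL03", "AC", pri)
  add_plan("ac", 1L, FALSE)

  add_lex("community", "TERM", "A group of people.")
  add_lex("pneumonia", "TERM",
          "An infection of the lungs, usually caused by viruses or bacteria.")
  add_concept("community acquired pneumonia", "CREAL04",
              "Community-Acquired Pneumonia", pri)
  add_plan("community acquired pneumonia", 4L, TRUE)

  add_lex("rhythm", "TERM", "The pattern of the heartbeat.")
  add_concept("normal sinus rhythm", "CREAL05", "Normal Sinus Rhythm", pri)
  add_plan("normal sinus rhythm", 4L, TRUE)

  lex_tab <- do.call(rbind, lex_rows)
  # collapse accidental duplicate term_keys from nonsense collisions
  lex_tab <- lex_tab[!duplicated(paste(lex_tab$term_key, lex_tab$sense_rank,
                                       sep = "\r")), , drop = FALSE]
  lex <- lexicon_from_table(lex_tab, dc)
  concepts <- concept_table(do.call(rbind, concept_rows))
  config <- default_semantic_config()
  modifiers <- default_modifiers()
  plan_tab <- do.call(rbind, plan)

  # independent slow re-derivation of every planned gold stage
  for (i in seq_len(nrow(plan_tab))) {
    got <- slow_stage_eval(plan_tab$surface[i], concepts, lex, config,
                           modifiers)
    want <- plan_tab$stage[i]
    ok <- (is.na(want) && is.na(got$stage)) ||
      (!is.na(want) && !is.na(got$stage) && got$stage == want &&
         got$partial == plan_tab$partial[i])
    if (!ok) {
      stop("bundle generator self-check failed for '", plan_tab$surface[i],
           "': planned stage ", want, ", derived ", got$stage, call. = FALSE)
    }
  }

  fillers <- c("the patient was resting comfortably and vital signs were",
               "stable on review of systems nothing remarkable was noted",
               "follow up was arranged with the primary care team",
               "the plan was discussed at length with the family")
  sentences_per_note <- 8L
  n_plant <- max(1L, round(sentences_per_note * jargon_density))
  templates <- c("The patient has %s today.",
                 "Assessment notes %s on examination.",
                 "History is notable for %s per the chart.")
  notes <- vector("list", n_notes)
  for (nn in seq_len(n_notes)) {
    planted <- sample(seq_len(nrow(plan_tab)), n_plant, replace = TRUE)
    slot <- sort(sample(seq_len(sentences_per_note), n_plant))
    text <- ""
    gold <- list()
    pi <- 1L
    for (s in seq_len(sentences_per_note)) {
      if (pi <= n_plant && s == slot[pi]) {
        row <- plan_tab[planted[pi], , drop = FALSE]
        tpl <- sample(templates, 1L)
        pre <- sub("%s.*$", "", tpl)
        sent <- sprintf(tpl, row$surface)
        start <- nchar(text) + nchar(pre)
        if (!is.na(row$stage)) {
          gold[[length(gold) + 1L]] <- data.frame(
            start = start, end = start + nchar(row$surface),
            stage = row$stage, partial = row$partial,
            stringsAsFactors = FALSE)
        }
        text <- paste0(text, sent, " ")
        pi <- pi + 1L
      } else {
        text <- paste0(text, sample(fillers, 1L), ". ")
      }
    }
    text <- trimws(text)
    gold_tab <- if (length(gold)) do.call(rbind, gold) else
      data.frame(start = integer(), end = integer(), stage = integer(),
                 partial = logical(), stringsAsFactors = FALSE)
    gold_tab <- gold_tab[order(gold_tab$start), , drop = FALSE]
    rownames(gold_tab) <- NULL
    notes[[nn]] <- list(text = text, gold = gold_tab)
  }

  structure(list(lexicon = lex, concepts = concepts, config = config,
                 modifiers = modifiers, terms = plan_tab, notes = notes,
                 seed = seed),
            class = "laylink_bundle")
}

is.null_or_absent <- function(lex_rows, key) {
  !any(vapply(lex_rows, function(r) any(r$term_key == key), logical(1)))
}

# build a lexicon object straight from a row table (shared with load_lexicon)
lexicon_from_table <- function(tab, drug_classes) {
  tf <- tempfile(fileext = ".tsv")
  dcf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tf, dcf)))
  write_tsv_strict(tab, tf, LEXICON_HEADER)
  write_tsv_strict(data.frame(class_key = names(drug_classes),
                              definition_text = unname(drug_classes),
                              stringsAsFactors = FALSE),
                   dcf, c("class_key", "definition_text"))
  load_lexicon(tf, dcf)
}

# deliberately naive stage evaluator, independent of lookup(): walks the
# lexicon entry structures directly, one stage at a time
slow_stage_eval <- function(surface, concepts, lex, config, modifiers) {
  rec <- concepts$records[[normalize_surface(surface)]]
  if (is.null(rec)) return(list(stage = NA_integer_, partial = FALSE))
  types <- rec$semantic_types
  policy <- if (length(intersect(types, config$prioritized)) > 0) "FULL"
  else if (all(types %in% config$deprioritized)) "SKIP"
  else "SHALLOW"
  if (policy == "SKIP") return(list(stage = NA_integer_, partial = FALSE))
  has_defs <- function(key) {
    e <- lex$entries[[key]]
    if (is.null(e)) return(FALSE)
    if (nrow(e$senses) > 0) return(TRUE)
    e$entry_class == "DRUG" && !is.na(e$drug_class_key)
  }
  s <- normalize_surface(surface)
  if (has_defs(s)) return(list(stage = 1L, partial = FALSE))
  if (has_defs(normalize_key(rec$preferred_name))) {
    return(list(stage = 2L, partial = FALSE))
  }
  if (policy == "SHALLOW") return(list(stage = NA_integer_, partial = FALSE))
  words <- term_words(s)
  kept <- words[!(words %in% modifiers)]
  trimmed <- paste(kept, collapse = " ")
  if (nzchar(trimmed) && trimmed != s && has_defs(trimmed)) {
    return(list(stage = 3L, partial = FALSE))
  }
  if (any(vapply(unique(kept), has_defs, logical(1)))) {
    return(list(stage = 4L, partial = TRUE))
  }
  list(stage = NA_integer_, partial = FALSE)
}

#' Write a bundle's resource files to a directory
#'
#' Emits `lexicon.tsv`, `drug_classes.tsv`, `concepts.tsv`, `config.txt`
#' (all three sections), `notes/note_NNN.txt` and `gold.tsv`.
#'
#' @param bundle a `laylink_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "notes"), recursive = TRUE, showWarnings = FALSE)
  write_lexicon(bundle$lexicon, file.path(dir, "lexicon.tsv"),
                file.path(dir, "drug_classes.tsv"))
  recs <- bundle$concepts$records
  ctab <- do.call(rbind, lapply(recs[sort(names(recs))], function(r) {
    data.frame(surface_form = r$surface_form, concept_id = r$concept_id,
               preferred_name = r$preferred_name,
               semantic_types = paste(r$semantic_types, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  write_tsv_strict(ctab, file.path(dir, "concepts.tsv"), CONCEPT_HEADER)
  writeLines(c("[prioritized]", bundle$config$prioritized,
               "[deprioritized]", bundle$config$deprioritized,
               "[modifiers]", unclass(bundle$modifiers)),
             file.path(dir, "config.txt"))
  gold <- list()
  for (i in seq_along(bundle$notes)) {
    writeLines(bundle$notes[[i]]$text,
               file.path(dir, "notes", sprintf("note_%03d.txt", i)))
    g <- bundle$notes[[i]]$gold
    if (nrow(g)) {
      gold[[length(gold) + 1L]] <- cbind(
        data.frame(note = sprintf("note_%03d.txt", i),
                   stringsAsFactors = FALSE), g)
    }
  }
  gtab <- if (length(gold)) do.call(rbind, gold) else
    data.frame(note = character(), start = integer(), end = integer(),
               stage = integer(), partial = logical(),
               stringsAsFactors = FALSE)
  gtab$partial <- ifelse(gtab$partial, "1", "0")
  gtab[] <- lapply(gtab, as.character)
  write_tsv_strict(gtab, file.path(dir, "gold.tsv"),
                   c("note", "start", "end", "stage", "partial"))
  invisible(dir)
}

# ---- importance world ------------------------------------------------------

#' Generate a distant-supervision simulation world
#'
#' Candidate terms get feature vectors drawn from the stated distributions
#' below; the true importance label is Bernoulli(logistic(eta)) where eta
#' is a standardized linear signal of separation `gamma = 3.5` centered so
#' the positive base rate is 0.25. The consumer vocabulary contains each
#' truly important term with probability `rho` (vocabulary recall), which
#' reproduces the distant-label failure mode: important terms missing from
#' the vocabulary get labeled negative. A small manual set carries true
#' labels for adaptation, drawn from the training half only.
#'
#' @param n number of candidate terms (>= 100).
#' @param rho vocabulary recall in (0, 1].
#' @param seed integer seed.
#' @param n_manual size of the manually labeled set.
#' @return a `laylink_world`: `candidates` (a `laylink_candidates`),
#'   `true_label`, `consumer_vocab`, `manual_idx`, `train_idx`, `test_idx`,
#'   `seed`, `params`.
#' @export
gen_importance_world <- function(n = 2000L, rho = 0.6, seed = 1L,
                                 n_manual = 150L) {
  stopifnot(n >= 100L, rho > 0, rho <= 1)
  with_seed(seed, {
    terms <- nonsense_words(n)
    p <- length(feature_names())
    wc <- sample(1:4, n, replace = TRUE, prob = c(0.55, 0.3, 0.1, 0.05))
    mwl <- pmax(2, stats::rnorm(n, 7, 2))
    feats <- cbind(
      tf = 1 + stats::rpois(n, 3),
      df = 1 + stats::rpois(n, 1),
      word_count = wc,
      char_length = round(wc * mwl + pmax(0, wc - 1)),
      mean_word_length = mwl,
      english_rank_bucket = sample(1:11, n, replace = TRUE,
                                   prob = c(rep(0.04, 10), 0.6)),
      matrix(stats::rbinom(n * 20L, 1L, 0.06), n, 20L))
    colnames(feats) <- feature_names()
    w_true <- c(0.10, 0.10, 0.20, 0.15, 0.60, 0.35,
                rep(1.2, 8), rep(0.3, 12))
    eta0 <- as.numeric(feats %*% w_true)
    gamma <- 3.5
    eta <- gamma * (eta0 - mean(eta0)) / stats::sd(eta0)
    b0 <- stats::uniroot(function(b) mean(stats::plogis(eta + b)) - 0.25,
                         c(-20, 20))$root
    true_label <- stats::rbinom(n, 1L, stats::plogis(eta + b0))
    if (mean(true_label) <= 0.1 || mean(true_label) >= 0.5) {
      stop("world generator: base rate out of (0.1, 0.5)", call. = FALSE)
    }
    # The vocabulary's misses are systematic, not uniform: the most
    # technical-looking important terms (strong medical suffixes, absent
    # from the general-English list) are the ones lay vocabularies lack.
    # Retention probability decreases with that technicality score and is
    # calibrated so mean retention over true positives equals rho.
    pos <- which(true_label == 1L)
    vocab <- if (rho >= 1) {
      terms[pos]
    } else {
      tech <- 2.0 * rowSums(feats[, 7:26, drop = FALSE]) +
        0.5 * (feats[, "english_rank_bucket"] == 11)
      tech <- (tech - mean(tech[pos])) / max(stats::sd(tech[pos]), 1e-9)
      a <- stats::uniroot(function(a) {
        mean(stats::plogis(a - 2 * tech[pos])) - rho
      }, c(-30, 30))$root
      keep <- stats::runif(length(pos)) <= stats::plogis(a - 2 * tech[pos])
      terms[pos[keep]]
    }
    idx <- sample(n)
    train_idx <- idx[seq_len(floor(n / 2))]
    test_idx <- idx[(floor(n / 2) + 1L):n]
    manual_idx <- sample(train_idx, min(n_manual, length(train_idx)))
    structure(list(candidates = candidate_set(terms, tf = feats[, "tf"],
                                              df = feats[, "df"]),
                   features = feats, true_label = true_label,
                   consumer_vocab = vocab, manual_idx = manual_idx,
                   train_idx = train_idx, test_idx = test_idx,
                   seed = seed,
                   params = list(n = n, rho = rho, gamma = gamma,
                                 base_rate = 0.25, n_manual = n_manual)),
              class = "laylink_world")
  })
}

# the world's features replace the corpus-derived ones so the generative
# signal is what the model sees
world_candidates <- function(world, idx) {
  cs <- candidate_set(world$candidates$terms[idx])
  cs$features <- world$features[idx, , drop = FALSE]
  cs
}

#' Run the distant-supervision pipeline on a simulation world
#'
#' Trains the base model on distant labels over the training half, adapts
#' it on the manual set, and evaluates both against the true labels of the
#' held-out half.
#'
#' @param world a `laylink_world`.
#' @return list with `auc_base`, `auc_adapted`, `model`.
#' @export
eval_importance_world <- function(world) {
  tr <- world_candidates(world, world$train_idx)
  te <- world_candidates(world, world$test_idx)
  distant <- labeled_set(
    tr, label = as.integer(tr$terms %in% world$consumer_vocab),
    origin = "DISTANT")
  model <- train_base(distant)
  manual <- labeled_set(world_candidates(world, world$manual_idx),
                        label = world$true_label[world$manual_idx],
                        origin = "MANUAL")
  adapted <- adapt(model, manual)
  y <- world$true_label[world$test_idx]
  list(auc_base = auc(score_candidates(model, te), y),
       auc_adapted = auc(score_candidates(adapted, te), y),
       model = adapted)
}

# ---- embedding world -------------------------------------------------------

#' Generate a clustered embedding world for synonym mining
#'
#' Each cluster has a unit-norm center; the target token's vector is a
#' noisy observation of the center (noise `2.5 * sigma` per coordinate,
#' a single noisy mention), while its true synonyms sit closer to the
#' center (noise `sigma`). Candidates for each target are its true
#' synonyms plus distractors sampled from other clusters. At `sigma = 0`
#' all vectors coincide with their centers and plain cosine ranking is
#' perfect; the PRF-improvement property is stated for `sigma <= 0.25`.
#'
#' @param n_clusters number of targets/clusters.
#' @param syn_per_cluster true synonyms per target.
#' @param d embedding dimension (>= 2).
#' @param sigma per-coordinate synonym noise (>= 0); default 0.12.
#' @param seed integer seed.
#' @param n_distractors distractor candidates per target.
#' @return a `laylink_embworld`: `vectors` (a `laylink_vectors` matrix),
#'   `targets`, `truth` (list per target), `candidates` (list per target),
#'   `sigma`, `seed`.
#' @export
gen_embedding_world <- function(n_clusters = 50L, syn_per_cluster = 6L,
                                d = 25L, sigma = 0.12, seed = 1L,
                                n_distractors = 20L) {
  stopifnot(d >= 2L, sigma >= 0, n_clusters >= 2L, syn_per_cluster >= 1L)
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * d), n_clusters, d)
    centers <- centers / sqrt(rowSums(centers^2))
    targets <- sprintf("target%03d", seq_len(n_clusters))
    rows <- list()
    truth <- stats::setNames(vector("list", n_clusters), targets)
    for (i in seq_len(n_clusters)) {
      rows[[targets[i]]] <- centers[i, ] +
        stats::rnorm(d, 0, 2.5 * sigma)
      syns <- sprintf("syn%03d_%02d", i, seq_len(syn_per_cluster))
      truth[[i]] <- syns
      for (j in seq_len(syn_per_cluster)) {
        rows[[syns[j]]] <- centers[i, ] + stats::rnorm(d, 0, sigma)
      }
    }
    vectors <- do.call(rbind, rows)
    class(vectors) <- c("laylink_vectors", "matrix", "array")
    candidates <- stats::setNames(vector("list", n_clusters), targets)
    for (i in seq_len(n_clusters)) {
      others <- unlist(truth[-i], use.names = FALSE)
      candidates[[i]] <- sample(c(truth[[i]],
                                  sample(others, min(n_distractors,
                                                     length(others)))))
    }
    structure(list(vectors = vectors, targets = targets, truth = truth,
                   candidates = candidates, sigma = sigma, seed = seed),
              class = "laylink_embworld")
  })
}

#' Evaluate plain-vs-PRF ranking on an embedding world
#'
#' @param world a `laylink_embworld`.
#' @param k,alpha,beta PRF parameters (see [prf_rerank()]).
#' @return list with `map_plain`, `map_prf`, and the per-target `ap` table.
#' @export
eval_embedding_world <- function(world, k = 5L, alpha = 1.0, beta = 0.75) {
  ap <- lapply(world$targets, function(tg) {
    ranked <- rank_by_similarity(tg, world$candidates[[tg]], world$vectors)
    rr <- prf_rerank(ranked, world$vectors, k = k, alpha = alpha,
                     beta = beta)
    data.frame(target = tg,
               ap_plain = average_precision(ranked$candidate,
                                            world$truth[[tg]]),
               ap_prf = average_precision(rr$candidate[order(rr$rank_prf)],
                                          world$truth[[tg]]),
               stringsAsFactors = FALSE)
  })
  ap <- do.call(rbind, ap)
  list(map_plain = mean(ap$ap_plain), map_prf = mean(ap$ap_prf), ap = ap)
}
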