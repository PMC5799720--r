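#' @title Term-importance ranking by adapted distant supervision
#' @description
#' Candidate EHR terms are labeled by distant supervision against a
#' consumer vocabulary (a term used by lay people is presumed important), a
#' regularized logistic model is trained on those noisy labels, and a small
#' manually labeled set adapts the model to the target notion of
#' importance via stacking (the base model's score becomes an extra feature
#' for a second logistic fit). Ranked probabilities then prioritize which
#' terms get definitions authored first.
#' @name laylink_importance
NULL

SUFFIX_TRIGRAMS <- c("mia", "tis", "sis", "oma", "thy", "omy", "ion", "gia",
                     "ive", "ous", "ate", "ine", "ary", "ery", "ogy", "eal",
                     "lar", "tic", "nal", "sia")

#' Names of the candidate-term feature vector, in order
#'
#' Six scalar features (corpus term frequency, document frequency, word
#' count, character length, mean word length, general-English rank bucket)
#' followed by an indicator block over a fixed set of word-final trigrams
#' common in medical vocabulary.
#'
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  c("tf", "df", "word_count", "char_length", "mean_word_length",
    "english_rank_bucket", paste0("suffix_", SUFFIX_TRIGRAMS))
}

load_english_ranks <- function() {
  path <- system.file("extdata", "english_common.txt", package = "laylink",
                      mustWork = TRUE)
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  words <- words[nzchar(words) & !startsWith(words, "#")]
  stats::setNames(seq_along(words), words)
}

# bucket 1..10 over the ranked list (100 words per bucket), 11 = absent
english_bucket <- function(words, ranks) {
  r <- ranks[words]
  b <- ceiling(ifelse(is.na(r), NA, r) / 100)
  b[is.na(b)] <- 11
  pmin(b, 10 + 1)
}

#' Extract candidate terms and their features from a note corpus
#'
#' Candidates are the distinct normalized surfaces the recognizer finds in
#' the corpus; features are computed deterministically from the corpus (no
#' randomness, no external services).
#'
#' @param corpus character vector of note texts.
#' @param concepts a `laylink_concepts` table.
#' @param max_ngram recognizer window width.
#' @return a `laylink_candidates` list with elements `terms` (character)
#'   and `features` (numeric matrix, rows aligned to `terms`, columns per
#'   [feature_names()]).
#' @export
extract_candidates <- function(corpus, concepts, max_ngram = 6L) {
  stopifnot(length(corpus) >= 1L)
  tf <- integer()
  df <- integer()
  for (note in corpus) {
    surfs <- vapply(recognize(note, concepts, max_ngram),
                    function(m) normalize_surface(m$surface), character(1))
    for (s in unique(surfs)) {
      tf[s] <- (if (is.na(tf[s])) 0L else tf[s]) + sum(surfs == s)
      df[s] <- (if (is.na(df[s])) 0L else df[s]) + 1L
    }
  }
  terms <- sort(names(tf))
  candidate_set(terms, tf = unname(tf[terms]), df = unname(df[terms]))
}

#' Build a candidate set from terms and corpus counts
#'
#' @param terms character vector of normalized terms.
#' @param tf,df term and document frequencies aligned to `terms`.
#' @return a `laylink_candidates` object.
#' @export
candidate_set <- function(terms, tf = rep(1, length(terms)),
                          df = rep(1, length(terms))) {
  stopifnot(all(tf >= 0), all(df >= 0), !anyDuplicated(terms))
  ranks <- load_english_ranks()
  feats <- t(vapply(seq_along(terms), function(i) {
    w <- term_words(terms[i])
    last <- w[length(w)]
    tri <- if (nchar(last) >= 3) substr(last, nchar(last) - 2, nchar(last))
           else ""
    c(tf[i], df[i], length(w), nchar(terms[i]), mean(nchar(w)),
      english_bucket(terms[i], ranks),
      as.numeric(SUFFIX_TRIGRAMS == tri))
  }, numeric(length(feature_names()))))
  if (!length(terms)) feats <- matrix(numeric(), 0, length(feature_names()))
  colnames(feats) <- feature_names()
  rownames(feats) <- terms
  structure(list(terms = terms, features = feats),
            class = "laylink_candidates")
}

#' @export
print.laylink_candidates <- function(x, ...) {
  cat("<laylink candidates>", length(x$terms), "term(s),",
      ncol(x$features), "features\n")
  invisible(x)
}

#' Distantly label candidates against a consumer vocabulary
#'
#' Every candidate whose normalized term occurs in the vocabulary is
#' labeled positive (important), all others negative; no candidate is
#' dropped. The labels are noisy by construction — important terms absent
#' from the vocabulary come out wrongly negative — which is exactly the
#' failure mode adaptation is meant to mitigate.
#'
#' @param candidates a `laylink_candidates` set.
#' @param consumer_vocab character vector of normalized vocabulary terms.
#' @return a `laylink_labeled` set: `candidates` plus `label` (1/0) and
#'   `origin` (`"DISTANT"`).
#' @export
distant_label <- function(candidates, consumer_vocab) {
  stopifnot(inherits(candidates, "laylink_candidates"),
            length(candidates$terms) >= 1L)
  labeled_set(candidates,
              label = as.integer(candidates$terms %in% consumer_vocab),
              origin = "DISTANT")
}

#' @param label integer vector of 1 (important) / 0 labels.
#' @param origin `"DISTANT"` or `"MANUAL"`, recycled across items.
#' @rdname distant_label
#' @export
labeled_set <- function(candidates, label, origin) {
  stopifnot(length(label) == length(candidates$terms),
            all(label %in% c(0L, 1L)),
            all(origin %in% c("DISTANT", "MANUAL")))
  structure(list(terms = candidates$terms, features = candidates$features,
                 label = as.integer(label),
                 origin = rep_len(origin, length(label))),
            class = "laylink_labeled")
}

ridge_logistic <- function(x, y, lambda = 1e-2) {
  if (length(unique(y)) < 2L) {
    stop("training error: both classes must be present", call. = FALSE)
  }
  # glmnet needs >= 2 columns; pad degenerate toy inputs with a zero column
  pad <- ncol(x) < 2L
  if (pad) x <- cbind(x, 0)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  if (pad) beta <- beta[1L]
  list(intercept = as.numeric(fit$a0), weights = beta, lambda = lambda)
}

linear_score <- function(coefs, x) {
  as.numeric(stats::plogis(coefs$intercept + x %*% coefs$weights))
}

#' Train the base importance model on distant labels
#'
#' Fits an L2-regularized logistic regression on the `DISTANT`-origin items.
#' Deterministic: the solver has no random component at a fixed `lambda`.
#'
#' @param labeled a `laylink_labeled` set containing DISTANT items of both
#'   classes.
#' @param lambda ridge penalty (default 0.01).
#' @return a `laylink_model` with `base` coefficients (and `adapted = NULL`).
#' @export
train_base <- function(labeled, lambda = 1e-2) {
  stopifnot(inherits(labeled, "laylink_labeled"))
  keep <- labeled$origin == "DISTANT"
  if (!any(keep)) stop("training error: no DISTANT items", call. = FALSE)
  coefs <- ridge_logistic(labeled$features[keep, , drop = FALSE],
                          labeled$label[keep], lambda)
  structure(list(base = coefs, adapted = NULL,
                 provenance = list(classifier = "ridge-logistic",
                                   transfer = "stacking",
                                   lambda = lambda)),
            class = "laylink_model")
}

#' Adapt the base model with manually labeled examples
#'
#' Stacked transfer: the base model's probability is appended to the
#' feature vector and a second ridge-logistic model is fit on the
#' `MANUAL`-origin items. Base weights are left untouched; scoring uses the
#' adapted model once present.
#'
#' @param model a trained `laylink_model`.
#' @param manual a `laylink_labeled` set with `origin == "MANUAL"` items of
#'   both classes.
#' @param lambda ridge penalty for the adapted fit.
#' @return the model with `adapted` coefficients filled in.
#' @export
adapt <- function(model, manual, lambda = 1e-2) {
  stopifnot(inherits(model, "laylink_model"),
            inherits(manual, "laylink_labeled"))
  keep <- manual$origin == "MANUAL"
  if (!any(keep)) stop("adaptation error: no MANUAL items", call. = FALSE)
  x <- manual$features[keep, , drop = FALSE]
  y <- manual$label[keep]
  if (length(unique(y)) < 2L) {
    stop("adaptation error: manual set must contain both classes",
         call. = FALSE)
  }
  x2 <- cbind(x, base_score = linear_score(model$base, x))
  model$adapted <- ridge_logistic(x2, y, lambda)
  model
}

#' Score candidates with an importance model
#'
#' @param model a `laylink_model`.
#' @param candidates a `laylink_candidates` (or `laylink_labeled`) set.
#' @return numeric vector of probabilities in \[0, 1\], aligned to
#'   `candidates$terms`.
#' @export
score_candidates <- function(model, candidates) {
  x <- candidates$features
  if (is.null(model$adapted)) return(linear_score(model$base, x))
  x2 <- cbind(x, base_score = linear_score(model$base, x))
  linear_score(model$adapted, x2)
}

#' Rank candidate terms by importance probability
#'
#' @inheritParams score_candidates
#' @return data.frame `term`, `probability`, `rank`, sorted by probability
#'   descending with lexicographic tie-break.
#' @export
rank_terms <- function(model, candidates) {
  p <- score_candidates(model, candidates)
  ord <- order(-p, candidates$terms)
  data.frame(term = candidates$terms[ord], probability = p[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Area under the ROC curve of a score vector against binary labels
#'
#' Rank-based (Mann-Whitney) AUC; ties get mid-ranks. Used by the
#' simulation checks of the importance module.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  stopifnot(n1 > 0L, n0 > 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read a manual-label TSV (`term<TAB>label`, label in {1,0})
#'
#' @param path TSV path.
#' @return data.frame `term` (normalized), `label` (integer).
#' @export
load_manual_labels <- function(path) {
  tab <- read_tsv_strict(path, c("term", "label"))
  lab <- suppressWarnings(as.integer(tab$label))
  if (nrow(tab) && any(is.na(lab) | !(lab %in% c(0L, 1L)))) {
    stop("format error in ", path, ": label must be 0 or 1", call. = FALSE)
  }
  data.frame(term = normalize_key(tab$term), label = lab,
             stringsAsFactors = FALSE)
}
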