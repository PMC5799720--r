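`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures and independent oracles. The oracles deliberately avoid
# the code paths they check: the recognizer oracle enumerates every window,
# the stage oracle evaluates all four stages directly.

make_paper_lexicon <- function() {
  lexicon(list(
    definition_entry("bacteremia", "TERM", data.frame(
      sense_rank = 1L,
      definition_text = "The presence of bacteria, a type of germ, in the blood",
      source_tag = "fixture")),
    definition_entry("ac", "ACRONYM", data.frame(
      sense_rank = 1:2,
      definition_text = c(paste("a short-hand name for a chemotherapy",
                                "combination used to treat breast cancer"),
                          "assist control, a ventilator mode"),
      source_tag = "fixture")),
    definition_entry("hecoria", "DRUG", empty_senses(),
                     drug_class_key = "calcineurin inhibitors"),
    definition_entry("lantus", "DRUG", data.frame(
      sense_rank = 1:2,
      definition_text = c("A long-acting insulin used to control blood sugar.",
                          "Also used off-label in veterinary care."),
      source_tag = "fixture")),
    definition_entry("community", "TERM", data.frame(
      sense_rank = 1L, definition_text = "A group of people.",
      source_tag = "fixture")),
    definition_entry("pneumonia", "TERM", data.frame(
      sense_rank = 1L,
      definition_text = "An infection of the lungs, usually caused by viruses or bacteria.",
      source_tag = "fixture")),
    definition_entry("rhythm", "TERM", data.frame(
      sense_rank = 1L, definition_text = "The pattern of the heartbeat.",
      source_tag = "fixture")),
    definition_entry("heart failure", "TERM", data.frame(
      sense_rank = 1L,
      definition_text = "When the heart cannot pump enough blood.",
      source_tag = "fixture"))),
    drug_classes = c("calcineurin inhibitors" =
                       "A drug used to reduce immune response."))
}

make_paper_concepts <- function() {
  concept_table(data.frame(
    surface_form = c("bacteremia", "ac", "hecoria", "lantus",
                     "community acquired pneumonia", "normal sinus rhythm",
                     "chronic left heart failure"),
    concept_id = c("C001", "C002", "C003", "C004", "C005", "C006", "C007"),
    preferred_name = c("Bacteremia", "AC", "Hecoria", "Insulin Glargine",
                       "Community-Acquired Pneumonia", "Normal Sinus Rhythm",
                       "Chronic Left-Sided Heart Failure"),
    semantic_types = c("Disease or Syndrome", "Disease or Syndrome",
                       "Pharmacologic Substance", "Pharmacologic Substance",
                       "Disease or Syndrome", "Finding",
                       "Disease or Syndrome"),
    stringsAsFactors = FALSE))
}

# exhaustive window-scan recognizer oracle: score every token window, then
# select non-overlapping spans leftmost-first, longest on ties
oracle_recognize <- function(text, concepts, max_ngram = 6L) {
  toks <- tokenize(text)
  n <- nrow(toks)
  spans <- list()
  for (i in seq_len(n)) {
    for (len in seq_len(min(max_ngram, n - i + 1L))) {
      j <- i + len - 1L
      surface <- substr(text, toks$start[i] + 1L, toks$end[j])
      if (!is.null(concepts$records[[normalize_surface(surface)]])) {
        spans[[length(spans) + 1L]] <- c(toks$start[i], toks$end[j])
      }
    }
  }
  if (!length(spans)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1], -m[, 2]), , drop = FALSE]
  kept <- matrix(integer(), 0, 2)
  last_end <- -1L
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] >= last_end) {
      kept <- rbind(kept, m[r, ])
      last_end <- m[r, 2]
    }
  }
  data.frame(start = kept[, 1], end = kept[, 2])
}

# independent four-stage oracle: evaluates every stage unconditionally and
# reports the minimal hitting stage under the policy
oracle_stage <- function(surface, preferred, lex, policy, modifiers) {
  s <- normalize_surface(surface)
  hit <- function(k) nrow(resolve_definitions(k, lex)) > 0
  stage_hits <- c(s1 = hit(s), s2 = hit(normalize_key(preferred)),
                  s3 = FALSE, s4 = FALSE)
  trimmed <- trim_modifiers(s, modifiers)
  if (nzchar(trimmed) && trimmed != s) stage_hits["s3"] <- hit(trimmed)
  words <- unique(term_words(trimmed))
  stage_hits["s4"] <- any(vapply(words, hit, logical(1)))
  max_stage <- if (policy == "SHALLOW") 2L else 4L
  w <- which(stage_hits[seq_len(max_stage)])
  if (!length(w)) NA_integer_ else unname(w[1])
}

make_match <- function(surface, preferred = surface,
                       types = "Disease or Syndrome", start = 0L) {
  list(start = start, end = start + nchar(surface), surface = surface,
       concept = list(surface_form = normalize_surface(surface),
                      concept_id = "CX", preferred_name = preferred,
                      semantic_types = types))
}

# random valid lexicon for round-trip property tests
random_lexicon <- function(n = 8L) {
  keys <- unique(replicate(n, paste(
    sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")))
  entries <- lapply(keys, function(k) {
    cls <- sample(c("TERM", "ACRONYM", "DRUG"), 1)
    if (cls == "DRUG" && runif(1) < 0.5) {
      definition_entry(k, "DRUG", empty_senses(), "classa")
    } else {
      ns <- sample(1:3, 1)
      definition_entry(k, cls, data.frame(
        sense_rank = seq_len(ns),
        definition_text = replicate(ns, paste(
          sample(c(letters, " "), 20, replace = TRUE), collapse = "")),
        source_tag = sample(c("src1", "src2"), ns, replace = TRUE)))
    }
  })
  lexicon(entries, drug_classes = c(classa = "A class definition."))
}

# random concept table + text for recognizer oracle properties
random_recognizer_case <- function(n_vocab = 12L, n_tokens = 40L) {
  vocab_words <- unique(replicate(n_vocab, paste(
    sample(letters[1:6], sample(2:4, 1), replace = TRUE), collapse = "")))
  surfaces <- unique(vapply(seq_len(n_vocab), function(i) {
    paste(sample(vocab_words, sample(1:3, 1), replace = TRUE),
          collapse = " ")
  }, character(1)))
  concepts <- concept_table(data.frame(
    surface_form = surfaces,
    concept_id = sprintf("C%03d", seq_along(surfaces)),
    preferred_name = surfaces,
    semantic_types = "Disease or Syndrome", stringsAsFactors = FALSE))
  text <- paste(sample(c(vocab_words, c("and", "the", "with")), n_tokens,
                       replace = TRUE), collapse = " ")
  list(text = text, concepts = concepts)
}

matches_frame <- function(matches) {
  if (!length(matches)) return(data.frame(start = integer(),
                                          end = integer()))
  data.frame(start = vapply(matches, `[[`, integer(1), "start"),
             end = vapply(matches, `[[`, integer(1), "end"))
}

results_frame <- function(note) {
  if (!length(note$results)) {
    return(data.frame(start = integer(), end = integer(), stage = integer(),
                      partial = logical()))
  }
  data.frame(start = vapply(note$results, `[[`, integer(1), "start"),
             end = vapply(note$results, `[[`, integer(1), "end"),
             stage = vapply(note$results, `[[`, integer(1), "stage"),
             partial = vapply(note$results, `[[`, logical(1), "partial"))
}
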