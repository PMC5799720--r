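#' Tokenize note text into offset-bearing tokens
#'
#' Tokens are maximal runs of letters and digits, with apostrophes kept when
#' internal to a word ("Cushing's" is one token). Punctuation and whitespace
#' separate tokens; a hyphen splits. Offsets are 0-based, half-open, so
#' `substr(text, start + 1, end)` recovers the token.
#'
#' @param text a single string.
#' @return data.frame with columns `text`, `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- data.frame(text = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+(?:'[[:alnum:]]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(text = regmatches(text, list(m))[[1]],
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Recognize medical-term spans by greedy leftmost-longest dictionary match
#'
#' A deterministic stand-in for an external concept recognizer: token
#' windows up to `max_ngram` tokens wide are normalized (case-folded,
#' whitespace-collapsed, trailing possessives stripped) and matched exactly
#' against the concept table's surface forms. Matching is greedy
#' leftmost-longest with token consumption, so no overlapping or nested
#' matches are ever emitted.
#'
#' @param text note text.
#' @param concepts a `laylink_concepts` table.
#' @param max_ngram widest window, in tokens (default 6).
#' @return a `laylink_matches` list of concept matches, each with fields
#'   `start`, `end`, `surface`, `concept`.
#' @export
recognize <- function(text, concepts, max_ngram = 6L) {
  stopifnot(inherits(concepts, "laylink_concepts"), max_ngram >= 1L)
  toks <- tokenize(text)
  out <- list()
  n <- nrow(toks)
  widest <- min(max_ngram, concepts$max_words)
  if (widest < 1L) return(structure(out, class = "laylink_matches"))
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(widest, n - i + 1L), 1L)) {
      j <- i + len - 1L
      surface <- substr(text, toks$start[i] + 1L, toks$end[j])
      rec <- concepts$records[[normalize_surface(surface)]]
      if (!is.null(rec)) {
        hit <- list(start = toks$start[i], end = toks$end[j],
                    surface = surface, concept = rec)
        i <- j + 1L
        break
      }
    }
    if (is.null(hit)) i <- i + 1L else out[[length(out) + 1L]] <- hit
  }
  structure(out, class = "laylink_matches")
}

#' Import precomputed term spans from an external tagger
#'
#' Reads TSV rows `start<TAB>end<TAB>concept_id<TAB>preferred_name<TAB>
#' semantic_types` (0-based half-open offsets, `|`-joined types), validates
#' every span against the note text, and resolves overlaps by keeping the
#' leftmost-longest span, dropping the rest with a warning. This is the
#' escape hatch that lets real tagger output drive the linker.
#'
#' @param path TSV path of span records.
#' @param text the note text the spans index into.
#' @return a `laylink_matches` list.
#' @export
import_external_matches <- function(path, text) {
  tab <- read_tsv_strict(path, c("start", "end", "concept_id",
                                 "preferred_name", "semantic_types"))
  if (!nrow(tab)) return(structure(list(), class = "laylink_matches"))
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  n <- nchar(text)
  for (i in seq_len(nrow(tab))) {
    if (is.na(start[i]) || is.na(end[i]) || start[i] < 0L ||
        end[i] > n || start[i] >= end[i]) {
      stop("format error in ", path, ": span out of bounds at row ", i,
           " (", tab$start[i], ",", tab$end[i], ") for text of length ", n,
           call. = FALSE)
    }
    st <- strsplit(tab$semantic_types[i], "|", fixed = TRUE)[[1]]
    if (!length(st[nzchar(st)])) {
      stop("format error in ", path, ": empty semantic_types at row ", i,
           call. = FALSE)
    }
  }
  ord <- order(start, -(end - start))
  kept <- list()
  last_end <- 0L
  dropped <- 0L
  for (i in ord) {
    if (start[i] < last_end) { dropped <- dropped + 1L; next }
    surface <- substr(text, start[i] + 1L, end[i])
    st <- strsplit(tab$semantic_types[i], "|", fixed = TRUE)[[1]]
    kept[[length(kept) + 1L]] <- list(
      start = start[i], end = end[i], surface = surface,
      concept = list(surface_form = normalize_surface(surface),
                     concept_id = tab$concept_id[i],
                     preferred_name = tab$preferred_name[i],
                     semantic_types = st[nzchar(st)]))
    last_end <- end[i]
  }
  if (dropped) {
    warning(dropped, " overlapping span(s) dropped from ", path,
            " (leftmost-longest kept)", call. = FALSE)
  }
  structure(kept, class = "laylink_matches")
}

#' @export
print.laylink_matches <- function(x, ...) {
  cat("<laylink matches>", length(x), "span(s)\n")
  for (m in x) {
    cat(sprintf("  [%d,%d) %-30s %s\n", m$start, m$end, m$surface,
                m$concept$concept_id))
  }
  invisible(x)
}
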