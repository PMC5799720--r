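#' Classify the lookup policy of a match from its semantic types
#'
#' Gating rule: if ANY semantic type of the concept is prioritized the term
#' gets the full four-stage lookup (`"FULL"`); otherwise, if ALL of its
#' types are deprioritized the term is ignored (`"SKIP"`); anything else is
#' searched at only the first two stages (`"SHALLOW"`).
#'
#' @param semantic_types character vector of the concept's semantic types
#'   (non-empty), or a match object carrying `$concept$semantic_types`.
#' @param config a `laylink_semconfig`.
#' @return one of `"FULL"`, `"SHALLOW"`, `"SKIP"`.
#' @export
classify_policy <- function(semantic_types, config) {
  if (is.list(semantic_types)) {
    semantic_types <- semantic_types$concept$semantic_types
  }
  stopifnot(length(semantic_types) >= 1L)
  if (any(semantic_types %in% config$prioritized)) return("FULL")
  if (all(semantic_types %in% config$deprioritized)) return("SKIP")
  "SHALLOW"
}

#' Remove modifier words from a term
#'
#' Drops every word of the (normalized) term that appears in the modifier
#' list, preserving the order of the remaining words. May return an empty
#' string when the term is all modifiers.
#'
#' @param term normalized term string.
#' @param modifiers a `laylink_modifiers` word set.
#' @return the trimmed term.
#' @export
trim_modifiers <- function(term, modifiers) {
  w <- term_words(term)
  paste(w[!(w %in% modifiers)], collapse = " ")
}

#' Four-stage definition lookup for one recognized match
#'
#' Stages, stopping at the first hit:
#' 1. exact match of the normalized surface form in the lexicon;
#' 2. the concept's preferred name;
#' 3. the surface with modifier words removed (only when trimming changed
#'    the term and left it non-empty);
#' 4. each distinct word of the trimmed term individually — a partial match
#'    that displays one labeled item per word that has a definition.
#'
#' `"SHALLOW"` policy stops after stage 2. Returns `NULL` on a complete
#' miss (the span is then not highlighted at all).
#'
#' @param match a concept match (from [recognize()] or
#'   [import_external_matches()]).
#' @param lex a `laylink_lexicon`.
#' @param policy `"FULL"` or `"SHALLOW"` (callers never pass `"SKIP"`).
#' @param modifiers a `laylink_modifiers` word set.
#' @param cache optional environment memoizing lookups across matches,
#'   keyed by (surface, preferred name, policy).
#' @param max_senses sense cap forwarded to [resolve_definitions()].
#' @return a `laylink_result` list (`stage`, `partial`, `items`, plus the
#'   match fields), or `NULL`.
#' @export
lookup <- function(match, lex, policy, modifiers, cache = NULL,
                   max_senses = Inf) {
  stopifnot(policy %in% c("FULL", "SHALLOW"))
  surface <- normalize_surface(match$surface)
  preferred <- normalize_key(match$concept$preferred_name)
  key <- paste(policy, surface, preferred, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[key]])) {
    hit <- cache[[key]]
    if (identical(hit, "MISS")) return(NULL)
    return(as_result(match, hit))
  }
  core <- lookup_core(surface, preferred, lex, policy, modifiers, max_senses)
  if (!is.null(cache)) cache[[key]] <- if (is.null(core)) "MISS" else core
  if (is.null(core)) NULL else as_result(match, core)
}

# stage machinery over normalized strings only; reused by the cache
lookup_core <- function(surface, preferred, lex, policy, modifiers,
                        max_senses = Inf) {
  item_frame <- function(defs, label = NA_character_) {
    data.frame(label = rep(label, nrow(defs)),
               definition_text = defs$definition_text,
               provenance = defs$provenance, stringsAsFactors = FALSE)
  }
  d1 <- resolve_definitions(surface, lex, max_senses)
  if (nrow(d1)) return(list(stage = 1L, partial = FALSE, items = item_frame(d1)))
  d2 <- resolve_definitions(preferred, lex, max_senses)
  if (nrow(d2)) return(list(stage = 2L, partial = FALSE, items = item_frame(d2)))
  if (policy == "SHALLOW") return(NULL)
  trimmed <- trim_modifiers(surface, modifiers)
  if (nzchar(trimmed) && !identical(trimmed, surface)) {
    d3 <- resolve_definitions(trimmed, lex, max_senses)
    if (nrow(d3)) return(list(stage = 3L, partial = FALSE, items = item_frame(d3)))
  }
  words <- unique(term_words(trimmed))
  items <- list()
  for (w in words) {
    dw <- resolve_definitions(w, lex, max_senses)
    if (nrow(dw)) items[[length(items) + 1L]] <- item_frame(dw, label = w)
  }
  if (!length(items)) return(NULL)
  list(stage = 4L, partial = TRUE, items = do.call(rbind, items))
}

as_result <- function(match, core) {
  structure(list(start = match$start, end = match$end,
                 surface = match$surface,
                 concept_id = match$concept$concept_id,
                 preferred_name = match$concept$preferred_name,
                 stage = core$stage, partial = core$partial,
                 items = core$items),
            class = "laylink_result")
}

#' Annotate a note end to end
#'
#' Recognizes term spans (or takes imported spans), gates each by semantic
#' type, runs the four-stage lookup under the resulting policy, and
#' assembles an annotated note. Lookups are memoized across matches in a
#' per-call hash table (interim search results are stored for reuse);
#' disabling the cache never changes the output. Counts of matches by
#' policy and results by stage are reported on standard error.
#'
#' @param text note text (single string).
#' @param concepts a `laylink_concepts` table.
#' @param lex a `laylink_lexicon`.
#' @param config a `laylink_semconfig`.
#' @param modifiers a `laylink_modifiers` word set.
#' @param matches optional precomputed `laylink_matches` (bypasses
#'   [recognize()]).
#' @param use_cache memoize lookups (default `TRUE`).
#' @param max_senses sense cap per entry.
#' @param max_ngram recognizer window width.
#' @param quiet suppress the stderr count lines.
#' @return a `laylink_note`: list with `text`, `results` (list of
#'   `laylink_result` sorted by start), and `provenance`.
#' @export
annotate <- function(text, concepts, lex, config, modifiers,
                     matches = NULL, use_cache = TRUE, max_senses = Inf,
                     max_ngram = 6L, quiet = FALSE) {
  if (is.null(matches)) matches <- recognize(text, concepts, max_ngram)
  cache <- if (use_cache) new.env(parent = emptyenv()) else NULL
  policy_counts <- c(FULL = 0L, SHALLOW = 0L, SKIP = 0L)
  stage_counts <- c(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 0L)
  results <- list()
  for (m in matches) {
    policy <- classify_policy(m$concept$semantic_types, config)
    policy_counts[policy] <- policy_counts[policy] + 1L
    if (policy == "SKIP") next
    r <- lookup(m, lex, policy, modifiers, cache, max_senses)
    if (is.null(r)) next
    stage_counts[as.character(r$stage)] <-
      stage_counts[as.character(r$stage)] + 1L
    results[[length(results) + 1L]] <- r
  }
  if (!quiet) {
    message("laylink: matches by policy: ",
            paste(names(policy_counts), policy_counts, sep = "=",
                  collapse = " "))
    message("laylink: results by stage: ",
            paste(names(stage_counts), stage_counts, sep = "=",
                  collapse = " "))
  }
  structure(list(text = text, results = results,
                 provenance = list(
                   text_hash = string_md5(text),
                   lexicon_entries = length(lex$entries),
                   cache = use_cache)),
            class = "laylink_note")
}

#' @export
print.laylink_note <- function(x, ...) {
  cat("<laylink annotated note>", nchar(x$text), "chars,",
      length(x$results), "linked term(s)\n")
  for (r in x$results) {
    cat(sprintf("  [%d,%d) %-28s stage %d%s\n", r$start, r$end, r$surface,
                r$stage, if (r$partial) " (partial)" else ""))
  }
  invisible(x)
}

#' Serialize an annotated note to a JSON record
#'
#' The record carries a hash of the note text (not the text itself) plus
#' every result's span, concept, stage, partial flag, and items;
#' [parse_annotations()] re-validates the spans against the text and fails
#' on any mismatch, so the round-trip is lossless or loud.
#'
#' @param note a `laylink_note`.
#' @return a JSON string.
#' @export
serialize_annotations <- function(note) {
  stopifnot(inherits(note, "laylink_note"))
  rec <- list(
    text_hash = note$provenance$text_hash,
    results = lapply(note$results, function(r) {
      list(start = r$start, end = r$end, surface = r$surface,
           concept_id = r$concept_id, preferred_name = r$preferred_name,
           stage = r$stage, partial = r$partial,
           items = lapply(seq_len(nrow(r$items)), function(i) {
             list(label = r$items$label[i],
                  definition_text = r$items$definition_text[i],
                  provenance = r$items$provenance[i])
           }))
    }))
  jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
}

#' @param record JSON string from [serialize_annotations()].
#' @param text the note text the record was produced from.
#' @rdname serialize_annotations
#' @return [parse_annotations()] returns the reconstructed `laylink_note`.
#' @export
parse_annotations <- function(record, text) {
  rec <- jsonlite::fromJSON(record, simplifyVector = FALSE)
  if (!identical(rec$text_hash, string_md5(text))) {
    stop("integrity error: annotation record does not match this text",
         call. = FALSE)
  }
  results <- lapply(rec$results, function(r) {
    slice <- substr(text, r$start + 1L, r$end)
    if (!identical(slice, r$surface)) {
      stop("integrity error: span [", r$start, ",", r$end,
           ") does not slice to '", r$surface, "'", call. = FALSE)
    }
    items <- do.call(rbind, lapply(r$items, function(it) {
      data.frame(label = if (is.null(it$label)) NA_character_ else it$label,
                 definition_text = it$definition_text,
                 provenance = it$provenance, stringsAsFactors = FALSE)
    }))
    structure(list(start = as.integer(r$start), end = as.integer(r$end),
                   surface = r$surface, concept_id = r$concept_id,
                   preferred_name = r$preferred_name,
                   stage = as.integer(r$stage), partial = r$partial,
                   items = items),
              class = "laylink_result")
  })
  structure(list(text = text, results = results,
                 provenance = list(text_hash = rec$text_hash)),
            class = "laylink_note")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&#39;", x, fixed = TRUE)
}

#' Render an annotated note as hover-definition HTML
#'
#' Each linked span is wrapped in a highlight `<span>` whose `title`
#' attribute carries the definitions (shown on hover). Partial (stage-4)
#' items are prefixed with their bracketed word label, e.g.
#' `[rhythm]: ...`. All text is entity-escaped and no hyperlinks are
#' emitted.
#'
#' @param note a `laylink_note`.
#' @return a single HTML string (a `<div>` fragment).
#' @export
render_html <- function(note) {
  stopifnot(inherits(note, "laylink_note"))
  parts <- character()
  pos <- 0L
  for (r in note$results) {
    if (r$start > pos) {
      parts <- c(parts, html_escape(substr(note$text, pos + 1L, r$start)))
    }
    defs <- vapply(seq_len(nrow(r$items)), function(i) {
      lab <- r$items$label[i]
      txt <- r$items$definition_text[i]
      if (is.na(lab)) txt else paste0("[", lab, "]: ", txt)
    }, character(1))
    parts <- c(parts, sprintf(
      '<span class="laylink-term" data-stage="%d" title="%s">%s</span>',
      r$stage, html_escape(paste(defs, collapse = " | ")),
      html_escape(substr(note$text, r$start + 1L, r$end))))
    pos <- r$end
  }
  if (pos < nchar(note$text)) {
    parts <- c(parts, html_escape(substr(note$text, pos + 1L,
                                         nchar(note$text))))
  }
  paste0('<div class="laylink-note">', paste(parts, collapse = ""), "</div>")
}
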