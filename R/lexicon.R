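#' @title Lay-definition lexicon
#' @description
#' The lexicon maps normalized term keys to ordered definition senses, with
#' an entry class per term (`TERM`, `ACRONYM`, `DRUG`) and an optional
#' drug-class fallback for sense-less drug entries. It stands in for a
#' curated consumer-health definition resource; the file dialect is a plain
#' UTF-8 TSV so content can be authored by hand or generated.
#'
#' @name laylink_lexicon
NULL

ENTRY_CLASSES <- c("TERM", "ACRONYM", "DRUG")

#' Construct a definition entry
#'
#' @param term_key term string; normalized on construction.
#' @param entry_class one of `"TERM"`, `"ACRONYM"`, `"DRUG"`.
#' @param senses data.frame with columns `sense_rank` (integer),
#'   `definition_text`, `source_tag`; may have zero rows for a DRUG entry
#'   that resolves through its drug class.
#' @param drug_class_key optional class key (DRUG entries only).
#' @return a `laylink_entry` list.
#' @export
definition_entry <- function(term_key, entry_class,
                             senses = empty_senses(),
                             drug_class_key = NA_character_) {
  term_key <- normalize_key(term_key)
  entry_class <- match.arg(entry_class, ENTRY_CLASSES)
  senses <- as.data.frame(senses, stringsAsFactors = FALSE)
  if (nrow(senses)) {
    senses$sense_rank <- as.integer(senses$sense_rank)
    senses <- senses[order(senses$sense_rank), , drop = FALSE]
    rownames(senses) <- NULL
    if (anyDuplicated(senses$sense_rank)) {
      stop("duplicate sense_rank in entry '", term_key, "'", call. = FALSE)
    }
    if (!identical(senses$sense_rank, seq_len(nrow(senses)))) {
      stop("sense_rank values for '", term_key,
           "' must be contiguous from 1", call. = FALSE)
    }
    if (any(!nzchar(senses$definition_text))) {
      stop("empty definition_text in entry '", term_key, "'", call. = FALSE)
    }
  }
  if (!is.na(drug_class_key) && entry_class != "DRUG") {
    stop("drug_class_key is only valid for DRUG entries ('",
         term_key, "')", call. = FALSE)
  }
  structure(list(term_key = term_key, entry_class = entry_class,
                 senses = senses,
                 drug_class_key = if (is.na(drug_class_key)) NA_character_
                                  else normalize_key(drug_class_key)),
            class = "laylink_entry")
}

#' @rdname definition_entry
#' @export
empty_senses <- function() {
  data.frame(sense_rank = integer(), definition_text = character(),
             source_tag = character(), stringsAsFactors = FALSE)
}

#' Construct a lexicon from entries and drug-class definitions
#'
#' @param entries list of [definition_entry()] objects.
#' @param drug_classes named character vector mapping normalized class keys
#'   to class-level definitions.
#' @return a `laylink_lexicon` object.
#' @export
lexicon <- function(entries = list(), drug_classes = character()) {
  if (length(drug_classes)) {
    names(drug_classes) <- normalize_key(names(drug_classes))
    if (any(!nzchar(drug_classes))) {
      stop("drug class definitions must be non-empty", call. = FALSE)
    }
  }
  ents <- list()
  for (e in entries) {
    stopifnot(inherits(e, "laylink_entry"))
    if (!is.null(ents[[e$term_key]])) {
      stop("duplicate lexicon entry for term_key '", e$term_key, "'",
           call. = FALSE)
    }
    ents[[e$term_key]] <- e
  }
  lex <- structure(list(entries = ents, drug_classes = drug_classes),
                   class = "laylink_lexicon")
  validate_lexicon(lex)
  lex
}

validate_lexicon <- function(lex) {
  for (e in lex$entries) {
    if (!is.na(e$drug_class_key) &&
        !(e$drug_class_key %in% names(lex$drug_classes))) {
      stop("referential-integrity error: entry '", e$term_key,
           "' references unknown drug class '", e$drug_class_key, "'",
           call. = FALSE)
    }
  }
  invisible(lex)
}

#' @export
print.laylink_lexicon <- function(x, ...) {
  cat("<laylink lexicon>", length(x$entries), "entries,",
      length(x$drug_classes), "drug classes\n")
  invisible(x)
}

LEXICON_HEADER <- c("term_key", "entry_class", "sense_rank",
                    "definition_text", "source_tag", "drug_class_key")

#' Read a lexicon from its TSV dialect
#'
#' The lexicon file is a UTF-8 TSV with header
#' `term_key, entry_class, sense_rank, definition_text, source_tag,
#' drug_class_key`; one row per sense, or a single sense-less row for DRUG
#' entries that resolve through a drug class. Keys are normalized on load.
#'
#' @param path lexicon TSV path.
#' @param drug_class_path optional TSV `class_key<TAB>definition_text`;
#'   required when any entry carries a `drug_class_key`.
#' @return a `laylink_lexicon`.
#' @export
load_lexicon <- function(path, drug_class_path = NULL) {
  tab <- read_tsv_strict(path, LEXICON_HEADER)
  drug_classes <- character()
  if (!is.null(drug_class_path)) {
    dc <- read_tsv_strict(drug_class_path, c("class_key", "definition_text"))
    if (nrow(dc)) {
      drug_classes <- stats::setNames(dc$definition_text,
                                      normalize_key(dc$class_key))
      if (anyDuplicated(names(drug_classes))) {
        stop("duplicate class_key in ", drug_class_path, call. = FALSE)
      }
    }
  }
  if (!nrow(tab)) return(lexicon(list(), drug_classes))
  tab$term_key <- normalize_key(tab$term_key)
  key <- paste(tab$term_key, tab$sense_rank, sep = "\r")
  has_rank <- nzchar(tab$sense_rank)
  dup <- duplicated(key) & has_rank
  if (any(dup)) {
    stop("format error in ", path, ": duplicate (term_key, sense_rank) at line ",
         which(dup)[1] + 1L, " (", tab$term_key[which(dup)[1]], ", ",
         tab$sense_rank[which(dup)[1]], ")", call. = FALSE)
  }
  entries <- lapply(split(seq_len(nrow(tab)), tab$term_key), function(idx) {
    rows <- tab[idx, , drop = FALSE]
    cls <- unique(rows$entry_class)
    if (length(cls) != 1L) {
      stop("format error in ", path, ": conflicting entry_class for '",
           rows$term_key[1], "'", call. = FALSE)
    }
    dck <- unique(rows$drug_class_key[nzchar(rows$drug_class_key)])
    if (length(dck) > 1L) {
      stop("format error in ", path, ": conflicting drug_class_key for '",
           rows$term_key[1], "'", call. = FALSE)
    }
    sensed <- rows[nzchar(rows$sense_rank), , drop = FALSE]
    senses <- if (nrow(sensed)) {
      data.frame(sense_rank = as.integer(sensed$sense_rank),
                 definition_text = sensed$definition_text,
                 source_tag = sensed$source_tag, stringsAsFactors = FALSE)
    } else empty_senses()
    definition_entry(rows$term_key[1], cls, senses,
                     if (length(dck)) dck else NA_character_)
  })
  lexicon(unname(entries), drug_classes)
}

#' Write a lexicon in its canonical TSV dialect
#'
#' Rows are sorted by `term_key` then `sense_rank`, so two writes of the
#' same lexicon are byte-identical and `load_lexicon(write_lexicon(L)) == L`.
#'
#' @param lex a `laylink_lexicon`.
#' @param path output lexicon TSV path.
#' @param drug_class_path optional output path for the drug-class TSV.
#' @return invisibly, `path`.
#' @export
write_lexicon <- function(lex, path, drug_class_path = NULL) {
  stopifnot(inherits(lex, "laylink_lexicon"))
  rows <- list()
  for (key in sort(names(lex$entries))) {
    e <- lex$entries[[key]]
    dck <- if (is.na(e$drug_class_key)) "" else e$drug_class_key
    if (nrow(e$senses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term_key = key, entry_class = e$entry_class,
        sense_rank = as.character(e$senses$sense_rank),
        definition_text = e$senses$definition_text,
        source_tag = e$senses$source_tag, drug_class_key = dck,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        term_key = key, entry_class = e$entry_class, sense_rank = "",
        definition_text = "", source_tag = "", drug_class_key = dck,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(), 0, 6),
                                  stringsAsFactors = FALSE), LEXICON_HEADER)
  write_tsv_strict(tab, path, LEXICON_HEADER)
  if (!is.null(drug_class_path)) {
    keys <- sort(names(lex$drug_classes))
    dc <- data.frame(class_key = keys,
                     definition_text = unname(lex$drug_classes[keys]),
                     stringsAsFactors = FALSE)
    write_tsv_strict(dc, drug_class_path, c("class_key", "definition_text"))
  }
  invisible(path)
}

#' Resolve the displayable definitions of a term key
#'
#' Display policy by entry class: acronyms show only the most-frequent
#' (rank-1) sense; drugs with authored senses show every sense in rank
#' order (multi-purpose drugs keep all their readings); sense-less drugs
#' fall back to their drug-class definition; plain terms show all senses in
#' rank order. An unknown key resolves to an empty result, never an error.
#'
#' @param term_key normalized term key.
#' @param lex a `laylink_lexicon`.
#' @param max_senses cap on the number of senses returned for non-acronym
#'   entries (`Inf` keeps all).
#' @return data.frame with columns `definition_text`, `provenance`
#'   (`"SENSE"` or `"DRUG_CLASS"`), zero rows when the key is unknown.
#' @export
resolve_definitions <- function(term_key, lex, max_senses = Inf) {
  empty <- data.frame(definition_text = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  e <- lex$entries[[term_key]]
  if (is.null(e)) return(empty)
  if (nrow(e$senses)) {
    keep <- if (e$entry_class == "ACRONYM") 1L else
      seq_len(min(nrow(e$senses), max_senses))
    return(data.frame(definition_text = e$senses$definition_text[keep],
                      provenance = rep("SENSE", length(keep)),
                      stringsAsFactors = FALSE))
  }
  if (e$entry_class == "DRUG" && !is.na(e$drug_class_key)) {
    return(data.frame(
      definition_text = unname(lex$drug_classes[[e$drug_class_key]]),
      provenance = "DRUG_CLASS", stringsAsFactors = FALSE))
  }
  empty
}

CONCEPT_HEADER <- c("surface_form", "concept_id", "preferred_name",
                    "semantic_types")

#' Load the concept table (surface form to concept record)
#'
#' Stand-in for an external concept recognizer's dictionary: each normalized
#' surface form maps to exactly one concept (ambiguity is expressed upstream
#' through lexicon sense ranks). `semantic_types` is `|`-joined in the file
#' and must be non-empty.
#'
#' @param path TSV path with header
#'   `surface_form, concept_id, preferred_name, semantic_types`.
#' @return a `laylink_concepts` object (named list of concept records keyed
#'   by normalized surface form).
#' @export
load_concept_table <- function(path) {
  tab <- read_tsv_strict(path, CONCEPT_HEADER)
  concept_table(tab)
}

#' Build a concept table from a data.frame
#'
#' @param tab data.frame with the concept-table columns.
#' @return a `laylink_concepts` object.
#' @export
concept_table <- function(tab) {
  recs <- list()
  if (nrow(tab)) {
    # records are indexed by the match-time normalization (possessive
    # stripped) so "cushing's syndrome" and "cushing syndrome" collide on
    # purpose; the stored surface_form keeps the key normalization
    surf <- normalize_surface(tab$surface_form)
    for (i in seq_len(nrow(tab))) {
      st <- strsplit(tab$semantic_types[i], "|", fixed = TRUE)[[1]]
      st <- st[nzchar(st)]
      if (!length(st)) {
        stop("format error: empty semantic_types for surface '",
             surf[i], "' (row ", i, ")", call. = FALSE)
      }
      prev <- recs[[surf[i]]]
      if (!is.null(prev)) {
        if (!identical(prev$concept_id, tab$concept_id[i])) {
          stop("format error: surface '", surf[i],
               "' maps to multiple concept_ids (row ", i, ")",
               call. = FALSE)
        }
        recs[[surf[i]]]$semantic_types <- union(prev$semantic_types, st)
        next
      }
      recs[[surf[i]]] <- list(surface_form = surf[i],
                              concept_id = tab$concept_id[i],
                              preferred_name = tab$preferred_name[i],
                              semantic_types = st)
    }
  }
  nwords <- if (length(recs)) {
    vapply(names(recs), function(s) length(term_words(s)), integer(1))
  } else integer()
  structure(list(records = recs, max_words = max(c(nwords, 0L))),
            class = "laylink_concepts")
}

#' Look up the concept record for a surface string
#'
#' @param concepts a `laylink_concepts` table.
#' @param surface raw surface string (normalized internally).
#' @return the concept record (list), or `NULL` when unknown.
#' @export
concept_lookup <- function(concepts, surface) {
  concepts$records[[normalize_surface(surface)]]
}

#' @export
print.laylink_concepts <- function(x, ...) {
  cat("<laylink concept table>", length(x$records), "surface forms\n")
  invisible(x)
}

#' Load semantic-type configuration and modifier list
#'
#' The config file has plain-text sections `[prioritized]`,
#' `[deprioritized]` and (optionally, same file or a separate one)
#' `[modifiers]`, one item per line, `#` comments. Prioritized and
#' deprioritized sets must be disjoint.
#'
#' @param path config file path.
#' @return list with elements `prioritized` and `deprioritized`
#'   (character vectors), class `laylink_semconfig`.
#' @export
load_semantic_config <- function(path) {
  sec <- read_sections(path)
  pri <- unique(sec[["prioritized"]] %||% character())
  dep <- unique(sec[["deprioritized"]] %||% character())
  semantic_config(pri, dep)
}

#' @param prioritized,deprioritized character vectors of semantic-type names.
#' @rdname load_semantic_config
#' @export
semantic_config <- function(prioritized, deprioritized) {
  both <- intersect(prioritized, deprioritized)
  if (length(both)) {
    stop("config error: semantic types in both sections: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(prioritized = prioritized, deprioritized = deprioritized),
            class = "laylink_semconfig")
}

#' @rdname load_semantic_config
#' @export
default_semantic_config <- function() {
  load_semantic_config(system.file("extdata", "default_config.txt",
                                   package = "laylink", mustWork = TRUE))
}

#' Load the modifier word list
#'
#' Single lowercase words removed at the modifier-trimming lookup stage
#' (common modifiers of diseases and body locations such as "chronic",
#' "severe", "left"). Multi-word lines are a format error.
#'
#' @param path config file path containing a `[modifiers]` section.
#' @return a `laylink_modifiers` character vector.
#' @export
load_modifiers <- function(path) {
  sec <- read_sections(path)
  modifier_list(sec[["modifiers"]] %||% character())
}

#' @param words character vector of single words.
#' @rdname load_modifiers
#' @export
modifier_list <- function(words) {
  words <- unique(normalize_key(words))
  words <- words[nzchar(words)]
  if (any(grepl(" ", words, fixed = TRUE))) {
    stop("modifier list must contain single words only", call. = FALSE)
  }
  structure(words, class = "laylink_modifiers")
}

#' @rdname load_modifiers
#' @export
default_modifiers <- function() {
  load_modifiers(system.file("extdata", "default_config.txt",
                             package = "laylink", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- shared TSV / section-file plumbing ------------------------------------

read_tsv_strict <- function(path, header) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           encoding = "UTF-8", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!identical(names(tab), header)) {
    stop("format error in ", path, ": expected header ",
         paste(header, collapse = "\t"), call. = FALSE)
  }
  tab
}

write_tsv_strict <- function(tab, path, header) {
  stopifnot(identical(names(tab), header))
  if (nrow(tab) &&
      any(vapply(tab, function(col) any(grepl("[\t\n\r]", col)), logical(1)))) {
    stop("fields may not contain tabs or newlines", call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(header, collapse = "\t"),
             if (nrow(tab)) do.call(paste, c(unname(as.list(tab)), sep = "\t")))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

read_sections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[current]])) out[[current]] <- character()
    } else {
      if (is.null(current)) {
        stop("config error in ", path, ": item before any [section]",
             call. = FALSE)
      }
      out[[current]] <- c(out[[current]], ln)
    }
  }
  out
}
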