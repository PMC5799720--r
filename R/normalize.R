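#' Normalize a term string to its lexicon key form
#'
#' Canonical key normalization used everywhere a surface string is compared
#' against the lexicon or the concept table: Unicode NFC, lowercase, strip
#' leading/trailing whitespace, collapse internal whitespace runs to a single
#' space. Stored keys never have the possessive stripped; see
#' [normalize_surface()] for match-time normalization.
#'
#' @param x character vector.
#' @return character vector of normalized keys.
#' @examples
#' normalize_key("  Cushing's   Syndrome ")
#' @export
normalize_key <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalize a surface form for dictionary matching
#'
#' Applies [normalize_key()] and additionally strips a trailing possessive
#' `'s` from each word, so that "Cushing's syndrome" matches the stored
#' surface "cushing syndrome" (or "cushing's syndrome", which the concept
#' table stores already key-normalized). Applied only at match time, never
#' to stored keys.
#'
#' @param x character vector.
#' @return character vector.
#' @export
normalize_surface <- function(x) {
  x <- normalize_key(x)
  # possessive trailing 's on any word of the surface
  gsub("'s(?=\\s|$)", "", x, perl = TRUE)
}

# internal: split a normalized term into its words
term_words <- function(x) {
  w <- strsplit(x, " ", fixed = TRUE)[[1]]
  w[nzchar(w)]
}

# internal: stable md5 of a UTF-8 string (used for provenance / text_hash)
string_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(charToRaw(enc2utf8(x)), tf)
  unname(tools::md5sum(tf))
}
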