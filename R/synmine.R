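#' @title Synonym mining from interwiki links with PRF reranking
#' @description
#' Candidate synonyms for a target term are its neighbors in an
#' interwiki-link graph (pages on a health topic tree link synonyms,
#' hyponyms and related terms to each other). Candidates are first ranked
#' by cosine similarity between word-embedding representations, then
#' reranked with Rocchio-style pseudo-relevance feedback: the top-ranked
#' candidates stand in for relevance judgments and sharpen the target's
#' representation.
#' @name laylink_synmine
NULL

#' Load an interwiki-link edge list
#'
#' TSV `term_a<TAB>term_b`, undirected; terms are normalized, self-edges
#' dropped, duplicate (unordered) pairs collapsed.
#'
#' @param path edge-list TSV path.
#' @return a `laylink_graph` with a two-column `edges` data.frame.
#' @export
load_edge_list <- function(path) {
  tab <- read_tsv_strict(path, c("term_a", "term_b"))
  link_graph(tab$term_a, tab$term_b)
}

#' @param term_a,term_b character vectors of endpoint terms.
#' @rdname load_edge_list
#' @export
link_graph <- function(term_a, term_b) {
  a <- normalize_key(term_a)
  b <- normalize_key(term_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  structure(list(edges = data.frame(term_a = lo[!dup], term_b = hi[!dup],
                                    stringsAsFactors = FALSE)),
            class = "laylink_graph")
}

#' Candidate synonyms of a target term
#'
#' All graph neighbors of the target, deduplicated, excluding the target
#' itself, in lexicographic order (the pre-ranking order).
#'
#' @param graph a `laylink_graph`.
#' @param target normalized target term.
#' @return character vector of candidates (possibly empty).
#' @export
syn_candidates <- function(graph, target) {
  target <- normalize_key(target)
  nb <- c(graph$edges$term_b[graph$edges$term_a == target],
          graph$edges$term_a[graph$edges$term_b == target])
  sort(unique(nb[nb != target]))
}

#' Read / write a word-vector table
#'
#' Plain-text format: header line `n d`, then one line per token:
#' `token v1 v2 ... vd`, space-separated.
#'
#' @param path vector-table path.
#' @return a numeric matrix with tokens as rownames (class
#'   `laylink_vectors`).
#' @export
load_vectors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hd <- as.integer(strsplit(trimws(lines[1]), " +")[[1]])
  if (length(hd) != 2L || anyNA(hd)) {
    stop("format error in ", path, ": expected header 'n d'", call. = FALSE)
  }
  n <- hd[1]; d <- hd[2]
  if (length(lines) - 1L != n) {
    stop("format error in ", path, ": header declares ", n, " rows, found ",
         length(lines) - 1L, call. = FALSE)
  }
  toks <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), " +")[[1]]
    if (length(parts) != d + 1L) {
      stop("format error in ", path, ": row ", i, " has ",
           length(parts) - 1L, " values, expected ", d, call. = FALSE)
    }
    toks[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  if (anyNA(mat)) stop("format error in ", path, ": non-numeric value",
                       call. = FALSE)
  if (anyDuplicated(toks)) {
    stop("format error in ", path, ": duplicate token", call. = FALSE)
  }
  rownames(mat) <- toks
  structure(mat, class = c("laylink_vectors", "matrix", "array"))
}

#' @param vectors a matrix with tokens as rownames.
#' @rdname load_vectors
#' @export
write_vectors <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  rows <- vapply(seq_len(nrow(vectors)), function(i) {
    paste(c(rownames(vectors)[i],
            formatC(vectors[i, ], format = "g", digits = 17)),
          collapse = " ")
  }, character(1))
  writeLines(enc2utf8(c(paste(nrow(vectors), ncol(vectors)), rows)), con,
             useBytes = TRUE)
  invisible(path)
}

#' Embed a (possibly multi-word) term
#'
#' A single word maps to its vector; a multi-word term to the arithmetic
#' mean of the vectors of its in-vocabulary words. `NULL` (missing) when no
#' word of the term is in the table.
#'
#' @param term normalized term.
#' @param vectors a `laylink_vectors` matrix.
#' @return numeric vector of length `ncol(vectors)`, or `NULL`.
#' @export
embed_term <- function(term, vectors) {
  w <- term_words(normalize_key(term))
  present <- w[w %in% rownames(vectors)]
  if (!length(present)) return(NULL)
  colMeans(vectors[present, , drop = FALSE])
}

cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Rank candidate synonyms by embedding cosine similarity
#'
#' Scored candidates are sorted by `sim_plain` descending with
#' lexicographic tie-break; candidates with no embedding sink to the
#' bottom in lexicographic order (`sim_plain = NA`).
#'
#' @param target normalized target term (must have an embedding).
#' @param candidates character vector of candidate terms.
#' @param vectors a `laylink_vectors` matrix.
#' @return data.frame `target`, `candidate`, `sim_plain`, `rank_plain`.
#' @export
rank_by_similarity <- function(target, candidates, vectors) {
  target <- normalize_key(target)
  t_emb <- embed_term(target, vectors)
  if (is.null(t_emb)) {
    stop("target '", target, "' has no embedding; skip this target",
         call. = FALSE)
  }
  candidates <- unique(normalize_key(candidates))
  sims <- vapply(candidates, function(cand) {
    e <- embed_term(cand, vectors)
    if (is.null(e)) NA_real_ else cosine(t_emb, e)
  }, numeric(1))
  ord <- syn_order(sims, candidates)
  data.frame(target = rep(target, length(candidates)),
             candidate = candidates[ord], sim_plain = unname(sims[ord]),
             rank_plain = seq_along(ord), stringsAsFactors = FALSE)
}

# scored first by score desc (ties lexicographic), then MISSING lexicographic
syn_order <- function(scores, terms) {
  scored <- which(!is.na(scores))
  missing <- which(is.na(scores))
  c(scored[order(-scores[scored], terms[scored])],
    missing[order(terms[missing])])
}

#' Rerank candidates with Rocchio pseudo-relevance feedback
#'
#' The feedback vector is `alpha * embed(target) + beta * mean(embeddings
#' of the top-k scored candidates)`; `sim_prf` is the cosine against it,
#' and candidates are re-sorted under the same tie and missing-value rules
#' as the plain pass. With `beta = 0` the ordering reduces to the plain
#' cosine ranking. When no candidate could be scored the input is returned
#' unchanged (with a warning).
#'
#' @param ranked data.frame from [rank_by_similarity()].
#' @param vectors a `laylink_vectors` matrix.
#' @param k feedback depth (clamped to the number of scored candidates).
#' @param alpha weight of the original target vector.
#' @param beta weight of the feedback centroid.
#' @return `ranked` with `sim_prf` and `rank_prf` columns filled.
#' @export
prf_rerank <- function(ranked, vectors, k = 5L, alpha = 1.0, beta = 0.75) {
  stopifnot(k >= 1L)
  if (!nrow(ranked)) {
    ranked$sim_prf <- numeric(0); ranked$rank_prf <- integer(0)
    return(ranked)
  }
  target <- ranked$target[1]
  t_emb <- embed_term(target, vectors)
  scored <- ranked$candidate[!is.na(ranked$sim_plain)]
  if (!length(scored)) {
    warning("no scored candidates for '", target,
            "'; PRF rerank is a no-op", call. = FALSE)
    ranked$sim_prf <- NA_real_
    ranked$rank_prf <- ranked$rank_plain
    return(ranked)
  }
  top <- scored[seq_len(min(k, length(scored)))]
  centroid <- colMeans(do.call(rbind, lapply(top, embed_term, vectors)))
  feedback <- alpha * t_emb + beta * centroid
  sims <- vapply(ranked$candidate, function(cand) {
    e <- embed_term(cand, vectors)
    if (is.null(e)) NA_real_ else cosine(feedback, e)
  }, numeric(1))
  ord <- syn_order(sims, ranked$candidate)
  out <- ranked[ord, , drop = FALSE]
  out$sim_prf <- unname(sims[ord])
  out$rank_prf <- seq_along(ord)
  rownames(out) <- NULL
  out
}

#' Mine and rank synonyms for one target term
#'
#' Convenience pipeline: candidate extraction from the link graph, plain
#' cosine ranking, PRF reranking.
#'
#' @inheritParams syn_candidates
#' @inheritParams prf_rerank
#' @return data.frame `target`, `candidate`, `sim_plain`, `rank_plain`,
#'   `sim_prf`, `rank_prf`.
#' @export
mine_synonyms <- function(graph, target, vectors, k = 5L, alpha = 1.0,
                          beta = 0.75) {
  cands <- syn_candidates(graph, target)
  if (!length(cands)) {
    return(data.frame(target = character(), candidate = character(),
                      sim_plain = numeric(), rank_plain = integer(),
                      sim_prf = numeric(), rank_prf = integer(),
                      stringsAsFactors = FALSE))
  }
  prf_rerank(rank_by_similarity(target, cands, vectors), vectors,
             k = k, alpha = alpha, beta = beta)
}

#' Mean average precision of a ranking against a truth set
#'
#' @param ranked_terms character vector in rank order.
#' @param truth character vector of relevant terms.
#' @return average precision in \[0, 1\] (`NA` if `truth` is empty).
#' @export
average_precision <- function(ranked_terms, truth) {
  rel <- ranked_terms %in% truth
  if (!any(rel)) return(0)
  if (!length(truth)) return(NA_real_)
  hits <- cumsum(rel)
  sum((hits / seq_along(rel))[rel]) / length(truth)
}
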