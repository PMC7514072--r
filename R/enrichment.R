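# Hypergeometric over-representation of a query gene set against a
# term -> gene annotation (equivalently a one-sided Fisher test), with BH
# correction across tested terms and top-k reporting.

#' Hypergeometric over-representation analysis
#'
#' For each term with between `min_term_size` and `max_term_size` annotated
#' genes, tests whether the query over-represents the term: the p-value is
#' the upper hypergeometric tail `P(X >= k)` for `k` overlap genes given a
#' universe of `N` genes of which `K` carry the term and a query of size `n`.
#' BH correction is applied across all tested terms. The annotation is taken
#' as already propagated (no ontology-graph ancestor inheritance).
#'
#' @param query Character vector of gene ids; members outside the universe
#'   are dropped with a warning.
#' @param annot An [annotation()] object.
#' @param min_term_size,max_term_size Term-size filters defining the BH
#'   family.
#' @return Data frame with columns `term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adjusted`, `fold_enrichment`, sorted by `p_adjusted` then decreasing
#'   fold enrichment then `term_id`. Empty query yields an empty result.
#' @examples
#' ann <- annotation(list(T1 = c("a", "b", "c", "d")),
#'                   universe = letters[1:10])
#' hypergeom_enrich(c("a", "b", "c", "d", "e"), ann)$p_value  # 6/252
#' @export
hypergeom_enrich <- function(query, annot, min_term_size = 3,
                             max_term_size = 500) {
  stopifnot(inherits(annot, "annotation"))
  N <- length(annot$universe)
  if (N == 0) stop("empty universe", call. = FALSE)
  outside <- setdiff(query, annot$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, annot$universe)
  }
  query <- unique(query)
  terms <- annot$terms[vapply(annot$terms, function(g)
    length(g) >= min_term_size && length(g) <= max_term_size, TRUE)]
  if (!length(query) || !length(terms)) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), fold_enrichment = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- length(query)
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, query)), 0L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(terms), k = unname(k), K = unname(K),
                    n = n, N = N, p_value = unname(p),
                    p_adjusted = bh_adjust(unname(p)),
                    fold_enrichment = unname((k / n) / (K / N)),
                    stringsAsFactors = FALSE)
  out[order(out$p_adjusted, -out$fold_enrichment, out$term_id), ,
      drop = FALSE]
}

#' Top enriched terms
#'
#' The `k` rows with the smallest adjusted p-value, ties broken by larger
#' fold enrichment, then lexicographic term id. Fewer rows than `k` are
#' returned as-is.
#'
#' @param rows A [hypergeom_enrich()] result.
#' @param k Positive integer (the study reports the top 25 terms per DEG
#'   set).
#' @return Sorted data frame of at most `k` rows.
#' @export
top_terms <- function(rows, k = 25) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  ord <- order(rows$p_adjusted, -rows$fold_enrichment, rows$term_id)
  rows[ord[seq_len(min(k, nrow(rows)))], , drop = FALSE]
}
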