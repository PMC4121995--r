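#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test per term: with a universe of `N` genes
#' of which `K` carry the term, and a query of `n` genes of which `k`
#' carry it, `p = P(X >= k)`. Terms absent from the query (`k = 0`) are
#' reported with p = 1. Results carry Bonferroni-adjusted p-values over
#' the number of tested terms and are sorted by p then term id.
#'
#' @param query character vector of query gene ids (must be a subset of
#'   the universe).
#' @param term_map data.frame with columns `gene`, `term_id`,
#'   `term_name`.
#' @param universe character vector; defaults to all genes in
#'   `term_map`.
#' @return data.frame: term_id, term_name, k, K, n, N, pvalue,
#'   p_bonferroni.
#' @export
hypergeom_enrich <- function(query, term_map, universe = NULL) {
  if (is.null(universe)) universe <- unique(term_map$gene)
  query <- unique(query)
  off <- setdiff(query, universe)
  if (length(off)) {
    stop("query genes outside the universe: ", paste(off, collapse = ", "))
  }
  bad <- setdiff(unique(term_map$gene), universe)
  if (length(bad)) {
    stop("term map covers genes outside the universe: ",
         paste(bad, collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  terms <- unique(term_map[, c("term_id", "term_name")])
  k <- K <- integer(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    genes <- unique(term_map$gene[term_map$term_id == terms$term_id[i]])
    K[i] <- length(genes)
    k[i] <- length(intersect(genes, query))
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms$term_id,
                    term_name = terms$term_name,
                    k = k, K = K, n = n, N = N, pvalue = p,
                    p_bonferroni = bonferroni(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni correction
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return `pmin(1, pvalues * length(pvalues))`, order preserved.
#' @export
bonferroni <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  pmin(1, pvalues * length(pvalues))
}
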