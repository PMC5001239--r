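#' Upper-tail hypergeometric p-value for set over-representation
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` members of a size-`K` set when sampling `n` genes from a
#' universe of `N`. Computed via the log-space tail of [stats::phyper()].
#'
#' @param k Overlap count.
#' @param K Gene-set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || N < max(K, n)) {
    abort_input("impossible hypergeometric parameters")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, input order preserved. A
#' validated wrapper over [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of a query gene set against every catalog
#' term, BH-adjusted across all terms represented in the universe. The query
#' is silently restricted to the universe (the number of discarded genes is
#' reported as an attribute); duplicate query genes are ignored.
#'
#' @param query Character vector of gene symbols.
#' @param catalog A gene-set catalog from [read_gmt()] or
#'   [geneset_catalog()].
#' @param universe Gene universe; defaults to the catalog's. A sensible
#'   choice is the set of genes surviving expression filtering.
#' @param padj_thresh Terms with `padj` below this are flagged `retained`.
#' @return Data frame (rows with overlap `k >= 1`, sorted by p-value):
#'   `term_id`, `description`, `k`, `K`, `n`, `N`, `pvalue`, `padj`,
#'   `retained`; attribute `n_discarded` counts query genes outside the
#'   universe.
#' @export
enrich <- function(query, catalog, universe = NULL, padj_thresh = 0.05) {
  universe <- unique(universe %||% catalog$universe)
  query <- unique(query)
  q <- intersect(query, universe)
  n_disc <- length(query) - length(q)
  if (length(q) == 0L) abort_input("query has no genes in the universe")

  members <- lapply(catalog$terms, intersect, universe)
  members <- members[vapply(members, length, 1L) > 0L]
  N <- length(universe); n <- length(q)
  k <- vapply(members, function(m) length(intersect(m, q)), 1L)
  K <- vapply(members, length, 1L)
  p <- vapply(seq_along(members), function(i) hypergeom_p(k[i], K[i], n, N),
              1.0)
  padj <- bh_adjust(p)
  out <- data.frame(term_id = names(members),
                    description = catalog$descriptions[names(members)] %||%
                      rep(NA_character_, length(members)),
                    k = k, K = K, n = n, N = N, pvalue = p, padj = padj,
                    retained = padj < padj_thresh,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$k >= 1L, , drop = FALSE]
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_disc
  out
}

#' Construct a gene-set catalog
#'
#' @param terms Named list: term id -> member gene symbols.
#' @param descriptions Optional named character vector of term descriptions.
#' @param universe Gene universe; defaults to the union of all members.
#' @return A `geneset_catalog` list.
#' @export
geneset_catalog <- function(terms, descriptions = NULL, universe = NULL) {
  if (is.null(names(terms)) || anyDuplicated(names(terms))) {
    abort_input("terms must have unique names")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  }
  structure(list(terms = lapply(terms, unique),
                 descriptions = descriptions,
                 universe = unique(universe %||%
                                     unlist(terms, use.names = FALSE))),
            class = "geneset_catalog")
}
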