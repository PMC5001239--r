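#' Counts per million
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param lib.sizes Per-sample library sizes; defaults to column sums.
#' @param norm.factors Per-sample normalization factors (e.g. from
#'   [tmm_norm_factors()]); used only when `normalized = TRUE`.
#' @param normalized Scale by effective library (lib.size x factor)?
#' @return Real matrix of the same shape.
#' @export
cpm <- function(counts, lib.sizes = colSums(counts), norm.factors = NULL,
                normalized = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_input("counts must be non-negative")
  if (any(lib.sizes <= 0)) abort_input("zero or negative library size")
  eff <- lib.sizes
  if (normalized) {
    if (is.null(norm.factors)) abort_config("normalized=TRUE needs norm.factors")
    eff <- lib.sizes * norm.factors
  }
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Remove features with low or no expression
#'
#' Keeps features with CPM strictly above `min.cpm` in at least `min.samples`
#' samples; all-zero features are always removed. By default the rule is
#' applied across the combined sample set; `per.group = TRUE` requires it
#' within each group instead.
#'
#' @inheritParams cpm
#' @param min.cpm CPM threshold (strict).
#' @param min.samples Minimum number of samples above threshold.
#' @param per.group Apply the rule within each group separately?
#' @param groups Two-level factor/character over samples; required when
#'   `per.group = TRUE`.
#' @return The filtered count matrix (rows subset, attributes dropped).
#' @export
filter_low_expression <- function(counts, lib.sizes = colSums(counts),
                                  min.cpm = 1, min.samples = 2,
                                  per.group = FALSE, groups = NULL) {
  x <- cpm(counts, lib.sizes)
  if (per.group) {
    if (is.null(groups)) abort_config("per.group filtering needs groups")
    keep <- rep(TRUE, nrow(x))
    for (g in unique(groups)) {
      keep <- keep & rowSums(x[, groups == g, drop = FALSE] > min.cpm) >=
        min.samples
    }
  } else {
    keep <- rowSums(x > min.cpm) >= min.samples
  }
  keep <- keep & rowSums(counts) > 0
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes one scaling factor per sample from the trimmed mean of
#' log2 expression ratios (M-values) against a reference sample, after
#' removing features with a zero in either sample and trimming 30% of the
#' M distribution and 5% of the A (mean-abundance) distribution at each end.
#' Factors are rescaled so their geometric mean is 1. A sample sharing no
#' nonzero feature with the reference gets factor 1 with a warning.
#'
#' @inheritParams cpm
#' @param ref Reference column (index or name); by default the sample whose
#'   upper-quartile CPM is closest to the mean upper quartile.
#' @param trim.M,trim.A Two-sided trim fractions for M and A.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_norm_factors <- function(counts, lib.sizes = colSums(counts), ref = NULL,
                             trim.M = 0.3, trim.A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) abort_input("TMM needs at least two samples")
  if (any(lib.sizes <= 0)) abort_input("zero library size")
  p <- sweep(counts, 2L, lib.sizes, "/")
  if (is.null(ref)) {
    uq <- apply(p, 2L, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  }
  pr <- p[, ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    pj <- p[, j]
    ok <- pj > 0 & pr > 0
    if (!any(ok)) {
      warning("sample ", j, " shares no nonzero feature with reference; ",
              "factor set to 1")
      return(1)
    }
    M <- log2(pj[ok] / pr[ok])
    A <- 0.5 * log2(pj[ok] * pr[ok])
    keepM <- M >= stats::quantile(M, trim.M) & M <= stats::quantile(M, 1 - trim.M)
    keepA <- A >= stats::quantile(A, trim.A) & A <= stats::quantile(A, 1 - trim.A)
    keep <- keepM & keepA
    if (!any(keep)) return(1)
    2^mean(M[keep])
  }, 1.0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

## Pseudo-counts equalized to the geometric-mean effective library:
## y_ij' = round(y_ij * L_geo / L_j), banker's rounding (base round()).
equalize_counts <- function(counts, lib.sizes, norm.factors = NULL) {
  eff <- lib.sizes * (norm.factors %||% rep(1, length(lib.sizes)))
  lgeo <- exp(mean(log(eff)))
  round(sweep(as.matrix(counts), 2L, lgeo / eff, "*"))
}

## Conditional log-likelihood of a feature-by-sample block of equal-mean NB
## counts given their sum (Dirichlet-multinomial); summed over features and
## groups. phi = 0 is the multinomial limit.
cond_loglik <- function(pseudo, groups, phi) {
  ll <- 0
  for (g in unique(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    if (phi < 1e-10) {
      ll <- ll + sum(lgamma(z + 1) - rowSums(lgamma(y + 1)) - z * log(n))
    } else {
      r <- 1 / phi
      ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r) +
                       lgamma(z + 1) - rowSums(lgamma(y + 1)))
    }
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional NB log-likelihood (given per-feature group
#' totals) over a single dispersion shared by all features, on pseudo-counts
#' equalized to the geometric-mean effective library. The search runs on
#' \[0, 10\] to tolerance 1e-6, with an explicit boundary check at 0.
#'
#' @inheritParams cpm
#' @param groups Two-level factor/character over samples.
#' @param norm.factors Optional per-sample normalization factors.
#' @return Estimated dispersion (phi >= 0).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       lib.sizes = colSums(counts),
                                       norm.factors = NULL) {
  counts <- as.matrix(counts)
  if (length(unique(groups)) != 2L) abort_input("groups must have two levels")
  if (all(counts == 0)) {
    warning("all-zero matrix; dispersion set to 0")
    return(0)
  }
  pseudo <- equalize_counts(counts, lib.sizes, norm.factors)
  f <- function(phi) cond_loglik(pseudo, groups, phi)
  opt <- stats::optimize(f, c(0, 10), maximum = TRUE, tol = 1e-6)
  if (f(0) >= opt$objective) 0 else opt$maximum
}

## Two-sided conditional NB exact p-value for group pseudo-sums a (n1
## samples) vs b (n2 samples) with common dispersion phi, equal effective
## libraries. Two-sided by probability ordering ("smallp") or by doubling
## the smaller tail.
exact_nb_pvalue <- function(a, b, n1, n2, phi, two.sided = c("smallp",
                                                             "doubling")) {
  two.sided <- match.arg(two.sided)
  t <- a + b
  if (t == 0) return(1)
  x <- 0:t
  if (phi < 1e-10) {
    lp <- stats::dbinom(x, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- 1 / phi
    lp <- stats::dnbinom(x, size = n1 * r, mu = n1, log = TRUE) +
      stats::dnbinom(t - x, size = n2 * r, mu = n2, log = TRUE)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  if (two.sided == "smallp") {
    sel <- lp <= lp[a + 1L] + 1e-12
    min(1, sum(exp(lp[sel])))
  } else {
    cum <- cumsum(exp(lp))
    lower <- cum[a + 1L]
    upper <- 1 - if (a == 0) 0 else cum[a]
    min(1, 2 * min(lower, upper))
  }
}

#' Exact negative-binomial differential-expression test
#'
#' Per-feature two-sided conditional exact test of case vs control counts
#' under a common-dispersion NB model, after equalizing effective libraries
#' by mean-scaling to the geometric-mean library. The two-sided p-value
#' aggregates outcomes by probability ordering (all group splits whose
#' conditional probability does not exceed the observed one); a
#' tail-doubling variant is available. Log2 fold changes are computed on
#' group mean CPM with a prior count (in CPM units) to damp zeros.
#'
#' @inheritParams estimate_common_dispersion
#' @param cases,controls Sample ids (must be columns of `counts`).
#' @param dispersion Common NB dispersion phi >= 0 (e.g. from
#'   [estimate_common_dispersion()]).
#' @param prior.cpm Prior count in CPM units added to both group means for
#'   the fold change (default 0.5; set 0 for the raw ratio).
#' @param two.sided `"smallp"` (probability ordering, default) or
#'   `"doubling"`.
#' @return A `de_table` data frame: `feature`, `log2fc` (case over control),
#'   `pvalue`, `padj` (Benjamini-Hochberg), `mean_cpm`; the dispersion and
#'   normalization factors are attached as attributes.
#' @export
exact_test <- function(counts, cases, controls, dispersion,
                       lib.sizes = colSums(counts), norm.factors = NULL,
                       prior.cpm = 0.5, two.sided = "smallp") {
  counts <- as.matrix(counts)
  if (length(cases) == 0L || length(controls) == 0L) {
    abort_input("both groups must be non-empty")
  }
  miss <- setdiff(c(cases, controls), colnames(counts))
  if (length(miss)) abort_input("samples absent from count matrix: ",
                                paste(miss, collapse = ", "))
  if (dispersion < 0) abort_config("dispersion must be >= 0")
  sel <- c(cases, controls)
  idx <- match(sel, colnames(counts))
  counts <- counts[, idx, drop = FALSE]
  lib.sizes <- lib.sizes[idx]
  nf <- if (is.null(norm.factors)) rep(1, length(idx)) else norm.factors[idx]
  groups <- c(rep("case", length(cases)), rep("control", length(controls)))

  pseudo <- equalize_counts(counts, lib.sizes, nf)
  a <- rowSums(pseudo[, groups == "case", drop = FALSE])
  b <- rowSums(pseudo[, groups == "control", drop = FALSE])
  n1 <- length(cases); n2 <- length(controls)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_nb_pvalue(a[i], b[i], n1, n2, dispersion, two.sided)
  }, 1.0)

  x <- cpm(counts, lib.sizes, nf, normalized = !is.null(norm.factors))
  mc <- rowMeans(x[, groups == "case", drop = FALSE])
  mn <- rowMeans(x[, groups == "control", drop = FALSE])
  log2fc <- log2((mc + prior.cpm) / (mn + prior.cpm))

  out <- data.frame(feature = rownames(counts) %||%
                      as.character(seq_len(nrow(counts))),
                    log2fc = log2fc, pvalue = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    mean_cpm = rowMeans(x), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  attr(out, "norm.factors") <- norm.factors
  class(out) <- c("de_table", class(out))
  out
}

#' Call differentially expressed features
#'
#' Strict thresholds on the raw p-value and |log2FC|, following the
#' published convention (adjusted p-values are carried in the table for
#' inspection but calls use raw p).
#'
#' @param table A [exact_test()] result.
#' @param lfc |log2FC| threshold (strict).
#' @param p Raw p-value threshold (strict).
#' @return List with `up` and `down` feature-id character vectors.
#' @export
call_de <- function(table, lfc = 1, p = 0.05) {
  stopifnot(is.data.frame(table))
  up <- table$feature[table$log2fc > lfc & table$pvalue < p]
  down <- table$feature[table$log2fc < -lfc & table$pvalue < p]
  list(up = up, down = down)
}

#' Annotate transcription factors among DE calls
#'
#' Case-sensitive symbol intersection with a transcription-factor catalog.
#'
#' @param up,down Character vectors of up-/down-regulated gene symbols.
#' @param tf_list Character vector of transcription-factor symbols.
#' @return List with `tf_up` and `tf_down`.
#' @export
annotate_tfs <- function(up, down, tf_list) {
  if (length(tf_list) == 0L) abort_input("tf_list is empty")
  list(tf_up = intersect(up, tf_list), tf_down = intersect(down, tf_list))
}
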