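#' Filter methylation probes by annotation
#'
#' Removes sex-chromosome probes, probes with a SNP within five base pairs
#' of the CpG, and probes with no reference gene, preserving probe order.
#' Every probe in the matrix must be annotated.
#'
#' @param beta Probe x sample matrix of beta-values in \[0, 1\].
#' @param anno Data frame with columns `probe_id`, `chrom`, `pos`,
#'   `gene_symbol` (`NA` or `""` when none; multiple genes separated by
#'   `";"`), `region`, `snp_within_5bp` (logical).
#' @return The filtered beta matrix.
#' @export
filter_probes <- function(beta, anno) {
  beta <- as.matrix(beta)
  miss <- setdiff(rownames(beta), anno$probe_id)
  if (length(miss)) {
    abort_input("probes missing from annotation: ",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  a <- anno[match(rownames(beta), anno$probe_id), ]
  sex <- a$chrom %in% c("chrX", "chrY", "X", "Y")
  nogene <- is.na(a$gene_symbol) | !nzchar(trimws(a$gene_symbol))
  keep <- !sex & !a$snp_within_5bp & !nogene
  beta[keep, , drop = FALSE]
}

#' Per-probe beta-difference (case mean minus control mean)
#'
#' Pairwise-complete means; probes with fewer than two observed values in
#' either group are dropped with a warning.
#'
#' @inheritParams filter_probes
#' @param cases,controls Sample ids (columns of `beta`).
#' @return Named numeric vector of beta-differences in \[-1, 1\].
#' @export
beta_difference <- function(beta, cases, controls) {
  beta <- as.matrix(beta)
  if (length(cases) == 0L || length(controls) == 0L) {
    abort_input("both groups must be non-empty")
  }
  bc <- beta[, cases, drop = FALSE]
  bn <- beta[, controls, drop = FALSE]
  nobs_c <- rowSums(!is.na(bc)); nobs_n <- rowSums(!is.na(bn))
  bad <- nobs_c < 2L | nobs_n < 2L
  if (any(bad)) {
    warning(sum(bad), " probe(s) with <2 observations per group excluded")
  }
  d <- rowMeans(bc, na.rm = TRUE) - rowMeans(bn, na.rm = TRUE)
  d[!bad]
}

## d and pooled SE for every probe, given a 0/1 case indicator over columns.
sam_d_core <- function(beta, is_case, s0 = NULL) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  xc <- beta[, is_case, drop = FALSE]
  xn <- beta[, !is_case, drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xn)
  ss <- rowSums((xc - m1)^2) + rowSums((xn - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (is.null(s0)) {
    s0 <- stats::median(s)
    if (s0 <= 0) {
      warning("all pooled SEs are zero; s0 set to machine-epsilon fallback")
      s0 <- sqrt(.Machine$double.eps)
    }
  }
  list(d = (m1 - m2) / (s + s0), s = s, s0 = s0)
}

#' SAM-style moderated two-class statistic
#'
#' For each probe, `d = (mean_case - mean_control) / (s + s0)` where `s` is
#' the pooled standard error of the mean difference and `s0` a small
#' exchangeability constant damping probes with tiny variance. `s0` defaults
#' to the median of all per-probe `s` values.
#'
#' @inheritParams beta_difference
#' @param s0 Optional exchangeability constant; estimated when `NULL`.
#' @return List with per-probe `d`, per-probe `s`, and the `s0` used.
#' @export
sam_statistic <- function(beta, cases, controls, s0 = NULL) {
  beta <- as.matrix(beta)
  if (length(cases) < 2L || length(controls) < 2L) {
    abort_input("SAM statistic needs >=2 samples per group")
  }
  b <- beta[, c(cases, controls), drop = FALSE]
  sam_d_core(b, c(rep(TRUE, length(cases)), rep(FALSE, length(controls))), s0)
}

#' Permutation p-values for the SAM statistic
#'
#' Group labels are permuted jointly across probes; `s0` is recomputed in
#' every permutation. Two-sided p-values are
#' `(1 + #{|d*| >= |d_obs|}) / (1 + n_perm)` for sampled permutations; when
#' the number of distinct label assignments is at most `n_perm` the full
#' enumeration is used and the +1 correction dropped.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for sampled permutations.
#' @return List with per-probe `pvalue`, observed `d`, `s0`, the number of
#'   permutations used and whether they were exhaustive.
#' @export
permutation_pvalues <- function(beta, cases, controls, n_perm = 1000,
                                seed = NULL) {
  if (n_perm < 1) abort_config("n_perm must be >= 1")
  beta <- as.matrix(beta)
  b <- beta[, c(cases, controls), drop = FALSE]
  n1 <- length(cases); n <- n1 + length(controls)
  obs <- sam_d_core(b, seq_len(n) <= n1)
  abs_obs <- abs(obs$d)

  n_assign <- choose(n, n1)
  exhaustive <- is.finite(n_assign) && n_assign <= n_perm
  count <- numeric(nrow(b))
  if (exhaustive) {
    combos <- utils::combn(n, n1)
    for (j in seq_len(ncol(combos))) {
      is_case <- seq_len(n) %in% combos[, j]
      dstar <- sam_d_core(b, is_case)$d
      count <- count + (abs(dstar) >= abs_obs)
    }
    p <- count / ncol(combos)
  } else {
    with_seed(seed, {
      for (j in seq_len(n_perm)) {
        is_case <- seq_len(n) %in% sample.int(n, n1)
        dstar <- sam_d_core(b, is_case)$d
        count <- count + (abs(dstar) >= abs_obs)
      }
    })
    p <- (1 + count) / (1 + n_perm)
  }
  list(pvalue = stats::setNames(p, rownames(b)), d = obs$d, s0 = obs$s0,
       n_perm = if (exhaustive) n_assign else n_perm, exhaustive = exhaustive)
}

#' Call differentially methylated probes and genes
#'
#' Strict thresholds on |beta-difference| and p-value; gene-level sets are
#' the union of gene symbols of called probes (a gene is hyper-methylated if
#' at least one of its probes is), with multi-gene annotations split on
#' `";"`.
#'
#' @param beta_diff Named per-probe beta-differences ([beta_difference()]).
#' @param pvalue Named per-probe p-values ([permutation_pvalues()]).
#' @param anno Probe annotation (see [filter_probes()]).
#' @param delta |beta-difference| threshold (strict).
#' @param p P-value threshold (strict).
#' @return List with `hyper_probes`, `hypo_probes`, `hyper_genes`,
#'   `hypo_genes`.
#' @export
call_dm <- function(beta_diff, pvalue, anno, delta = 0.15, p = 0.01) {
  probes <- intersect(names(beta_diff), names(pvalue))
  bd <- beta_diff[probes]; pv <- pvalue[probes]
  hyper <- probes[bd > delta & pv < p]
  hypo <- probes[bd < -delta & pv < p]
  genes_of <- function(pr) {
    g <- anno$gene_symbol[match(pr, anno$probe_id)]
    g <- g[!is.na(g) & nzchar(g)]
    unique(trimws(unlist(strsplit(g, ";", fixed = TRUE))))
  }
  list(hyper_probes = hyper, hypo_probes = hypo,
       hyper_genes = genes_of(hyper), hypo_genes = genes_of(hypo))
}

#' Compare genomic-region distributions of hyper vs hypo probes
#'
#' For each region label, a two-proportion z-test (pooled variance, no
#' continuity correction) of region membership between the hyper- and
#' hypo-methylated probe sets, Benjamini-Hochberg adjusted across regions.
#'
#' @param hyper,hypo Probe-id character vectors (both non-empty).
#' @param anno Probe annotation with a `region` column.
#' @return Data frame: `region`, `prop_hyper`, `prop_hypo`, `z`, `pvalue`,
#'   `padj`.
#' @export
region_distribution_test <- function(hyper, hypo, anno) {
  if (length(hyper) == 0L || length(hypo) == 0L) {
    abort_input("both probe sets must be non-empty")
  }
  r1 <- anno$region[match(hyper, anno$probe_id)]
  r2 <- anno$region[match(hypo, anno$probe_id)]
  regions <- sort(unique(c(r1, r2)))
  n1 <- length(hyper); n2 <- length(hypo)
  rows <- lapply(regions, function(rg) {
    k1 <- sum(r1 == rg); k2 <- sum(r2 == rg)
    p1 <- k1 / n1; p2 <- k2 / n2
    pool <- (k1 + k2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    data.frame(region = rg, prop_hyper = p1, prop_hypo = p2, z = z,
               pvalue = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out
}
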