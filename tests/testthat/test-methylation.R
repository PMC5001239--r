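make_anno <- function(probes, chrom = "chr1", gene = "G1", snp = FALSE,
                      region = "Body") {
  data.frame(probe_id = probes,
             chrom = rep_len(chrom, length(probes)),
             pos = seq_along(probes),
             gene_symbol = rep_len(gene, length(probes)),
             region = rep_len(region, length(probes)),
             snp_within_5bp = rep_len(snp, length(probes)),
             stringsAsFactors = FALSE)
}

test_that("probe filter removes sex, SNP-adjacent and gene-less probes", {
  probes <- paste0("cg", 1:6)
  anno <- make_anno(probes)
  anno$chrom[1] <- "chrX"
  anno$snp_within_5bp[2] <- TRUE
  anno$gene_symbol[3] <- ""
  beta <- matrix(0.5, 6, 4, dimnames = list(probes, paste0("s", 1:4)))
  kept <- filter_probes(beta, anno)
  expect_identical(rownames(kept), paste0("cg", 4:6))
  expect_error(filter_probes(rbind(beta, cgX = rep(0.5, 4)), anno),
               class = "stratomics_input_error")
})

test_that("beta-difference is the case-minus-control mean", {
  beta <- rbind(p1 = c(0.2, 0.4, 0.6, 0.8),
                p2 = c(0.5, 0.5, 0.5, 0.5))
  colnames(beta) <- c("c1", "c2", "n1", "n2")
  d <- beta_difference(beta, c("c1", "c2"), c("n1", "n2"))
  expect_equal(unname(d["p1"]), -0.4)
  expect_equal(unname(d["p2"]), 0)
  beta["p1", "c2"] <- NA   # one observation left in cases: excluded
  expect_warning(d2 <- beta_difference(beta, c("c1", "c2"), c("n1", "n2")),
                 "excluded")
  expect_false("p1" %in% names(d2))
})

test_that("SAM statistic matches its definition, including pinned s0", {
  beta <- rbind(p1 = c(1, 1, 0, 0),
                p2 = c(0.8, 0.6, 0.5, 0.6))
  colnames(beta) <- c("c1", "c2", "n1", "n2")
  r <- sam_statistic(beta, c("c1", "c2"), c("n1", "n2"), s0 = 0.5)
  # p1: zero within-group variance -> d = mean diff / s0 = 1 / 0.5
  expect_equal(unname(r$d["p1"]), 2)
  expect_equal(unname(r$d["p2"]),
               sam_d_oracle(c(0.8, 0.6), c(0.5, 0.6), 0.5))
  # doubling the mean difference doubles d at fixed s, s0
  beta2 <- beta
  beta2["p1", c("c1", "c2")] <- 2
  r2 <- sam_statistic(beta2, c("c1", "c2"), c("n1", "n2"), s0 = 0.5)
  expect_equal(unname(r2$d["p1"]), 4)
  # identical group means -> d = 0
  beta3 <- rbind(p1 = c(0.3, 0.7, 0.7, 0.3), p2 = c(0.8, 0.6, 0.5, 0.6))
  colnames(beta3) <- c("c1", "c2", "n1", "n2")
  r3 <- sam_statistic(beta3, c("c1", "c2"), c("n1", "n2"), s0 = 0.5)
  expect_equal(unname(r3$d["p1"]), 0)
})

test_that("permutation p-values are exact under full enumeration", {
  m <- rbind(p1 = c(1, 1, 0, 0), p2 = c(0.2, 0.8, 0.5, 0.5))
  colnames(m) <- c("a", "b", "c", "d")
  r <- permutation_pvalues(m, c("a", "b"), c("c", "d"), n_perm = 50)
  expect_true(r$exhaustive)
  expect_equal(unname(r$pvalue["p1"]), 2 / 6)
  # constant probe: every permutation ties the observed d = 0
  m2 <- rbind(p1 = rep(0.4, 6), p2 = c(1, 1, 1, 0, 0, 0))
  colnames(m2) <- paste0("s", 1:6)
  # both probes have zero pooled SE here, so s0 falls back with a warning
  # (re-raised in every enumerated permutation, hence suppressed around)
  expect_warning(sam_statistic(m2, paste0("s", 1:3), paste0("s", 4:6)),
                 "machine-epsilon")
  r2 <- suppressWarnings(
    permutation_pvalues(m2, paste0("s", 1:3), paste0("s", 4:6),
                        n_perm = 100))
  expect_equal(unname(r2$pvalue["p1"]), 1)
  expect_error(permutation_pvalues(m, c("a", "b"), c("c", "d"), n_perm = 0),
               class = "stratomics_config_error")
})

test_that("enumerated p equals brute-force enumeration on random matrices", {
  set.seed(12)
  for (i in 1:5) {
    n1 <- sample(2:3, 1); n2 <- sample(2:3, 1)
    m <- matrix(runif(8 * (n1 + n2)), 8,
                dimnames = list(paste0("p", 1:8),
                                paste0("s", 1:(n1 + n2))))
    cases <- paste0("s", 1:n1); ctrls <- paste0("s", n1 + 1:n2)
    r <- permutation_pvalues(m, cases, ctrls, n_perm = 1000)
    expect_true(r$exhaustive)
    # brute force: all label assignments via combn, s0 refit each time
    combos <- combn(n1 + n2, n1)
    absd <- sapply(seq_len(ncol(combos)), function(j) {
      idx <- combos[, j]
      st <- sam_statistic(m, colnames(m)[idx], colnames(m)[-idx])
      abs(st$d)
    })
    obs <- abs(sam_statistic(m, cases, ctrls)$d)
    pref <- rowMeans(absd >= obs)
    expect_equal(unname(r$pvalue), unname(pref))
  }
})

test_that("DM calls are strict and symmetric, with gene-level union", {
  probes <- paste0("cg", 1:4)
  anno <- make_anno(probes, gene = c("A", "A", "B;C", "D"))
  bd <- c(cg1 = 0.2, cg2 = 0.16, cg3 = -0.3, cg4 = 0.15)
  pv <- c(cg1 = 0.005, cg2 = 0.005, cg3 = 0.001, cg4 = 0.0001)
  dm <- call_dm(bd, pv, anno)
  expect_setequal(dm$hyper_probes, c("cg1", "cg2"))
  expect_identical(dm$hypo_probes, "cg3")          # cg4 at boundary: ns
  expect_identical(dm$hyper_genes, "A")            # two probes, one gene
  expect_setequal(dm$hypo_genes, c("B", "C"))      # multi-gene split
  flip <- call_dm(-bd, pv, anno)
  expect_setequal(flip$hyper_probes, dm$hypo_probes)
  expect_setequal(flip$hypo_probes, dm$hyper_probes)
  expect_lte(length(dm$hyper_genes), length(dm$hyper_probes))
})

test_that("region distribution test flags divergent regions", {
  hyper <- paste0("h", 1:50); hypo <- paste0("l", 1:50)
  anno <- rbind(make_anno(hyper, region = "Body"),
                make_anno(hypo, region = "IGR"))
  r <- region_distribution_test(hyper, hypo, anno)
  expect_lt(r$pvalue[r$region == "Body"], 0.001)
  expect_equal(sum(r$prop_hyper), 1)
  expect_equal(sum(r$prop_hypo), 1)
  # identical distributions: z = 0, p = 1
  anno2 <- rbind(make_anno(hyper, region = "Body"),
                 make_anno(hypo, region = "Body"))
  r2 <- region_distribution_test(hyper, hypo, anno2)
  expect_equal(r2$z, 0)
  expect_equal(r2$pvalue, 1)
  expect_error(region_distribution_test(character(0), hypo, anno),
               class = "stratomics_input_error")
})
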