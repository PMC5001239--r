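test_that("simulation is deterministic given the seed", {
  b1 <- simulate_multiomics(small_config())
  b2 <- simulate_multiomics(small_config())
  expect_identical(b1$mutations, b2$mutations)
  expect_identical(b1$mrna, b2$mrna)
  expect_identical(b1$beta, b2$beta)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_multiomics(small_config(seed = 8))
  expect_false(identical(b1$mrna, b3$mrna))
})

test_that("cohort generator honors the stratification contract", {
  cfg <- small_config()
  b <- simulate_cohort(cfg)
  co <- stratify(b$mutations, cohort_design(), samples = b$samples)
  expect_setequal(co$case_ids, b$truth$case_ids)
  expect_setequal(co$control_ids, b$truth$control_ids)
  expect_setequal(names(co$excluded), b$truth$other_ids)
  # every case carries a truncating target variant
  for (s in b$truth$case_ids) {
    rows <- b$mutations[b$mutations$sample_id == s, ]
    expect_true(any(is_truncating(rows$gene_symbol, rows$variant_class,
                                  cohort_design())))
  }
  # no control carries target- or exclusion-gene variants
  ctrl_rows <- b$mutations[b$mutations$sample_id %in% b$truth$control_ids, ]
  expect_false(any(ctrl_rows$gene_symbol %in%
                     c("PBRM1", "VHL", "BAP1", "SETD2", "PTEN", "KDM5C")))
})

test_that("truth bookkeeping is consistent across layers", {
  cfg <- small_config()
  b <- simulate_multiomics(cfg)
  t <- b$truth
  expect_length(intersect(t$de_genes_up, t$de_genes_down), 0)
  expect_equal(length(t$de_genes_up) + length(t$de_genes_down),
               cfg$n_de_genes)
  expect_equal(length(t$dm_probes_hyper) + length(t$dm_probes_hypo),
               cfg$n_dm_probes)
  expect_equal(length(t$de_mirnas_up) + length(t$de_mirnas_down),
               cfg$n_de_mirnas)
  expect_true(all(c(t$de_genes_up, t$de_genes_down) %in% rownames(b$mrna)))
  expect_true(all(c(t$dm_probes_hyper, t$dm_probes_hypo) %in%
                    rownames(b$beta)))
  expect_true(all(unlist(b$target_map) %in% rownames(b$mrna)))
  expect_true(all(b$ppi$gene_a != b$ppi$gene_b))
  expect_false(any(duplicated(
    stratomics:::pair_key(b$ppi$gene_a, b$ppi$gene_b))))
  # planted probes always survive the probe filter
  kept <- rownames(filter_probes(b$beta, b$anno))
  expect_true(all(c(t$dm_probes_hyper, t$dm_probes_hypo) %in% kept))
  # SNP-flagged probes never survive it
  flagged <- b$anno$probe_id[b$anno$snp_within_5bp]
  expect_length(intersect(kept, flagged), 0)
})

test_that("planted count effects match their nominal size at large n", {
  cfg <- sim_config(n_case = 500, n_control = 500, n_other = 0,
                    n_genes = 300, n_de_genes = 30, n_probes = 10,
                    n_mirnas = 10, n_de_mirnas = 0, n_dm_probes = 0,
                    nb_dispersion = 0.1, module_cor_sd = 0, seed = 5)
  b <- simulate_cohort(cfg)
  counts <- simulate_counts(cfg, b$truth, "mRNA")
  x <- cpm(counts)
  is_case <- colnames(counts) %in% b$truth$case_ids
  ratio <- log2(rowMeans(x[, is_case]) / rowMeans(x[, !is_case]))
  for (g in b$truth$de_genes_up) {
    expect_equal(unname(ratio[g]), 2, tolerance = 0.1 / 2)
  }
  null_genes <- setdiff(rownames(counts),
                        names(b$truth$gene_log2fc))
  expect_lt(max(abs(ratio[null_genes])), 0.35)
})

test_that("library sizes set the expected column totals", {
  cfg <- sim_config(n_case = 5, n_control = 5, n_other = 0, n_genes = 500,
                    n_de_genes = 0, n_dm_probes = 0, n_de_mirnas = 0,
                    n_probes = 10, n_mirnas = 10, module_cor_sd = 0,
                    nb_dispersion = 0,  # Poisson: mean identity, tight MC noise
                    lib_size_range = c(1e6, 1e6), seed = 2)
  b <- simulate_cohort(cfg)
  counts <- simulate_counts(cfg, b$truth, "mRNA")
  expect_true(all(abs(colSums(counts) - 1e6) / 1e6 < 0.05))
})

test_that("planted beta shifts match their nominal size at large n", {
  cfg <- sim_config(n_case = 500, n_control = 500, n_other = 0,
                    n_genes = 50, n_probes = 200, n_dm_probes = 20,
                    n_de_genes = 0, n_de_mirnas = 0, n_mirnas = 10,
                    delta_beta = 0.3, beta_precision = 50, seed = 6)
  b <- simulate_cohort(cfg)
  meth <- simulate_beta(cfg, b$truth)
  expect_true(all(meth$beta >= 0 & meth$beta <= 1))
  d <- beta_difference(meth$beta, b$truth$case_ids, b$truth$control_ids)
  for (p in b$truth$dm_probes_hyper) {
    expect_equal(unname(d[p]), 0.3, tolerance = 0.02 / 0.3)
  }
  for (p in b$truth$dm_probes_hypo) {
    expect_equal(unname(d[p]), -0.3, tolerance = 0.02 / 0.3)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_case = -1), class = "stratomics_config_error")
  expect_error(sim_config(n_de_genes = 10, n_genes = 5),
               class = "stratomics_config_error")
  expect_error(sim_config(nb_dispersion = -0.1),
               class = "stratomics_config_error")
  expect_error(sim_config(lib_size_range = c(2e6, 1e6)),
               class = "stratomics_config_error")
})
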