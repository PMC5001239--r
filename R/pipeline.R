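#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end analysis. All
#' thresholds default to the published cutoffs: |log2FC| > 1 with p < 0.05
#' for expression layers, |beta-difference| > 0.15 with p < 0.01 for
#' methylation, adjusted p < 0.05 for enrichment, top 5% correlations and a
#' display degree filter of 3 for the networks.
#'
#' @param maf,samples,mrna,mirna,beta,anno,targets,gmt,ppi,tfs Input file
#'   paths (`samples`, a one-id-per-line roster, may be `NULL`).
#' @param outdir Output directory for serialized intermediates.
#' @param design A [cohort_design()].
#' @param lfc,p_de DE thresholds.
#' @param delta_beta,p_dm,n_perm Methylation thresholds and permutation
#'   count.
#' @param padj_enrich Enrichment retention threshold.
#' @param top_fraction,cor_mode,min_degree Network parameters.
#' @param min_cpm,min_samples Expression-filter parameters.
#' @param prior_cpm Fold-change prior in CPM units.
#' @param seed Seed for the stochastic stages (permutations).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(maf, mrna, mirna, beta, anno, targets, gmt, ppi,
                            tfs, outdir, samples = NULL,
                            design = cohort_design(),
                            lfc = 1, p_de = 0.05,
                            delta_beta = 0.15, p_dm = 0.01, n_perm = 1000,
                            padj_enrich = 0.05,
                            top_fraction = 0.05, cor_mode = "absolute",
                            min_degree = 3,
                            min_cpm = 1, min_samples = 2, prior_cpm = 0.5,
                            seed = 1) {
  cfg <- as.list(environment())
  if (n_perm < 1) abort_config("n_perm must be >= 1")
  if (top_fraction <= 0 || top_fraction > 1) {
    abort_config("top_fraction must lie in (0, 1]")
  }
  for (th in c("lfc", "p_de", "delta_beta", "p_dm", "padj_enrich")) {
    if (cfg[[th]] < 0) abort_config(th, " must be >= 0")
  }
  structure(cfg, class = "pipeline_config")
}

## Stable hash of the configuration (md5 of its canonical JSON), recorded
## in the report and in every serialized output header.
config_hash <- function(config) {
  plain <- lapply(unclass(config), function(x) {
    if (inherits(x, "cohort_design")) unclass(x) else x
  })
  js <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                         null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Run the full stratified multi-omics pipeline
#'
#' Executes, in order: cohort stratification (with driver-gene exclusion and
#' the matched-omics restriction), mRNA differential expression (filter,
#' TMM, common dispersion, exact test, calls, TF annotation), differential
#' methylation (probe filter, beta-difference, SAM statistic with
#' permutation p-values, calls, region comparison), miRNA differential
#' expression, miRNA-target integration with hyper-down genes, gene-set
#' enrichment of every result family, and the co-expression networks
#' (background = top-fraction case-group correlations intersected with the
#' PPI; up-regulated subnetwork; down-regulated core around the hyper-down
#' seeds; degree display filter). All intermediates are serialized under
#' `config$outdir` with the configuration hash in their header.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list of per-stage counts and provenance, also
#'   written as `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(x) file.path(config$outdir, x)
  stage <- "input"
  report <- list(config_hash = hash,
                 thresholds = unclass(config)[c(
                   "lfc", "p_de", "delta_beta", "p_dm", "n_perm",
                   "padj_enrich", "top_fraction", "cor_mode", "min_degree",
                   "min_cpm", "min_samples", "prior_cpm", "seed")])
  fail <- function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               out("FAILED"))
    stop(errorCondition(paste0("pipeline failed at stage '", stage, "': ",
                               conditionMessage(e)),
                        class = setdiff(class(e), c("error", "condition"))))
  }
  tryCatch({
    maf <- read_maf(config$maf)
    roster <- if (is.null(config$samples)) NULL else
      readLines(config$samples)
    mrna <- read_matrix(config$mrna, integer = TRUE)
    mirna <- read_matrix(config$mirna, integer = TRUE)
    beta <- read_matrix(config$beta)
    anno <- read_tsv_checked(config$anno,
                             required = c("probe_id", "chrom", "pos",
                                          "gene_symbol", "region",
                                          "snp_within_5bp"),
                             numeric_cols = "pos")
    anno$snp_within_5bp <- as.logical(anno$snp_within_5bp)
    target_map <- read_target_map(config$targets)
    catalog <- read_gmt(config$gmt)
    ppi <- read_ppi(config$ppi)
    tfs <- readLines(config$tfs)

    ## --- stratification -------------------------------------------------
    stage <- "stratify"
    cohort <- stratify(maf, config$design, samples = roster)
    cohort <- require_matched_omics(cohort,
                                    list(rna = colnames(mrna),
                                         meth = colnames(beta),
                                         mirna = colnames(mirna)))
    if (length(cohort$case_ids) == 0L) {
      abort_input("stratification produced an empty case group")
    }
    if (length(cohort$control_ids) == 0L) {
      abort_input("stratification produced an empty control group")
    }
    cases <- cohort$case_ids; controls <- cohort$control_ids
    report$cohort <- list(n_cases = length(cases),
                          n_controls = length(controls),
                          n_excluded = length(cohort$excluded))
    writeLines(c(paste0("# config: ", hash), cases), out("case_ids.txt"))
    writeLines(c(paste0("# config: ", hash), controls),
               out("control_ids.txt"))

    ## --- mRNA differential expression -----------------------------------
    stage <- "mrna_de"
    use <- c(cases, controls)
    mrna_u <- mrna[, use, drop = FALSE]
    mrna_f <- filter_low_expression(mrna_u, min.cpm = config$min_cpm,
                                    min.samples = config$min_samples)
    libs <- colSums(mrna_u)[use]
    nf <- tmm_norm_factors(mrna_f, libs)
    groups <- ifelse(use %in% cases, "case", "control")
    phi <- estimate_common_dispersion(mrna_f, groups, libs, nf)
    de <- exact_test(mrna_f, cases, controls, phi, libs, nf,
                     prior.cpm = config$prior_cpm)
    calls <- call_de(de, config$lfc, config$p_de)
    tf_ann <- annotate_tfs(calls$up, calls$down, tfs)
    write_tsv(de, out("mrna_de.tsv"), paste("config:", hash))
    report$mrna <- list(n_input = nrow(mrna), n_filtered = nrow(mrna_f),
                        dispersion = phi,
                        n_up = length(calls$up), n_down = length(calls$down),
                        n_tf_up = length(tf_ann$tf_up),
                        n_tf_down = length(tf_ann$tf_down))

    ## --- methylation -----------------------------------------------------
    stage <- "methylation"
    if (config$n_perm < 1) abort_config("n_perm must be >= 1")
    beta_u <- beta[, use, drop = FALSE]
    beta_f <- filter_probes(beta_u, anno)
    bdiff <- beta_difference(beta_f, cases, controls)
    perm <- permutation_pvalues(beta_f, cases, controls,
                                n_perm = config$n_perm, seed = config$seed)
    dm <- call_dm(bdiff, perm$pvalue, anno, config$delta_beta, config$p_dm)
    dm_table <- data.frame(probe_id = names(bdiff),
                           beta_diff = unname(bdiff),
                           d_stat = unname(perm$d[names(bdiff)]),
                           pvalue = unname(perm$pvalue[names(bdiff)]),
                           stringsAsFactors = FALSE)
    write_tsv(dm_table, out("methylation_dm.tsv"), paste("config:", hash))
    region_cmp <- if (length(dm$hyper_probes) && length(dm$hypo_probes)) {
      region_distribution_test(dm$hyper_probes, dm$hypo_probes, anno)
    } else NULL
    if (!is.null(region_cmp)) {
      write_tsv(region_cmp, out("region_distribution.tsv"),
                paste("config:", hash))
    }
    report$methylation <- list(n_input = nrow(beta),
                               n_filtered = nrow(beta_f), s0 = perm$s0,
                               n_hyper_probes = length(dm$hyper_probes),
                               n_hypo_probes = length(dm$hypo_probes),
                               n_hyper_genes = length(dm$hyper_genes),
                               n_hypo_genes = length(dm$hypo_genes))

    ## --- miRNA differential expression -----------------------------------
    stage <- "mirna_de"
    mirna_u <- mirna[, use, drop = FALSE]
    mirna_f <- filter_low_expression(mirna_u, min.cpm = config$min_cpm,
                                     min.samples = config$min_samples)
    mlibs <- colSums(mirna_u)[use]
    mnf <- tmm_norm_factors(mirna_f, mlibs)
    mphi <- estimate_common_dispersion(mirna_f, groups, mlibs, mnf)
    mde <- exact_test(mirna_f, cases, controls, mphi, mlibs, mnf,
                      prior.cpm = config$prior_cpm)
    mcalls <- call_de(mde, config$lfc, config$p_de)
    write_tsv(mde, out("mirna_de.tsv"), paste("config:", hash))
    report$mirna <- list(n_input = nrow(mirna), n_filtered = nrow(mirna_f),
                         dispersion = mphi,
                         n_up = length(mcalls$up),
                         n_down = length(mcalls$down))

    ## --- integration ------------------------------------------------------
    stage <- "integration"
    expressed <- rownames(mrna_f)
    up_t <- targets_of(mcalls$up, target_map, universe = expressed)
    down_t <- targets_of(mcalls$down, target_map, universe = expressed)
    integ <- integrate_omics(calls$up, calls$down, up_t$genes, down_t$genes,
                             dm$hyper_genes)
    write_tsv(integ$venn, out("integration_venn.tsv"),
              paste("config:", hash))
    report$integration <- list(
      n_up_mirna_targets = length(up_t$genes),
      n_down_mirna_targets = length(down_t$genes),
      n_up_mirnas_with_targets = up_t$n_with_targets,
      n_down_mirnas_with_targets = down_t$n_with_targets,
      n_hyper_down = length(integ$hyper_down_genes),
      n_hyper_down_mirna_targets = length(integ$hyper_down_mirna_targets))

    ## --- enrichment -------------------------------------------------------
    stage <- "enrichment"
    families <- list(up = calls$up, down = calls$down,
                     hyper = dm$hyper_genes, hypo = dm$hypo_genes,
                     mirna_targets = union(up_t$genes, down_t$genes))
    report$enrichment <- list()
    for (fam in names(families)) {
      genes <- intersect(families[[fam]], expressed)
      if (length(genes) == 0L) {
        report$enrichment[[fam]] <- list(n_tested = 0L, n_retained = 0L)
        next
      }
      er <- enrich(genes, catalog, universe = expressed,
                   padj_thresh = config$padj_enrich)
      write_tsv(er, out(paste0("enrichment_", fam, ".tsv")),
                paste("config:", hash))
      report$enrichment[[fam]] <- list(n_tested = nrow(er),
                                       n_retained = sum(er$retained))
    }

    ## --- networks ---------------------------------------------------------
    stage <- "network"
    logcpm <- log2(cpm(mrna_f[, cases, drop = FALSE],
                       libs[cases] * nf[cases]) + 1)
    pairs <- pearson_pairs(logcpm)
    top <- top_fraction_pairs(pairs, config$top_fraction, config$cor_mode)
    background <- build_background(top, ppi)
    up_net <- project_subnetwork(background, calls$up, mcalls$up,
                                 target_map, direction = "up")
    down_net <- project_subnetwork(background, calls$down, mcalls$down,
                                   target_map, direction = "down")
    core <- if (length(integ$hyper_down_genes)) {
      suppressWarnings(core_network(down_net, integ$hyper_down_genes))
    } else empty_network()
    up_show <- filter_by_degree(up_net, config$min_degree)
    core_show <- filter_by_degree(core, config$min_degree)
    write_network(background, out("background_edges.tsv"),
                  out("background_nodes.tsv"), paste("config:", hash))
    write_network(up_net, out("up_network_edges.tsv"),
                  out("up_network_nodes.tsv"), paste("config:", hash))
    write_network(core, out("core_network_edges.tsv"),
                  out("core_network_nodes.tsv"), paste("config:", hash))
    report$network <- list(
      n_pairs = nrow(pairs), n_top_pairs = nrow(top),
      n_background_edges = igraph::ecount(background),
      n_background_nodes = igraph::vcount(background),
      n_up_nodes = igraph::vcount(up_net),
      n_up_edges = igraph::ecount(up_net),
      n_core_nodes = igraph::vcount(core),
      n_core_edges = igraph::ecount(core),
      n_up_shown = igraph::vcount(up_show),
      n_core_shown = igraph::vcount(core_show))

    stage <- "report"
    class(report) <- "run_report"
    jsonlite::write_json(unclass(report), out("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, error = fail)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `design` may be given
#' as a mapping with `target_gene`, `exclusion_genes`,
#' `truncating_classes`. Relative input paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathkeys <- c("maf", "samples", "mrna", "mirna", "beta", "anno",
                "targets", "gmt", "ppi", "tfs", "outdir")
  for (k in intersect(pathkeys, names(y))) {
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]])) {
      y[[k]] <- file.path(base, y[[k]])
    }
  }
  if (!is.null(y$design)) {
    y$design <- do.call(cohort_design, y$design)
  }
  do.call(pipeline_config, y)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "\n")
  cat("  cohort:", x$cohort$n_cases, "cases /", x$cohort$n_controls,
      "controls\n")
  cat("  mRNA DE:", x$mrna$n_up, "up /", x$mrna$n_down, "down",
      sprintf("(phi = %.3f)", x$mrna$dispersion), "\n")
  cat("  methylation:", x$methylation$n_hyper_probes, "hyper /",
      x$methylation$n_hypo_probes, "hypo probes ->",
      x$methylation$n_hyper_genes, "/", x$methylation$n_hypo_genes,
      "genes\n")
  cat("  miRNA DE:", x$mirna$n_up, "up /", x$mirna$n_down, "down\n")
  cat("  hyper-down genes:", x$integration$n_hyper_down,
      "(miRNA targets:", x$integration$n_hyper_down_mirna_targets, ")\n")
  cat("  background network:", x$network$n_background_nodes, "nodes /",
      x$network$n_background_edges, "edges\n")
  invisible(x)
}
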