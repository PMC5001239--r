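#' Synthetic multi-omics simulation configuration
#'
#' Defines the study conditions emulated by the generator: a small
#' truncating-mutation case group versus a larger "pan-negative" control
#' group (defaults 11 vs 33, the stratified cohort size of the motivating
#' study), with planted differential expression (negative-binomial counts),
#' differential methylation (beta-distributed probe values), enriched gene
#' sets, and a co-expressed module wired into the PPI as a clique.
#'
#' @param n_case,n_control,n_other Group sizes; `n_other` samples carry
#'   disqualifying variants and are removed by stratification.
#' @param n_genes,n_mirnas,n_probes Feature-universe sizes.
#' @param n_de_genes,n_de_mirnas,n_dm_probes Planted signal counts.
#' @param effect_log2fc Planted |log2 fold change| on counts.
#' @param delta_beta Planted beta-value shift on methylation probes.
#' @param nb_dispersion Common NB dispersion (0 = Poisson).
#' @param beta_precision Concentration of the beta distributions.
#' @param lib_size_range Uniform range of per-sample library sizes.
#' @param frac_down Fraction of planted DE genes that are down in cases.
#' @param frac_hyper Fraction of planted DM probes shifted up (hyper) in
#'   cases.
#' @param module_size Size of the planted co-expressed PPI clique.
#' @param module_cor_sd SD (log2 units) of the shared latent factor that
#'   correlates module genes in the case group; 0 disables the module
#'   signal.
#' @param ppi_mean_degree Mean degree of the random PPI graph.
#' @param n_gene_sets Number of background catalog terms.
#' @param target_gene,exclusion_genes Driver genes used in the mutation
#'   layer.
#' @param seed Global seed, expanded into per-layer substreams.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_case = 11, n_control = 33, n_other = 6,
                       n_genes = 2000, n_mirnas = 300, n_probes = 4000,
                       n_de_genes = 200, n_de_mirnas = 40, n_dm_probes = 200,
                       effect_log2fc = 2, delta_beta = 0.3,
                       nb_dispersion = 0.1, beta_precision = 50,
                       lib_size_range = c(5e5, 1e6),
                       frac_down = 0.8, frac_hyper = 0.9,
                       module_size = 12, module_cor_sd = 1.5,
                       ppi_mean_degree = 4, n_gene_sets = 50,
                       target_gene = "PBRM1",
                       exclusion_genes = c("VHL", "BAP1", "SETD2", "PTEN",
                                           "KDM5C"),
                       seed = 7) {
  cfg <- as.list(environment())
  sizes <- c(n_case, n_control, n_other, n_genes, n_mirnas, n_probes,
             n_de_genes, n_de_mirnas, n_dm_probes, n_gene_sets, module_size)
  if (any(sizes < 0)) abort_config("sizes must be non-negative")
  if (n_de_genes > n_genes) abort_config("n_de_genes > n_genes")
  if (n_dm_probes > n_probes) abort_config("n_dm_probes > n_probes")
  if (n_de_mirnas > n_mirnas) abort_config("n_de_mirnas > n_mirnas")
  if (nb_dispersion < 0) abort_config("nb_dispersion must be >= 0")
  if (beta_precision <= 0) abort_config("beta_precision must be > 0")
  if (frac_down < 0 || frac_down > 1) abort_config("frac_down in [0,1]")
  if (any(lib_size_range <= 0) || lib_size_range[1] > lib_size_range[2]) {
    abort_config("invalid lib_size_range")
  }
  structure(cfg, class = "sim_config")
}

sim_feature_names <- function(config) {
  list(genes = sprintf("G%04d", seq_len(config$n_genes)),
       mirnas = sprintf("sim-miR-%03d", seq_len(config$n_mirnas)),
       probes = sprintf("cg%07d", seq_len(config$n_probes)))
}

#' Simulate a mutation table with recorded ground truth
#'
#' Every case sample carries at least one truncating variant of the target
#' gene (variant classes drawn in the nonsense/splice/frameshift-deletion
#' proportions observed in the motivating cohort, 5:3:3); controls carry
#' only passenger variants in bystander genes; "other" samples carry either
#' an exclusion-gene variant or a non-truncating target variant, so
#' stratification removes them.
#'
#' The returned ground truth also fixes the planted feature sets used by the
#' other layers (DE genes with per-gene signed log2FC, DM probes with signed
#' delta-beta and their gene assignment, DE miRNAs, the enriched term, the
#' co-expressed module), so the layers can be generated independently from
#' per-layer seed substreams.
#'
#' @param config A [sim_config()].
#' @return List with `mutations` (data frame `sample_id`, `gene_symbol`,
#'   `variant_class`, `protein_pos`), `samples` (full roster), and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stream_seeds(config$seed)
  nm <- sim_feature_names(config)
  n_tot <- config$n_case + config$n_control + config$n_other
  samples <- sprintf("S%03d", seq_len(n_tot))
  case_ids <- samples[seq_len(config$n_case)]
  control_ids <- samples[config$n_case + seq_len(config$n_control)]
  other_ids <- setdiff(samples, c(case_ids, control_ids))

  truth <- with_seed(seeds[["mutation"]], {
    ## planted DE genes with signed effects
    de_genes <- sample(nm$genes, config$n_de_genes)
    n_down <- round(config$frac_down * config$n_de_genes)
    down <- de_genes[seq_len(n_down)]
    up <- setdiff(de_genes, down)
    de_mirnas <- sample(nm$mirnas, config$n_de_mirnas)
    mir_down <- de_mirnas[seq_len(config$n_de_mirnas %/% 2)]
    mir_up <- setdiff(de_mirnas, mir_down)
    ## planted DM probes: a block of hyper probes is assigned to planted
    ## down genes so a hyper-down overlap exists by construction
    dm_probes <- sample(nm$probes, config$n_dm_probes)
    n_hyper <- round(config$frac_hyper * config$n_dm_probes)
    hyper <- dm_probes[seq_len(n_hyper)]
    hypo <- setdiff(dm_probes, hyper)
    n_overlap <- min(length(hyper), length(down), 30L)
    hyper_gene <- c(sample(down, n_overlap),
                    sample(setdiff(nm$genes, de_genes),
                           length(hyper) - n_overlap, replace = TRUE))
    hypo_gene <- sample(setdiff(nm$genes, de_genes), length(hypo),
                        replace = TRUE)
    module <- sample(setdiff(nm$genes, de_genes), config$module_size)
    list(
      de_genes_up = up, de_genes_down = down,
      gene_log2fc = stats::setNames(
        c(rep(config$effect_log2fc, length(up)),
          rep(-config$effect_log2fc, length(down))), c(up, down)),
      de_mirnas_up = mir_up, de_mirnas_down = mir_down,
      mirna_log2fc = stats::setNames(
        c(rep(config$effect_log2fc, length(mir_up)),
          rep(-config$effect_log2fc, length(mir_down))),
        c(mir_up, mir_down)),
      dm_probes_hyper = hyper, dm_probes_hypo = hypo,
      dm_probe_gene = stats::setNames(c(hyper_gene, hypo_gene),
                                      c(hyper, hypo)),
      dm_delta = stats::setNames(
        c(rep(config$delta_beta, length(hyper)),
          rep(-config$delta_beta, length(hypo))), c(hyper, hypo)),
      planted_term = "TERM_PLANTED",
      planted_module = module,
      case_ids = case_ids, control_ids = control_ids,
      other_ids = other_ids)
  })

  mutations <- with_seed(seeds[["mutation"]] + 1L, {
    passenger_genes <- sprintf("BYSTANDER%03d", 1:50)
    trunc_classes <- c("nonsense", "splice_site", "frameshift_del")
    rows <- list()
    for (s in case_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene_symbol = config$target_gene,
        variant_class = sample(trunc_classes, 1, prob = c(5, 3, 3)),
        protein_pos = sample.int(1600L, 1), stringsAsFactors = FALSE)
    }
    for (s in other_ids) {
      if (stats::runif(1) < 0.5) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene_symbol = sample(config$exclusion_genes, 1),
          variant_class = sample(VARIANT_CLASSES, 1),
          protein_pos = sample.int(1000L, 1), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene_symbol = config$target_gene,
          variant_class = sample(c("missense", "silent", "in_frame_indel"),
                                 1),
          protein_pos = sample.int(1600L, 1), stringsAsFactors = FALSE)
      }
    }
    ## passenger calls in bystander genes for every sample
    for (s in samples) {
      k <- stats::rpois(1, 3)
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s,
          gene_symbol = sample(passenger_genes, k, replace = TRUE),
          variant_class = sample(c("missense", "silent"), k, replace = TRUE),
          protein_pos = sample.int(1000L, k, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  list(mutations = mutations, samples = samples, truth = truth)
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Counts are drawn feature-wise from a negative binomial with a per-sample
#' library-size scaling of log-normal baseline abundances; planted features
#' have their case-group mean multiplied by `2^(signed effect)`; dispersion
#' is common to all features (0 = Poisson). When `module_cor_sd > 0` the
#' planted module genes share a mean-corrected log-normal latent factor
#' across case samples, inducing strong positive co-expression in cases only
#' (mRNA layer).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_cohort()].
#' @param layer `"mRNA"` or `"miRNA"`.
#' @return Integer feature x sample count matrix (all cohort samples).
#' @export
simulate_counts <- function(config, truth, layer = c("mRNA", "miRNA")) {
  layer <- match.arg(layer)
  seeds <- stream_seeds(config$seed)
  nm <- sim_feature_names(config)
  feats <- if (layer == "mRNA") nm$genes else nm$mirnas
  lfc <- if (layer == "mRNA") truth$gene_log2fc else truth$mirna_log2fc
  samples <- c(truth$case_ids, truth$control_ids, truth$other_ids)

  with_seed(seeds[[if (layer == "mRNA") "mrna" else "mirna"]], {
    nf <- length(feats); ns <- length(samples)
    w <- exp(stats::rnorm(nf, 0, 1.2))
    prop <- w / sum(w)
    libs <- round(stats::runif(ns, config$lib_size_range[1],
                               config$lib_size_range[2]))
    mu <- outer(prop, libs)
    is_case <- samples %in% truth$case_ids
    planted <- match(names(lfc), feats)
    mu[planted, is_case] <- mu[planted, is_case] * 2^lfc
    if (layer == "mRNA" && config$module_cor_sd > 0 &&
        length(truth$planted_module)) {
      z <- stats::rnorm(sum(is_case), 0, config$module_cor_sd)
      fac <- 2^z / 2^(config$module_cor_sd^2 * log(2) / 2)
      mi <- match(truth$planted_module, feats)
      mu[mi, is_case] <- sweep(mu[mi, is_case, drop = FALSE], 2L, fac, "*")
    }
    counts <- if (config$nb_dispersion < 1e-12) {
      matrix(stats::rpois(nf * ns, mu), nf, ns)
    } else {
      matrix(stats::rnbinom(nf * ns, size = 1 / config$nb_dispersion,
                            mu = mu), nf, ns)
    }
    dimnames(counts) <- list(feats, samples)
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Simulate a beta-value methylation matrix with annotation
#'
#' Beta-values are drawn per probe from beta distributions with baseline
#' mean in (0.05, 0.95) (bimodal, as on methylation arrays) and the
#' configured precision; planted hyper probes have their case mean shifted
#' by `+delta_beta` (hypo by `-delta_beta`), clipped to \[0.02, 0.98\] with
#' a warning when clipping occurs. Planted probes draw baselines that leave
#' room for the shift. The annotation assigns chromosomes (some X/Y), gene
#' symbols (some absent), region labels and a SNP-proximity flag; planted
#' probes always receive a clean (retained) annotation and carry the gene
#' assignment fixed in the ground truth, with hyper probes biased toward
#' promoter/body regions.
#'
#' @inheritParams simulate_counts
#' @return List with `beta` (probe x sample matrix) and `anno` (data frame).
#' @export
simulate_beta <- function(config, truth) {
  seeds <- stream_seeds(config$seed)
  nm <- sim_feature_names(config)
  samples <- c(truth$case_ids, truth$control_ids, truth$other_ids)
  regions <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR", "IGR")

  with_seed(seeds[["beta"]], {
    np <- length(nm$probes); ns <- length(samples)
    lo <- stats::runif(np) < 0.5
    base <- ifelse(lo, stats::rbeta(np, 2, 10), stats::rbeta(np, 10, 2))
    base <- pmin(pmax(base, 0.05), 0.95)
    planted <- names(truth$dm_delta)
    pi_ <- match(planted, nm$probes)
    ## leave headroom for the shift
    base[pi_] <- ifelse(truth$dm_delta > 0,
                        stats::runif(length(pi_), 0.10, 0.60),
                        stats::runif(length(pi_), 0.40, 0.90))
    m <- matrix(base, np, ns)
    is_case <- samples %in% truth$case_ids
    shifted <- base[pi_] + truth$dm_delta
    if (any(shifted < 0.02 | shifted > 0.98)) {
      warning("planted shift pushes some case means outside [0.02, 0.98]; ",
              "clipped")
      shifted <- pmin(pmax(shifted, 0.02), 0.98)
    }
    m[pi_, is_case] <- matrix(shifted, length(pi_), sum(is_case))
    prec <- config$beta_precision
    beta <- matrix(stats::rbeta(np * ns, m * prec, (1 - m) * prec), np, ns)
    dimnames(beta) <- list(nm$probes, samples)

    ## annotation
    chrom <- sample(paste0("chr", 1:22), np, replace = TRUE)
    sexpick <- sample.int(np, round(0.05 * np))
    chrom[sexpick] <- sample(c("chrX", "chrY"), length(sexpick),
                             replace = TRUE)
    gene <- sample(nm$genes, np, replace = TRUE)
    gene[sample.int(np, round(0.10 * np))] <- ""
    snp <- stats::runif(np) < 0.05
    region <- sample(regions, np, replace = TRUE,
                     prob = c(0.15, 0.12, 0.08, 0.06, 0.33, 0.06, 0.20))
    ## planted probes keep a clean annotation and their truth gene
    chrom[pi_] <- sample(paste0("chr", 1:22), length(pi_), replace = TRUE)
    snp[pi_] <- FALSE
    gene[pi_] <- truth$dm_probe_gene[planted]
    hyper_i <- match(truth$dm_probes_hyper, nm$probes)
    region[hyper_i] <- sample(c("TSS1500", "TSS200", "Body"), length(hyper_i),
                              replace = TRUE, prob = c(0.3, 0.3, 0.4))
    anno <- data.frame(probe_id = nm$probes, chrom = chrom,
                       pos = sample.int(2.4e8, np, replace = TRUE),
                       gene_symbol = gene, region = region,
                       snp_within_5bp = snp, stringsAsFactors = FALSE)
    list(beta = beta, anno = anno)
  })
}

#' Simulate annotation resources: miRNA targets, gene sets, PPI, TF list
#'
#' The target map links every miRNA to a random gene set plus deliberate
#' links from planted DE miRNAs to planted DE genes; the catalog contains
#' background terms plus a planted term drawn preferentially from planted
#' down-regulated genes; the PPI is an Erdos-Renyi-style random edge list
#' with the planted module wired in as a clique; the TF list contains a
#' fixed fraction of the planted DE genes plus random background genes.
#'
#' @inheritParams simulate_counts
#' @return List with `target_map` (named list), `catalog`
#'   ([geneset_catalog()]), `ppi` (data frame `gene_a`, `gene_b`), and
#'   `tf_list` (character).
#' @export
simulate_annotations <- function(config, truth) {
  seeds <- stream_seeds(config$seed)
  nm <- sim_feature_names(config)

  target_map <- with_seed(seeds[["annotation"]], {
    tm <- lapply(nm$mirnas, function(m) {
      sample(nm$genes, sample(5:30, 1))
    })
    names(tm) <- nm$mirnas
    de_genes <- c(truth$de_genes_up, truth$de_genes_down)
    if (length(de_genes)) {
      for (m in c(truth$de_mirnas_up, truth$de_mirnas_down)) {
        tm[[m]] <- unique(c(tm[[m]],
                            sample(de_genes, min(10, length(de_genes)))))
      }
    }
    tm
  })

  catalog <- with_seed(seeds[["genesets"]], {
    terms <- lapply(seq_len(config$n_gene_sets), function(i) {
      sample(nm$genes, sample(20:100, 1))
    })
    names(terms) <- sprintf("TERM_%03d", seq_len(config$n_gene_sets))
    n_pl <- 40L
    n_from_down <- min(length(truth$de_genes_down), 28L)
    terms[[truth$planted_term]] <-
      unique(c(sample(truth$de_genes_down, n_from_down),
               sample(nm$genes, n_pl - n_from_down)))
    desc <- stats::setNames(paste("synthetic gene set", names(terms)),
                            names(terms))
    geneset_catalog(terms, desc, universe = nm$genes)
  })

  ppi <- with_seed(seeds[["ppi"]], {
    n_edges <- round(config$ppi_mean_degree * config$n_genes / 2)
    a <- sample(nm$genes, n_edges, replace = TRUE)
    b <- sample(nm$genes, n_edges, replace = TRUE)
    keep <- a != b
    df <- data.frame(gene_a = pmin(a[keep], b[keep]),
                     gene_b = pmax(a[keep], b[keep]),
                     stringsAsFactors = FALSE)
    if (length(truth$planted_module) >= 2) {
      cl <- t(utils::combn(sort(truth$planted_module), 2))
      df <- rbind(df, data.frame(gene_a = cl[, 1], gene_b = cl[, 2],
                                 stringsAsFactors = FALSE))
    }
    df[!duplicated(pair_key(df$gene_a, df$gene_b)), , drop = FALSE]
  })

  tf_list <- with_seed(seeds[["genesets"]] + 1L, {
    de_genes <- c(truth$de_genes_up, truth$de_genes_down)
    n_de_tf <- round(0.15 * length(de_genes))
    unique(c(if (n_de_tf > 0) sample(de_genes, n_de_tf),
             sample(nm$genes, 60)))
  })

  list(target_map = target_map, catalog = catalog, ppi = ppi,
       tf_list = tf_list)
}

#' Simulate the full multi-omics bundle
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_counts()]
#' (both layers), [simulate_beta()] and [simulate_annotations()] from one
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List with `mutations`, `samples`, `truth`, `mrna`, `mirna`,
#'   `beta`, `anno`, `target_map`, `catalog`, `ppi`, `tf_list`, and the
#'   `config`.
#' @export
simulate_multiomics <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  meth <- simulate_beta(config, cohort$truth)
  ann <- simulate_annotations(config, cohort$truth)
  c(cohort,
    list(mrna = simulate_counts(config, cohort$truth, "mRNA"),
         mirna = simulate_counts(config, cohort$truth, "miRNA"),
         beta = meth$beta, anno = meth$anno),
    ann, list(config = config))
}
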