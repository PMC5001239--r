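#' Variant-class vocabulary
#'
#' Canonical variant classes used throughout the package, and the default
#' mapping from MAF `Variant_Classification` strings onto them. Unknown
#' strings map to `"other"` with a warning at read time.
#'
#' @format A character vector (canonical classes) and a named character
#'   vector (MAF string -> canonical class).
#' @name variant_vocabulary
NULL

#' @rdname variant_vocabulary
#' @export
VARIANT_CLASSES <- c("nonsense", "frameshift_del", "frameshift_ins",
                     "splice_site", "missense", "silent", "in_frame_indel",
                     "other")

#' @rdname variant_vocabulary
#' @export
MAF_CLASS_MAP <- c(
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift_del",
  Frame_Shift_Ins   = "frameshift_ins",
  Splice_Site       = "splice_site",
  Missense_Mutation = "missense",
  Silent            = "silent",
  In_Frame_Del      = "in_frame_indel",
  In_Frame_Ins      = "in_frame_indel",
  Nonstop_Mutation  = "nonsense",
  Translation_Start_Site = "other",
  RNA               = "other",
  IGR               = "other",
  Intron            = "other",
  "5'UTR"           = "other",
  "3'UTR"           = "other",
  "5'Flank"         = "other",
  "3'Flank"         = "other"
)

#' Define a stratified case/control cohort design
#'
#' A design names the target driver gene whose truncating mutations define
#' the case group, the co-driver genes whose mutation disqualifies a sample
#' from either group (yielding the "pan-negative" control group), and which
#' variant classes count as truncating (loss of function).
#'
#' @param target_gene Gene symbol whose truncating mutations define cases.
#' @param exclusion_genes Character vector of co-driver genes; any mutation
#'   in one of these excludes the sample from both groups. Defaults to the
#'   five high-confidence ccRCC drivers.
#' @param truncating_classes Variant classes treated as truncating. The
#'   default adds frameshift insertions to the observed
#'   nonsense/splice/frameshift-deletion classes on the loss-of-function
#'   rationale; drop it here if undesired.
#' @return An object of class `cohort_design`.
#' @examples
#' cohort_design("PBRM1")
#' @export
cohort_design <- function(target_gene = "PBRM1",
                          exclusion_genes = c("VHL", "BAP1", "SETD2",
                                              "PTEN", "KDM5C"),
                          truncating_classes = c("nonsense", "frameshift_del",
                                                 "frameshift_ins",
                                                 "splice_site")) {
  target_gene <- trimws(target_gene)
  exclusion_genes <- trimws(exclusion_genes)
  if (!nzchar(target_gene)) abort_config("target_gene must be non-empty")
  if (target_gene %in% exclusion_genes) {
    abort_config("target_gene must not be among exclusion_genes")
  }
  if (length(truncating_classes) == 0L) {
    abort_config("truncating_classes must be non-empty")
  }
  bad <- setdiff(truncating_classes, VARIANT_CLASSES)
  if (length(bad)) abort_config("unknown variant classes: ",
                                paste(bad, collapse = ", "))
  structure(list(target_gene = target_gene,
                 exclusion_genes = exclusion_genes,
                 truncating_classes = truncating_classes),
            class = "cohort_design")
}

#' Is a mutation record a truncating target-gene variant?
#'
#' @param gene_symbol,variant_class Fields of the mutation record (vectorized).
#' @param design A [cohort_design()].
#' @return Logical: `TRUE` iff the record hits the target gene with a
#'   truncating class.
#' @export
is_truncating <- function(gene_symbol, variant_class, design) {
  stopifnot(inherits(design, "cohort_design"))
  gene_symbol == design$target_gene &
    variant_class %in% design$truncating_classes
}

#' Stratify a cohort by target-gene truncating mutations
#'
#' Partitions samples into cases (at least one truncating target-gene variant,
#' no exclusion-gene variant), "pan-negative" controls (no target-gene and no
#' exclusion-gene variant), and excluded samples with a recorded reason.
#' Exclusion-gene carriers are excluded regardless of target-gene status;
#' samples whose only target-gene variants are non-truncating are excluded
#' rather than treated as controls, so controls are truly target-negative.
#'
#' @param mutations A data frame with columns `sample_id`, `gene_symbol`,
#'   `variant_class` (canonical; see [MAF_CLASS_MAP]).
#' @param design A [cohort_design()].
#' @param samples Optional character vector of all sample ids in the cohort
#'   (samples with zero somatic calls carry no rows in a mutation table);
#'   defaults to the ids present in `mutations`.
#' @return An object of class `stratified_cohort`: list with `case_ids`,
#'   `control_ids`, and `excluded` (named character vector of reasons,
#'   one of `exclusion_gene_mutation`, `target_nontruncating_only`,
#'   `missing_omics`).
#' @examples
#' maf <- data.frame(
#'   sample_id = c("S1", "S2", "S2", "S4", "S5"),
#'   gene_symbol = c("PBRM1", "PBRM1", "VHL", "PBRM1", "SETD2"),
#'   variant_class = c("nonsense", "nonsense", "missense", "missense",
#'                     "nonsense"))
#' stratify(maf, cohort_design("PBRM1"), samples = paste0("S", 1:5))
#' @export
stratify <- function(mutations, design, samples = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.data.frame(mutations) || nrow(mutations) == 0L) {
    abort_input("mutation table is empty")
  }
  req <- c("sample_id", "gene_symbol", "variant_class")
  miss <- setdiff(req, names(mutations))
  if (length(miss)) abort_input("mutation table lacks columns: ",
                                paste(miss, collapse = ", "))
  sid <- trimws(as.character(mutations$sample_id))
  gene <- trimws(as.character(mutations$gene_symbol))
  vc <- as.character(mutations$variant_class)
  if (any(!nzchar(sid)) || any(!nzchar(gene))) {
    abort_input("sample_id and gene_symbol must be non-empty")
  }
  bad <- setdiff(unique(vc), VARIANT_CLASSES)
  if (length(bad)) abort_input("non-canonical variant classes: ",
                               paste(bad, collapse = ", "))

  samples <- if (is.null(samples)) unique(sid) else unique(trimws(samples))
  extra <- setdiff(sid, samples)
  if (length(extra)) abort_input("mutation rows for samples outside the ",
                                 "roster: ", paste(extra, collapse = ", "))

  has_excl <- sid[gene %in% design$exclusion_genes]
  has_target <- sid[gene == design$target_gene]
  has_trunc <- sid[is_truncating(gene, vc, design)]

  excluded <- character(0)
  reason <- character(0)
  is_excl <- samples %in% has_excl
  is_trunc <- samples %in% has_trunc
  is_target <- samples %in% has_target

  cases <- samples[!is_excl & is_trunc]
  controls <- samples[!is_excl & !is_target]
  excl1 <- samples[is_excl]
  excl2 <- samples[!is_excl & is_target & !is_trunc]

  excluded <- stats::setNames(
    c(rep("exclusion_gene_mutation", length(excl1)),
      rep("target_nontruncating_only", length(excl2))),
    c(excl1, excl2))

  structure(list(case_ids = cases, control_ids = controls,
                 excluded = excluded),
            class = "stratified_cohort")
}

#' Restrict a stratified cohort to samples with complete multi-omics data
#'
#' Keeps only cases/controls present on every platform; removed samples are
#' recorded as excluded with reason `missing_omics`.
#'
#' @param cohort A [stratify()] result.
#' @param available Named list of character vectors, one per platform
#'   (e.g. `list(rna = ..., meth = ..., mirna = ...)`), each the sample ids
#'   with data on that platform.
#' @return The restricted `stratified_cohort`.
#' @export
require_matched_omics <- function(cohort, available) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  if (!is.list(available) || length(available) == 0L) {
    abort_input("available must be a non-empty named list of sample-id sets")
  }
  if (any(vapply(available, length, 1L) == 0L)) {
    abort_input("an omics availability set is empty")
  }
  keep <- Reduce(intersect, lapply(available, trimws))
  drop_case <- setdiff(cohort$case_ids, keep)
  drop_ctrl <- setdiff(cohort$control_ids, keep)
  dropped <- c(drop_case, drop_ctrl)
  cohort$case_ids <- intersect(cohort$case_ids, keep)
  cohort$control_ids <- intersect(cohort$control_ids, keep)
  cohort$excluded <- c(cohort$excluded,
                       stats::setNames(rep("missing_omics", length(dropped)),
                                       dropped))
  if (length(cohort$case_ids) == 0L && length(cohort$control_ids) == 0L) {
    abort_input("no sample has complete multi-omics data")
  }
  cohort
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat("Stratified cohort:", length(x$case_ids), "cases,",
      length(x$control_ids), "controls,",
      length(x$excluded), "excluded\n")
  if (length(x$excluded)) {
    print(table(x$excluded))
  }
  invisible(x)
}
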