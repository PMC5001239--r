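#' Target genes of a set of miRNAs
#'
#' Union of target sets of the query miRNAs present in the target map;
#' miRNAs absent from the map contribute nothing.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param target_map Named list: miRNA id -> character vector of gene
#'   symbols (see [read_target_map()]).
#' @param universe Optional gene universe (e.g. expressed genes after
#'   filtering); when given, target sets are intersected with it before the
#'   union, so overlaps are computed on the analyzed gene space.
#' @return List with `genes` (the union) and `n_with_targets` (how many
#'   query miRNAs had at least one target after restriction).
#' @export
targets_of <- function(mirnas, target_map, universe = NULL) {
  sets <- target_map[intersect(mirnas, names(target_map))]
  if (!is.null(universe)) sets <- lapply(sets, intersect, universe)
  sets <- sets[vapply(sets, length, 1L) > 0L]
  list(genes = unique(unlist(sets, use.names = FALSE)) %||% character(0),
       n_with_targets = length(sets))
}

#' Hyper-methylated, down-regulated ("hyper-down") genes
#'
#' @param down_genes Down-regulated gene symbols.
#' @param hyper_genes Hyper-methylated gene symbols.
#' @return Their intersection.
#' @export
hyper_down_genes <- function(down_genes, hyper_genes) {
  intersect(down_genes, hyper_genes)
}

#' Integrate expression, methylation and miRNA-target layers
#'
#' Computes every region of the four-set Venn diagram over up-regulated
#' genes, down-regulated genes, targets of up-regulated miRNAs, and targets
#' of down-regulated miRNAs, plus the hyper-down gene set and the hyper-down
#' genes that are also miRNA targets (targets of either miRNA direction;
#' per-direction breakdown included).
#'
#' @param up_genes,down_genes DE gene-symbol vectors.
#' @param up_targets,down_targets Target-gene vectors of up-/down-regulated
#'   miRNAs.
#' @param hyper_genes Hyper-methylated gene symbols.
#' @return List with `venn` (data frame of all 15 non-empty membership
#'   patterns: logical columns `deg_up`, `deg_down`, `tgt_up`, `tgt_down`
#'   and `count`), `hyper_down_genes`, `hyper_down_mirna_targets`,
#'   `hyper_down_targets_up_mirnas`, `hyper_down_targets_down_mirnas`.
#' @export
integrate_omics <- function(up_genes, down_genes, up_targets, down_targets,
                            hyper_genes) {
  sets <- list(deg_up = unique(up_genes), deg_down = unique(down_genes),
               tgt_up = unique(up_targets), tgt_down = unique(down_targets))
  uni <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(deg_up = c(FALSE, TRUE), deg_down = c(FALSE, TRUE),
                          tgt_up = c(FALSE, TRUE), tgt_down = c(FALSE, TRUE))
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  patterns$count <- vapply(seq_len(nrow(patterns)), function(i) {
    want <- unlist(patterns[i, 1:4])
    if (length(uni) == 0L) return(0L)
    sum(apply(member, 1L, function(m) all(m == want)))
  }, 1L)
  rownames(patterns) <- NULL

  hd <- hyper_down_genes(sets$deg_down, hyper_genes)
  list(venn = patterns,
       hyper_down_genes = hd,
       hyper_down_mirna_targets = intersect(hd, union(sets$tgt_up,
                                                      sets$tgt_down)),
       hyper_down_targets_up_mirnas = intersect(hd, sets$tgt_up),
       hyper_down_targets_down_mirnas = intersect(hd, sets$tgt_down))
}
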