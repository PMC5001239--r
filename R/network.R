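#' Pairwise Pearson correlations among features
#'
#' Computes `r` for every unordered feature pair from a feature x sample
#' matrix (typically log2-CPM of the case group), working blockwise over
#' feature blocks so the peak working set is bounded by `block^2` pairs.
#' Zero-variance features are dropped with a warning.
#'
#' @param expr Numeric feature x sample matrix with at least 3 samples.
#' @param block Feature-block size for the blockwise computation.
#' @return Data frame `a`, `b`, `r` with one row per unordered pair
#'   (`a` precedes `b` in the input order).
#' @export
pearson_pairs <- function(expr, block = 1000L) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) abort_input("need >=3 samples for correlations")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) dropped")
    expr <- expr[v > 0, , drop = FALSE]
  }
  n <- nrow(expr)
  if (n < 2L) abort_input("fewer than two variable features")
  feats <- rownames(expr) %||% as.character(seq_len(n))
  starts <- seq(1L, n, by = block)
  out <- vector("list", length(starts) * (length(starts) + 1L) / 2L)
  idx <- 0L
  for (bi in seq_along(starts)) {
    i0 <- starts[bi]; i1 <- min(i0 + block - 1L, n)
    xi <- t(expr[i0:i1, , drop = FALSE])
    for (bj in bi:length(starts)) {
      j0 <- starts[bj]; j1 <- min(j0 + block - 1L, n)
      r <- stats::cor(xi, t(expr[j0:j1, , drop = FALSE]))
      if (bi == bj) {
        keep <- which(upper.tri(r), arr.ind = TRUE)
      } else {
        keep <- which(matrix(TRUE, nrow(r), ncol(r)), arr.ind = TRUE)
      }
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        a = feats[i0:i1][keep[, 1L]],
        b = feats[j0:j1][keep[, 2L]],
        r = r[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(idx)])
  rownames(res) <- NULL
  res
}

#' Keep the top fraction of co-expressed pairs
#'
#' Selects the `ceiling(fraction * n_pairs)` pairs with the largest score
#' (signed `r` or `|r|`); all pairs tying with the cutoff score are
#' included, so the result may exceed the nominal count.
#'
#' @param pairs Data frame from [pearson_pairs()].
#' @param fraction Fraction of pairs to keep, in (0, 1\].
#' @param mode `"absolute"` ranks by `|r|` (default), `"signed"` by `r`.
#' @return The selected rows of `pairs`.
#' @export
top_fraction_pairs <- function(pairs, fraction = 0.05,
                               mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort_config("fraction must lie in (0, 1]")
  }
  if (nrow(pairs) == 0L) abort_input("no pairs supplied")
  score <- if (mode == "absolute") abs(pairs$r) else pairs$r
  m <- ceiling(fraction * nrow(pairs))
  cutoff <- sort(score, decreasing = TRUE)[m]
  pairs[score >= cutoff, , drop = FALSE]
}

empty_network <- function() {
  igraph::make_empty_graph(directed = FALSE)
}

set_default_attrs <- function(g) {
  if (!"node_type" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "node_type", value = "gene")
  }
  if (!"direction" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "direction", value = "none")
  }
  if (!"hyper_down" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "hyper_down", value = FALSE)
  }
  g
}

#' Build the mutation-specific background co-expression network
#'
#' Intersects the top-fraction co-expressed pairs with a reference
#' protein-protein interaction edge list (undirected, exact symbol match);
#' isolated nodes are dropped. An empty intersection yields an empty network
#' with a warning.
#'
#' @param pairs Selected pairs from [top_fraction_pairs()].
#' @param ppi Data frame with columns `gene_a`, `gene_b`.
#' @return An undirected [igraph::igraph] with edge attributes `r` and
#'   `source = "coexpression"` and node attributes `node_type`, `direction`,
#'   `hyper_down`.
#' @export
build_background <- function(pairs, ppi) {
  ppi_keys <- unique(pair_key(ppi$gene_a, ppi$gene_b))
  keep <- pair_key(pairs$a, pairs$b) %in% ppi_keys
  sel <- pairs[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no co-expressed pair is present in the PPI; empty network")
    return(set_default_attrs(empty_network()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = sel$a, to = sel$b, r = sel$r,
               source = "coexpression", stringsAsFactors = FALSE),
    directed = FALSE)
  set_default_attrs(igraph::simplify(g, edge.attr.comb = "first"))
}

#' Project a gene set and its regulating miRNAs onto the background
#'
#' Induced subgraph of the background on the given genes; every miRNA whose
#' targets intersect the retained genes is then added as a miRNA node with
#' an edge (source `"mirna_target"`) to each retained target.
#'
#' @param background Network from [build_background()].
#' @param gene_set Gene symbols to retain (e.g. up- or down-regulated DEGs).
#' @param mirnas miRNA ids to consider (e.g. DE miRNAs); may be empty.
#' @param target_map Named list miRNA -> target genes.
#' @param direction Direction label stored on the retained gene nodes.
#' @return An `igraph` network.
#' @export
project_subnetwork <- function(background, gene_set, mirnas = character(0),
                               target_map = list(), direction = "none") {
  nodes <- intersect(gene_set, igraph::V(background)$name)
  g <- igraph::induced_subgraph(background, nodes)
  g <- igraph::set_vertex_attr(g, "direction", value = direction)
  for (m in intersect(mirnas, names(target_map))) {
    tg <- intersect(target_map[[m]], igraph::V(g)$name[
      igraph::V(g)$node_type == "gene"])
    if (length(tg) == 0L) next
    g <- igraph::add_vertices(g, 1L, name = m, node_type = "miRNA",
                              direction = "none", hyper_down = FALSE)
    g <- igraph::add_edges(g, as.vector(rbind(m, tg)),
                           attr = list(source = rep("mirna_target",
                                                    length(tg)),
                                       r = rep(NA_real_, length(tg))))
  }
  g
}

#' Core subnetwork: seed genes and their first neighbors
#'
#' Induced subgraph on the closed neighborhood of the seed genes (the seeds
#' plus every node adjacent to a seed); seeds present in the network are
#' flagged `hyper_down = TRUE`.
#'
#' @param subnetwork An `igraph` network.
#' @param seeds Seed gene symbols (e.g. hyper-down genes).
#' @return The core `igraph` network (empty, with a warning, when no seed is
#'   present).
#' @export
core_network <- function(subnetwork, seeds) {
  present <- intersect(seeds, igraph::V(subnetwork)$name)
  if (length(present) == 0L) {
    warning("no seed gene present in the subnetwork; empty core")
    return(set_default_attrs(empty_network()))
  }
  nb <- igraph::ego(subnetwork, order = 1,
                    nodes = present, mode = "all")
  keep <- unique(unlist(lapply(nb, names), use.names = FALSE))
  g <- igraph::induced_subgraph(subnetwork, keep)
  igraph::set_vertex_attr(g, "hyper_down",
                          index = match(present, igraph::V(g)$name),
                          value = TRUE)
}

#' Single-pass degree filter
#'
#' Removes nodes whose degree in the input network is below `min_degree`
#' (degrees computed once, on the input; no iterative re-pruning), then
#' drops dangling edges. An iterative k-core mode is available.
#'
#' @param network An `igraph` network.
#' @param min_degree Minimum degree to retain a node.
#' @param iterative Use the iterative k-core instead of the single pass?
#' @return The filtered network.
#' @export
filter_by_degree <- function(network, min_degree = 3, iterative = FALSE) {
  if (iterative) {
    keep <- igraph::V(network)[igraph::coreness(network) >= min_degree]
    return(igraph::induced_subgraph(network, keep))
  }
  deg <- igraph::degree(network)
  igraph::induced_subgraph(network, igraph::V(network)[deg >= min_degree])
}
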