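## Tab-separated dialect shared by all readers/writers: header row,
## '#' comment lines, no quoting. Readers validate shape and id uniqueness.

read_tsv_checked <- function(path, required = NULL, numeric_cols = NULL) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    abort_input(path, ": ragged row at line ",
                which(nf != nf[1])[1])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort_input(path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) {
      abort_input(path, ": non-numeric value in column '", cc, "' at line ",
                  bad[1] + 1L)
    }
    df[[cc]] <- v
  }
  df
}

write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a MAF-like somatic mutation table
#'
#' Tab-separated with columns `sample_id`, `gene_symbol`, `variant_class`
#' (canonical or standard MAF `Variant_Classification` strings, which are
#' mapped via [MAF_CLASS_MAP]; unknown strings map to `"other"` with a
#' warning), and optional `protein_pos`.
#'
#' @param path File path.
#' @param class_map Vocabulary mapping, MAF string -> canonical class.
#' @return Data frame with canonical `variant_class`.
#' @export
read_maf <- function(path, class_map = MAF_CLASS_MAP) {
  df <- read_tsv_checked(path, required = c("sample_id", "gene_symbol",
                                            "variant_class"))
  vc <- df$variant_class
  mapped <- ifelse(vc %in% VARIANT_CLASSES, vc,
                   unname(class_map[vc]))
  unknown <- unique(vc[is.na(mapped)])
  if (length(unknown)) {
    warning("unknown variant classification(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
    mapped[is.na(mapped)] <- "other"
  }
  df$variant_class <- mapped
  df
}

#' @rdname read_maf
#' @param mutations Mutation data frame.
#' @param header_comment Optional provenance comment written as a `#` line.
#' @export
write_maf <- function(mutations, path, header_comment = NULL) {
  write_tsv(mutations, path, header_comment)
}

#' Read / write a feature-by-sample numeric matrix (counts or beta-values)
#'
#' First column holds feature ids (header name free), remaining columns one
#' sample each. Duplicate feature or sample ids are an error.
#'
#' @param path File path.
#' @param integer Coerce to integer counts?
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, integer = FALSE) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) abort_input(path, ": expected feature column plus ",
                                 "sample columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) abort_input(path, ": duplicate feature ids")
  if (anyDuplicated(names(df)[-1L])) abort_input(path,
                                                 ": duplicate sample ids")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    mn <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)))
    if (any(is.na(mn) & !is.na(m))) {
      abort_input(path, ": non-numeric cell in matrix body")
    }
    m <- mn
  }
  rownames(m) <- ids
  if (integer) storage.mode(m) <- "integer"
  m
}

#' @rdname read_matrix
#' @param m Matrix to write.
#' @param id_col Header name of the feature-id column.
#' @param header_comment Optional provenance comment written as a `#` line.
#' @export
write_matrix <- function(m, path, id_col = "feature",
                         header_comment = NULL) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path, header_comment)
}

#' Read / write a GMT gene-set catalog
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member genes. Lines with fewer than three fields are an error
#' (reported with the line number).
#'
#' @param path File path.
#' @param universe Optional universe passed to [geneset_catalog()].
#' @return A `geneset_catalog`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    abort_input(path, ": GMT line ", short[1],
                " has fewer than three fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) abort_input(path, ": duplicate term ids")
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- ids
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  geneset_catalog(terms, desc, universe)
}

#' @rdname read_gmt
#' @param catalog A `geneset_catalog`.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$terms), function(id) {
    paste(c(id, catalog$descriptions[[id]], catalog$terms[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a miRNA-to-target map
#'
#' Two-column TSV (`mirna_id`, `gene_symbol`), one interaction per row.
#'
#' @param path File path.
#' @return Named list: miRNA id -> character vector of targets.
#' @export
read_target_map <- function(path) {
  df <- read_tsv_checked(path, required = c("mirna_id", "gene_symbol"))
  split(df$gene_symbol, df$mirna_id)
}

#' @rdname read_target_map
#' @param target_map Named list miRNA -> targets.
#' @export
write_target_map <- function(target_map, path) {
  df <- data.frame(
    mirna_id = rep(names(target_map), lengths(target_map)),
    gene_symbol = unlist(target_map, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write a PPI edge list
#'
#' Two-column TSV (`gene_a`, `gene_b`); self-loops and duplicate undirected
#' edges are dropped on read.
#'
#' @param path File path.
#' @return Data frame `gene_a`, `gene_b`.
#' @export
read_ppi <- function(path) {
  df <- read_tsv_checked(path, required = c("gene_a", "gene_b"))
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  df <- df[!duplicated(pair_key(df$gene_a, df$gene_b)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_ppi
#' @param ppi Edge-list data frame.
#' @export
write_ppi <- function(ppi, path) {
  write_tsv(ppi, path)
}

#' Write a network as edge-list plus node-attribute TSVs
#'
#' @param network An `igraph` network.
#' @param edge_path,node_path Output paths.
#' @param header_comment Optional `#` provenance line.
#' @return Invisibly, the edge path.
#' @export
write_network <- function(network, edge_path, node_path,
                          header_comment = NULL) {
  ed <- igraph::as_data_frame(network, what = "edges")
  vd <- igraph::as_data_frame(network, what = "vertices")
  write_tsv(ed, edge_path, header_comment)
  write_tsv(vd, node_path, header_comment)
  invisible(edge_path)
}

#' Write the full synthetic bundle to a directory
#'
#' Serializes every layer of a [simulate_multiomics()] bundle in the
#' package's plain-text formats plus the ground truth as JSON.
#'
#' @param bundle A [simulate_multiomics()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_maf(bundle$mutations, fp("mutations.tsv"))
  writeLines(bundle$samples, fp("samples.txt"))
  write_matrix(bundle$mrna, fp("mrna_counts.tsv"), id_col = "gene")
  write_matrix(bundle$mirna, fp("mirna_counts.tsv"), id_col = "mirna")
  write_matrix(bundle$beta, fp("beta.tsv"), id_col = "probe_id")
  write_tsv(bundle$anno, fp("probe_anno.tsv"))
  write_target_map(bundle$target_map, fp("targets.tsv"))
  write_gmt(bundle$catalog, fp("genesets.gmt"))
  write_ppi(bundle$ppi, fp("ppi.tsv"))
  writeLines(bundle$tf_list, fp("tf_list.txt"))
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}
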