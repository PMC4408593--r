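## Readers and writers for the plain-text formats the pipeline touches.
## All files are TSV, UTF-8, LF line endings, "." decimal separator.  Every
## reader is the exact inverse of its writer on valid objects; no function
## in the package relies on file row order beyond the stored id lists.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read a labelled expression (or methylation) matrix
#'
#' The matrix file is TSV with a header row of sample ids and gene ids in
#' the first column; the label file is two-column TSV (`sample_id`,
#' `label`) with labels `group_A` / `group_N`.  Samples present in the
#' matrix but absent from the label file are an error, as are duplicate
#' ids, non-numeric cells and missing values.
#'
#' @param matrix_path Path to the gene-by-sample TSV matrix.
#' @param labels_path Path to the two-column label TSV.
#' @return A [labeled_expression()] object.
#' @export
read_labeled_expression <- function(matrix_path, labels_path) {
  raw <- .read_tsv(matrix_path, colClasses = "character")
  if (ncol(raw) < 2) stop("matrix file needs a gene id column and >=1 sample")
  gene_ids <- raw[[1]]
  .assert_unique(gene_ids, "gene ids")
  .assert_unique(colnames(raw)[-1], "sample ids")
  values <- matrix(NA_real_, nrow(raw), ncol(raw) - 1,
                   dimnames = list(gene_ids, colnames(raw)[-1]))
  for (j in 2:ncol(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !(raw[[j]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column %s",
                   raw[[j]][bad[1]], bad[1], gene_ids[bad[1]],
                   colnames(raw)[j]), call. = FALSE)
    values[, j - 1] <- v
  }
  lab <- .read_tsv(labels_path, header = FALSE, colClasses = "character")
  if (ncol(lab) < 2) stop("label file must have two columns")
  labels <- setNames(lab[[2]], lab[[1]])
  labeled_expression(values, labels)
}

#' Write a labelled expression matrix
#'
#' @param x A [labeled_expression()] object.
#' @param matrix_path,labels_path Output file paths.
#' @return Invisibly, `x`.
#' @export
write_labeled_expression <- function(x, matrix_path, labels_path) {
  stopifnot(inherits(x, "labeled_expression"))
  df <- data.frame(gene_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(x$labels), unname(x$labels)), labels_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read an edge list as a motif prior or PPI matrix
#'
#' The file holds TSV triples (`source`, `target`, `weight`) with no
#' header.  For `kind = "motif"` the result is a dense binary TF-by-gene
#' matrix (any listed pair is an edge; absent pairs are 0).  For
#' `kind = "ppi"` pairs are undirected: the matrix is symmetrised and the
#' diagonal set to 1.  An empty file yields an empty object.
#'
#' @param path Path to the TSV edge list.
#' @param kind `"motif"` or `"ppi"`.
#' @return A [motif_prior()] or [ppi_matrix()] object.
#' @export
read_edge_list <- function(path, kind = c("motif", "ppi")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1)) == 0) {
    empty <- matrix(0, 0, 0)
    if (kind == "motif")
      return(structure(list(adjacency = matrix(0, 0, 0,
        dimnames = list(character(), character()))), class = "motif_prior"))
    return(structure(list(adjacency = matrix(0, 0, 0,
      dimnames = list(character(), character()))), class = "ppi_matrix"))
  }
  df <- .read_tsv(path, header = FALSE)
  if (ncol(df) < 3) df[[3]] <- 1
  src <- as.character(df[[1]]); tgt <- as.character(df[[2]])
  w <- as.numeric(df[[3]])
  if (anyNA(w)) stop("non-numeric edge weight in ", path)
  if (any(w < 0)) stop("negative edge weight in ", path)
  if (kind == "motif") {
    if (any(src == tgt)) stop("self-loop in motif edge list: ",
                              src[which(src == tgt)[1]])
    tfs <- sort(unique(src)); genes <- sort(unique(tgt))
    adj <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
    adj[cbind(src, tgt)] <- as.numeric(w > 0)
    return(motif_prior(adj))
  }
  tfs <- sort(unique(c(src, tgt)))
  adj <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  adj[cbind(src, tgt)] <- w
  adj <- pmax(adj, t(adj))
  diag(adj) <- 1
  ppi_matrix(adj)
}

#' Write an edge list
#'
#' Inverse of [read_edge_list()]: writes the nonzero entries of a motif
#' prior or PPI matrix as TSV triples.  For a PPI matrix only the upper
#' triangle is written, diagonal included (so TFs without off-diagonal
#' interactions keep their identity through a round trip).
#'
#' @param x A [motif_prior()] or [ppi_matrix()] object.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_edge_list <- function(x, path) {
  adj <- x$adjacency
  if (inherits(x, "ppi_matrix")) adj[lower.tri(adj)] <- 0
  idx <- which(adj != 0, arr.ind = TRUE)
  df <- data.frame(src = rownames(adj)[idx[, 1]],
                   tgt = colnames(adj)[idx[, 2]],
                   w = format(adj[idx], digits = 17, trim = TRUE))
  write.table(df[order(df$src, df$tgt), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Write a regulatory network as full-precision TSV triples
#'
#' Weights are serialised with 17 significant digits (shortest
#' round-trippable decimal for doubles), so `read_network(write_network(x))`
#' reproduces weights to well under 1e-12.
#'
#' @param network A [regulatory_network()] object.
#' @param path Output path.
#' @return Invisibly, `network`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  w <- network$weights
  df <- data.frame(tf = rep(rownames(w), times = ncol(w)),
                   gene = rep(colnames(w), each = nrow(w)),
                   weight = sprintf("%.17g", as.vector(w)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(network)
}

#' Read a regulatory network from TSV triples
#'
#' @param path Path written by [write_network()] (or any TSV of
#'   `tf, gene, weight` triples covering a complete TF-by-gene grid).
#' @return A [regulatory_network()] object.
#' @export
read_network <- function(path) {
  df <- .read_tsv(path, header = FALSE)
  if (ncol(df) != 3) stop("network file must have 3 columns (tf, gene, weight)")
  tfs <- unique(as.character(df[[1]]))
  genes <- unique(as.character(df[[2]]))
  w <- matrix(NA_real_, length(tfs), length(genes),
              dimnames = list(tfs, genes))
  w[cbind(as.character(df[[1]]), as.character(df[[2]]))] <- as.numeric(df[[3]])
  if (anyNA(w)) stop("network file does not cover the full TF x gene grid")
  regulatory_network(w)
}

#' Read CNV segments in seg format
#'
#' Accepts TCGA level-3 style segment tables: columns `sample`, `chrom`,
#' `start`, `end`, optionally `num_mark`, and `seg_mean` (log R ratio).
#' Coordinates are taken as 0-based half-open.
#'
#' @param path Path to a tab-separated seg file with header.
#' @return A data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `log_r`, validated (start < end; no overlapping segments within a
#'   sample and chromosome).
#' @export
read_cnv_segments <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) == 6) df <- df[, -5]
  if (ncol(df) != 5)
    stop("seg file must have columns sample, chrom, start, end[, num_mark], seg_mean")
  names(df) <- c("sample", "chrom", "start", "end", "log_r")
  cnv_segment_table(df)
}

#' Validate a CNV segment table
#'
#' @param df Data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `log_r`.
#' @return The validated data.frame with class `"cnv_segment_table"`.
#' @export
cnv_segment_table <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("sample", "chrom", "start", "end", "log_r") %in% names(df)))
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$log_r <- as.numeric(df$log_r)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("malformed segment (start >= end) at row %d", bad[1]))
  for (key in split(seq_len(nrow(df)), paste(df$sample, df$chrom))) {
    if (length(key) < 2) next
    seg <- df[key, ][order(df$start[key]), ]
    if (any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping segments within sample ", seg$sample[1],
           " on ", seg$chrom[1])
  }
  class(df) <- c("cnv_segment_table", "data.frame")
  df
}
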