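#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd var median pnorm phyper pt p.adjust quantile
#'   setNames rnorm rbinom runif lm.fit model.matrix
#' @importFrom utils read.delim write.table head combn
NULL

## The two abstract subtype labels used throughout the package.  Any
## biological naming (e.g. angiogenic / non-angiogenic tumour subtypes)
## is an alias applied at presentation time only.
GROUP_LEVELS <- c("group_A", "group_N")

## The six activation/repression classes plus the "none" sink.
GENE_CLASSES <- c("A+", "A-", "A+;N-", "N+;A-", "N-", "N+", "none")

.assert_unique <- function(x, what) {
  if (anyDuplicated(x))
    stop("duplicate ", what, ": ",
         paste(unique(x[duplicated(x)]), collapse = ", "), call. = FALSE)
}

#' Labelled expression matrix
#'
#' Bundle a genes-by-samples matrix of (log-scale) expression values with a
#' two-level subtype label per sample.  This is the substrate for subtype
#' co-expression and for every per-gene two-group test in the package.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param labels Named character vector mapping every sample id to
#'   `"group_A"` or `"group_N"`.  Order need not match `values`.
#' @return An object of class `"labeled_expression"`: a list with elements
#'   `values` (matrix) and `labels` (character vector aligned to the matrix
#'   columns).
#' @export
labeled_expression <- function(values, labels) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("missing values in expression matrix are not allowed")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  .assert_unique(rownames(values), "gene ids")
  .assert_unique(colnames(values), "sample ids")
  labels <- unlist(labels)
  missing <- setdiff(colnames(values), names(labels))
  if (length(missing))
    stop("no subtype label for sample(s): ", paste(missing, collapse = ", "))
  labels <- labels[colnames(values)]
  bad <- setdiff(unique(labels), GROUP_LEVELS)
  if (length(bad))
    stop("labels must be one of ", paste(GROUP_LEVELS, collapse = "/"),
         "; found: ", paste(bad, collapse = ", "))
  if (!all(GROUP_LEVELS %in% labels))
    stop("both label groups must be non-empty")
  structure(list(values = values, labels = labels),
            class = "labeled_expression")
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat(sprintf("labeled_expression: %d genes x %d samples (%d group_A, %d group_N)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "group_A"), sum(x$labels == "group_N")))
  invisible(x)
}

#' @export
dim.labeled_expression <- function(x) dim(x$values)

#' Restrict an expression matrix to one subtype group
#'
#' @param x A [labeled_expression()] object.
#' @param group `"group_A"` or `"group_N"`.
#' @return Numeric matrix of the group's samples.
#' @export
group_values <- function(x, group = GROUP_LEVELS) {
  stopifnot(inherits(x, "labeled_expression"))
  group <- match.arg(group)
  x$values[, x$labels == group, drop = FALSE]
}

#' Regulatory network of inferred edge weights
#'
#' A TFs-by-genes real-valued matrix of edge confidence scores in z-score
#' units, the output of [infer_network()] and the input to network
#' comparison.
#'
#' @param weights Numeric matrix with TF rownames and gene colnames; all
#'   values finite.
#' @return An object of class `"regulatory_network"` wrapping the matrix.
#' @export
regulatory_network <- function(weights) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || !all(is.finite(weights)))
    stop("network weights must be finite numeric values")
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("network needs TF rownames and gene colnames")
  .assert_unique(rownames(weights), "tf ids")
  .assert_unique(colnames(weights), "gene ids")
  structure(list(weights = weights), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d TFs x %d genes, weights in [%.3g, %.3g]\n",
              nrow(x$weights), ncol(x$weights),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Binary motif prior
#'
#' TFs-by-genes 0/1 adjacency giving the sequence-derived candidate edges
#' ("routes for communication") that seed network inference.
#'
#' @param adjacency Numeric or logical matrix with entries in `{0, 1}`, TF
#'   rownames, gene colnames.
#' @return An object of class `"motif_prior"`.
#' @export
motif_prior <- function(adjacency) {
  adjacency <- as.matrix(adjacency) * 1
  if (!all(adjacency %in% c(0, 1)))
    stop("motif prior entries must be 0 or 1")
  if ((nrow(adjacency) > 0 && is.null(rownames(adjacency))) ||
      (ncol(adjacency) > 0 && is.null(colnames(adjacency))))
    stop("motif prior needs TF rownames and gene colnames")
  .assert_unique(rownames(adjacency), "tf ids")
  .assert_unique(colnames(adjacency), "gene ids")
  structure(list(adjacency = adjacency), class = "motif_prior")
}

#' @export
print.motif_prior <- function(x, ...) {
  cat(sprintf("motif_prior: %d TFs x %d genes, %d edges\n",
              nrow(x$adjacency), ncol(x$adjacency), sum(x$adjacency)))
  invisible(x)
}

#' TF-TF interaction matrix
#'
#' Symmetric non-negative TF-by-TF adjacency (protein-protein interaction
#' evidence) with unit diagonal by convention.
#'
#' @param adjacency Symmetric numeric matrix with identical row/col TF
#'   names; the diagonal is forced to 1.
#' @return An object of class `"ppi_matrix"`.
#' @export
ppi_matrix <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency)))
    stop("PPI matrix must be symmetric")
  if (any(adjacency < 0)) stop("PPI weights must be non-negative")
  if (is.null(rownames(adjacency))) stop("PPI matrix needs TF names")
  if (!identical(rownames(adjacency), colnames(adjacency)))
    stop("PPI row and column names must agree")
  .assert_unique(rownames(adjacency), "tf ids")
  diag(adjacency) <- 1
  structure(list(adjacency = adjacency), class = "ppi_matrix")
}

#' @export
print.ppi_matrix <- function(x, ...) {
  cat(sprintf("ppi_matrix: %d TFs, %d off-diagonal interactions\n",
              nrow(x$adjacency),
              sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

#' Subtype-specific edge set
#'
#' A labelled set of (TF, gene) edges defining one subtype-specific
#' subnetwork, together with the TF and gene universes of the parent
#' networks (so that zero out-degrees are well-defined).
#'
#' @param label `"group_A"` or `"group_N"`.
#' @param edges Two-column data.frame (`tf`, `gene`) of edges.
#' @param tf_ids,gene_ids Character vectors: the id universes the edges are
#'   resolved against.
#' @return An object of class `"edge_set"`.
#' @export
edge_set <- function(label = GROUP_LEVELS, edges, tf_ids, gene_ids) {
  label <- match.arg(label)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    names(edges)[1:2] <- c("tf", "gene")
    edges$tf <- as.character(edges$tf)
    edges$gene <- as.character(edges$gene)
    if (!all(edges$tf %in% tf_ids))
      stop("edge TF not in universe: ",
           paste(setdiff(edges$tf, tf_ids), collapse = ", "))
    if (!all(edges$gene %in% gene_ids))
      stop("edge gene not in universe: ",
           paste(setdiff(edges$gene, gene_ids), collapse = ", "))
    if (anyDuplicated(paste(edges$tf, edges$gene)))
      stop("duplicate edges in edge set")
  } else {
    edges <- data.frame(tf = character(), gene = character())
  }
  structure(list(label = label, edges = edges,
                 tf_ids = as.character(tf_ids),
                 gene_ids = as.character(gene_ids)),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set [%s]: %d edges, %d TFs with >=1 edge, %d target genes\n",
              x$label, nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$gene))))
  invisible(x)
}

#' Per-TF out-degrees of an edge set
#'
#' @param x An [edge_set()] object.
#' @return Named integer vector over the full TF universe (zeros included).
#' @export
out_degrees <- function(x) {
  stopifnot(inherits(x, "edge_set"))
  k <- table(factor(x$edges$tf, levels = x$tf_ids))
  setNames(as.integer(k), x$tf_ids)
}

#' Total number of edges in an edge set
#'
#' @param x An [edge_set()] object.
#' @return Integer edge count.
#' @export
n_edges <- function(x) nrow(x$edges)

#' Genes targeted by at least one edge
#'
#' @param x An [edge_set()] object.
#' @return Character vector of targeted gene ids.
#' @export
targeted_genes <- function(x) unique(x$edges$gene)
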