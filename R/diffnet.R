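## Comparison of the two inferred networks: subtype-specific edge-set
## selection by the CDF-product rule, six-class gene classification, TF
## rewiring enrichment and combinatorial co-targeting tests.

#' Map an edge weight to a support probability
#'
#' Applies the standard normal cumulative distribution function to a
#' z-score edge weight, giving the probability that the edge is
#' "supported" (or, applied to a weight difference, "different").
#'
#' @param z Finite numeric vector of z-scores.
#' @return `pnorm(z)`, values in (0, 1).
#' @export
edge_probability <- function(z) {
  stopifnot(all(is.finite(z)))
  pnorm(z)
}

#' Extract subtype-specific subnetworks
#'
#' An edge (i, j) is assigned to the group_A subnetwork when
#' `pnorm(W_A) * pnorm(W_A - W_N) > cutoff` -- it must be both
#' well-supported in the group_A network and more supported there than in
#' the group_N network -- and symmetrically for group_N.  The inequality
#' is strict, and for any `cutoff >= 0.5` the two sets are provably
#' disjoint (the two difference factors are `p` and `1 - p`).
#'
#' @param w_a,w_n [regulatory_network()] objects with identical TF and
#'   gene ids in identical order.
#' @param cutoff Probability-product threshold in (0, 1); default 0.8.
#' @return List with elements `group_A` and `group_N`, each an
#'   [edge_set()].
#' @export
extract_subnetworks <- function(w_a, w_n, cutoff = 0.8) {
  stopifnot(inherits(w_a, "regulatory_network"),
            inherits(w_n, "regulatory_network"))
  if (!identical(dimnames(w_a$weights), dimnames(w_n$weights)))
    stop("the two networks must share TF and gene ids in the same order")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  WA <- w_a$weights; WN <- w_n$weights
  pa <- pnorm(WA) * pnorm(WA - WN) > cutoff
  pn <- pnorm(WN) * pnorm(WN - WA) > cutoff
  tfs <- rownames(WA); genes <- colnames(WA)
  mk <- function(mask, label) {
    idx <- which(mask, arr.ind = TRUE)
    edge_set(label, data.frame(tf = tfs[idx[, 1]], gene = genes[idx[, 2]]),
             tf_ids = tfs, gene_ids = genes)
  }
  out <- list(group_A = mk(pa, "group_A"), group_N = mk(pn, "group_N"))
  if (cutoff >= 0.5 && any(pa & pn))
    stop("internal error: subnetworks overlap at cutoff >= 0.5")
  out
}

#' Classify target genes into six activation/repression classes
#'
#' Crosses each gene's targeting pattern (group_A only, group_N only, or
#' both subnetworks) with the sign of its differential-expression
#' t-statistic (positive = higher in group_A) to assign one of the six
#' mutually exclusive classes; untargeted genes, and targeted genes with a
#' zero statistic, fall in `"none"`.
#'
#' \describe{
#'   \item{A+}{targeted only in group_A, higher expression in group_A
#'     (putative activation in group_A)}
#'   \item{A-}{targeted only in group_A, higher in group_N (repression)}
#'   \item{A+;N-}{targeted in both, higher in group_A}
#'   \item{N+;A-}{targeted in both, higher in group_N}
#'   \item{N-}{targeted only in group_N, higher in group_A}
#'   \item{N+}{targeted only in group_N, higher in group_N}
#' }
#'
#' @param edges_a,edges_n The two [edge_set()]s from
#'   [extract_subnetworks()].
#' @param de Named numeric vector of per-gene t-statistics (group_A
#'   positive orientation), or a data.frame with columns `gene` and `t`
#'   as produced by [per_gene_ttest()].  Must cover all targeted genes.
#' @return Data.frame of class `"gene_class_table"` with columns `gene`
#'   and `class`, one row per gene in the union gene universe.
#' @export
classify_target_genes <- function(edges_a, edges_n, de) {
  stopifnot(inherits(edges_a, "edge_set"), inherits(edges_n, "edge_set"))
  if (is.data.frame(de)) de <- setNames(de$t, de$gene)
  genes <- union(edges_a$gene_ids, edges_n$gene_ids)
  in_a <- genes %in% targeted_genes(edges_a)
  in_n <- genes %in% targeted_genes(edges_n)
  targeted <- in_a | in_n
  missing <- setdiff(genes[targeted], names(de))
  if (length(missing))
    stop("targeted gene(s) missing from differential-expression table: ",
         paste(missing, collapse = ", "))
  t_val <- de[genes]
  cls <- rep("none", length(genes))
  pos <- !is.na(t_val) & t_val > 0
  neg <- !is.na(t_val) & t_val < 0
  cls[in_a & !in_n & pos] <- "A+"
  cls[in_a & !in_n & neg] <- "A-"
  cls[in_a & in_n & pos] <- "A+;N-"
  cls[in_a & in_n & neg] <- "N+;A-"
  cls[!in_a & in_n & pos] <- "N-"
  cls[!in_a & in_n & neg] <- "N+"
  out <- data.frame(gene = genes, class = factor(cls, levels = GENE_CLASSES),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_class_table", "data.frame")
  out
}

#' TF rewiring enrichment between the two subnetworks
#'
#' For every TF with at least `min_edges` edges across the two
#' subnetworks, computes the edge enrichment
#' `E = (k_A / k_N) / (n_A / n_N)` (out-degrees normalised by subnetwork
#' totals; `k_N = 0` gives `E = Inf`, flagged in `e_infinite`) and an
#' upper-tail hypergeometric p-value for the imbalance: the probability of
#' drawing at least `k_A` group_A edges when `k_A + k_N` edges are drawn
#' without replacement from the pooled `n_A + n_N` subnetwork edges.  The
#' group_A tail is reported when `E > 1` and the group_N tail when
#' `E < 1`; at `E = 1` the smaller of the two tails is reported.
#'
#' @param edges_a,edges_n The two [edge_set()]s.
#' @param min_edges Minimum total out-degree `k_A + k_N` for a TF to be
#'   scored (small-degree TFs give unstable enrichments); default 20.
#' @return Data.frame with one row per scored TF: `tf`, `k_a`, `k_n`,
#'   `n_a`, `n_n`, `enrichment`, `e_infinite`, `p`.
#' @export
tf_edge_enrichment <- function(edges_a, edges_n, min_edges = 20) {
  stopifnot(inherits(edges_a, "edge_set"), inherits(edges_n, "edge_set"))
  n_a <- n_edges(edges_a); n_n <- n_edges(edges_n)
  if (n_a == 0 || n_n == 0)
    stop("both subnetworks must contain at least one edge")
  tfs <- union(edges_a$tf_ids, edges_n$tf_ids)
  k_a <- out_degrees(edges_a)[tfs]; k_a[is.na(k_a)] <- 0
  k_n <- out_degrees(edges_n)[tfs]; k_n[is.na(k_n)] <- 0
  keep <- (k_a + k_n) >= min_edges
  tfs <- tfs[keep]; k_a <- k_a[keep]; k_n <- k_n[keep]
  E <- (k_a / k_n) / (n_a / n_n)
  p_a <- phyper(k_a - 1, n_a, n_n, k_a + k_n, lower.tail = FALSE)
  p_n <- phyper(k_n - 1, n_n, n_a, k_a + k_n, lower.tail = FALSE)
  p <- ifelse(E > 1, p_a, ifelse(E < 1, p_n, pmin(p_a, p_n)))
  data.frame(tf = tfs, k_a = as.integer(k_a), k_n = as.integer(k_n),
             n_a = rep(n_a, length(tfs)), n_n = rep(n_n, length(tfs)),
             enrichment = as.numeric(E),
             e_infinite = is.infinite(E), p = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select key (rewired) transcription factors
#'
#' Filters the [tf_edge_enrichment()] table to TFs whose edge enrichment
#' exceeds `e_cut` (or falls below `1 / e_cut`) with hypergeometric
#' significance below `p_cut`, sorted by p ascending.
#'
#' @param records Data.frame from [tf_edge_enrichment()].
#' @param e_cut Enrichment bound (default 1.5; the reciprocal bound is
#'   applied automatically).
#' @param p_cut Significance bound (default 1e-3).
#' @return Character vector of TF ids, most significant first.
#' @export
identify_key_tfs <- function(records, e_cut = 1.5, p_cut = 1e-3) {
  stopifnot(is.data.frame(records),
            all(c("tf", "enrichment", "p") %in% names(records)))
  hit <- (records$enrichment > e_cut | records$enrichment < 1 / e_cut) &
    records$p < p_cut
  records$tf[hit][order(records$p[hit])]
}

#' Combinatorial co-targeting enrichment for TF pairs
#'
#' Tests whether genes of one activation/repression class are co-targeted
#' by a pair of TFs more often than chance, with the union of genes
#' targeted in either subnetwork as the background universe.  For a pair
#' (tf1, tf2) and a class, `n_tf1` and `n_tf2` count the class genes
#' targeted by each TF in the class's own subnetwork (group_A for classes
#' `A+`/`A-`, group_N for `N+`/`N-`), `n_both` their intersection, and
#' `p` the upper-tail hypergeometric probability of an overlap at least
#' that large.
#'
#' @param edges_a,edges_n The two [edge_set()]s.
#' @param classes A `gene_class_table` from [classify_target_genes()].
#' @param class_label One of `"A+"`, `"A-"`, `"N+"`, `"N-"`.
#' @param tf_pairs Optional two-column matrix or data.frame of TF id
#'   pairs; by default all unordered pairs of TFs with at least one
#'   class-gene target are tested.
#' @return Data.frame with columns `tf1`, `tf2`, `class`, `n_universe`,
#'   `n_tf1`, `n_tf2`, `n_both`, `p`, sorted by p.
#' @export
cotargeting_enrichment <- function(edges_a, edges_n, classes, class_label,
                                   tf_pairs = NULL) {
  stopifnot(inherits(edges_a, "edge_set"), inherits(edges_n, "edge_set"))
  if (!class_label %in% c("A+", "A-", "N+", "N-"))
    stop("class_label must be one of A+, A-, N+, N-")
  universe <- union(targeted_genes(edges_a), targeted_genes(edges_n))
  if (!length(universe)) stop("empty target universe")
  side <- if (class_label %in% c("A+", "A-")) edges_a else edges_n
  class_genes <- classes$gene[classes$class == class_label]
  ed <- side$edges[side$edges$gene %in% class_genes, ]
  tf_targets <- split(ed$gene, factor(ed$tf, levels = side$tf_ids))
  if (is.null(tf_pairs)) {
    active <- names(tf_targets)[lengths(tf_targets) > 0]
    if (length(active) < 2)
      return(data.frame(tf1 = character(), tf2 = character(),
                        class = character(), n_universe = integer(),
                        n_tf1 = integer(), n_tf2 = integer(),
                        n_both = integer(), p = numeric()))
    tf_pairs <- t(combn(active, 2))
  } else {
    tf_pairs <- as.matrix(tf_pairs)
  }
  if (any(tf_pairs[, 1] == tf_pairs[, 2]))
    stop("a co-targeting pair must consist of two distinct TFs")
  n_u <- length(universe)
  res <- lapply(seq_len(nrow(tf_pairs)), function(i) {
    t1 <- tf_pairs[i, 1]; t2 <- tf_pairs[i, 2]
    g1 <- unique(tf_targets[[t1]]); g2 <- unique(tf_targets[[t2]])
    nb <- length(intersect(g1, g2))
    p <- phyper(nb - 1, length(g2), n_u - length(g2), length(g1),
                lower.tail = FALSE)
    data.frame(tf1 = t1, tf2 = t2, class = class_label, n_universe = n_u,
               n_tf1 = length(g1), n_tf2 = length(g2), n_both = nb, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}
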