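## Per-gene two-group tests (expression, methylation, CNV) with
## Benjamini-Hochberg correction, the meta-t target-set statistic, the
## segment-to-gene CNV mapping, and the random-set null control.

#' Per-gene two-sample t-tests across a labelled matrix
#'
#' Welch (unequal-variance) two-sample t per gene, oriented group_A minus
#' group_N, with two-sided p-values and Benjamini-Hochberg adjusted FDR
#' across all testable genes.  Genes with zero variance in both groups
#' have an undefined statistic: they are flagged (`NA` t/p) and excluded
#' from the FDR ranking.  Genes that are entirely missing (`NA` in every
#' sample, as happens in methylation tables) are dropped.
#'
#' @param values Numeric gene-by-sample matrix (may contain NAs, e.g. a
#'   methylation or CNV gene-value matrix), or a [labeled_expression()]
#'   object (in which case `labels` is taken from it).
#' @param labels Named character vector of `group_A`/`group_N` labels.
#' @param var_equal Use the pooled-variance (Student) statistic instead of
#'   Welch.  Default FALSE.
#' @return Data.frame of class `"gene_stat_table"`: `gene`, `t`, `df`,
#'   `p`, `fdr`, with positive t meaning higher values in group_A.
#' @export
per_gene_ttest <- function(values, labels = NULL, var_equal = FALSE) {
  if (inherits(values, "labeled_expression")) {
    labels <- values$labels
    values <- values$values
  }
  stopifnot(is.matrix(values), !is.null(labels))
  labels <- labels[colnames(values)]
  if (anyNA(labels)) stop("every sample column needs a label")
  a <- values[, labels == "group_A", drop = FALSE]
  n <- values[, labels == "group_N", drop = FALSE]
  if (ncol(a) < 2 || ncol(n) < 2) stop("need >= 2 samples per group")
  stat <- .rowwise_welch(a, n, var_equal)
  keep <- !is.na(stat$t)
  fdr <- rep(NA_real_, nrow(values))
  fdr[keep] <- p.adjust(stat$p[keep], method = "BH")
  drop_all_na <- stat$n_a == 0 & stat$n_n == 0
  out <- data.frame(gene = rownames(values), t = stat$t, df = stat$df,
                    p = stat$p, fdr = fdr, stringsAsFactors = FALSE)
  out <- out[!drop_all_na, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_stat_table", "data.frame")
  out
}

## Vectorised two-sample t over matrix rows, NA-tolerant.
.rowwise_welch <- function(a, n, var_equal = FALSE) {
  cnt <- function(m) rowSums(!is.na(m))
  n_a <- cnt(a); n_n <- cnt(n)
  m_a <- rowMeans(a, na.rm = TRUE); m_n <- rowMeans(n, na.rm = TRUE)
  ss <- function(m, mu) rowSums((m - mu)^2, na.rm = TRUE)
  v_a <- ss(a, m_a) / pmax(n_a - 1, 1)
  v_n <- ss(n, m_n) / pmax(n_n - 1, 1)
  ok <- n_a >= 2 & n_n >= 2 & (v_a + v_n) > 0
  if (var_equal) {
    sp2 <- ((n_a - 1) * v_a + (n_n - 1) * v_n) / (n_a + n_n - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_n))
    df <- n_a + n_n - 2
  } else {
    se <- sqrt(v_a / n_a + v_n / n_n)
    df <- (v_a / n_a + v_n / n_n)^2 /
      ((v_a / n_a)^2 / (n_a - 1) + (v_n / n_n)^2 / (n_n - 1))
  }
  t_stat <- ifelse(ok, (m_a - m_n) / se, NA_real_)
  df <- ifelse(ok, df, NA_real_)
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, n_a = n_a, n_n = n_n)
}

#' Meta-t statistic for a gene set
#'
#' Summarises whether a set of genes is coordinately shifted relative to
#' the rest of the genome: a Welch two-sample t comparing the member
#' genes' per-gene t-statistics against the non-members' (sample-variance
#' convention), with a two-sided p-value.  Used for expression,
#' methylation, CNV and treatment layers alike.
#'
#' @param stats A `gene_stat_table` from [per_gene_ttest()], or a named
#'   numeric vector of per-gene t-statistics.
#' @param members Character vector of member gene ids; after intersection
#'   with the table it must contain at least 2 genes and leave at least 2
#'   non-members.
#' @param set_id Optional label carried into the result.
#' @return One-row data.frame: `set_id`, `n_set`, `n_rest`, `meta_t`,
#'   `p`.
#' @export
set_meta_t <- function(stats, members, set_id = NA_character_) {
  tv <- if (is.data.frame(stats)) setNames(stats$t, stats$gene) else stats
  tv <- tv[!is.na(tv)]
  members <- unique(members)
  in_set <- names(tv) %in% members
  n_set <- sum(in_set); n_rest <- sum(!in_set)
  if (n_set < 2) stop("fewer than 2 member genes present in the table")
  if (n_rest < 2) stop("set covers (almost) the whole table; no background left")
  x <- tv[in_set]; y <- tv[!in_set]
  vx <- var(x); vy <- var(y)
  se <- sqrt(vx / n_set + vy / n_rest)
  meta_t <- (mean(x) - mean(y)) / se
  df <- (vx / n_set + vy / n_rest)^2 /
    ((vx / n_set)^2 / (n_set - 1) + (vy / n_rest)^2 / (n_rest - 1))
  data.frame(set_id = set_id, n_set = n_set, n_rest = n_rest,
             meta_t = meta_t, p = 2 * pt(-abs(meta_t), df),
             stringsAsFactors = FALSE)
}

#' Map CNV segments to per-gene, per-sample values
#'
#' For each gene and sample, the length-weighted mean log R ratio of all
#' segments overlapping the gene's span; `NA` where no segment overlaps.
#' Coordinates are 0-based half-open on both sides and must share one
#' assembly.  Downstream differential-CNV analysis feeds the resulting
#' matrix to [per_gene_ttest()] and [set_meta_t()].
#'
#' @param segments A `cnv_segment_table` (see [read_cnv_segments()]).
#' @param gene_coords Data.frame with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @return Numeric gene-by-sample matrix.
#' @export
cnv_gene_values <- function(segments, gene_coords) {
  stopifnot(all(c("sample", "chrom", "start", "end", "log_r") %in%
                  names(segments)),
            all(c("gene", "chrom", "start", "end") %in% names(gene_coords)))
  if (any(gene_coords$start >= gene_coords$end))
    stop("gene coordinates must satisfy start < end")
  samples <- unique(segments$sample)
  genes <- GenomicRanges::GRanges(
    gene_coords$chrom,
    IRanges::IRanges(gene_coords$start + 1, gene_coords$end))
  out <- matrix(NA_real_, nrow(gene_coords), length(samples),
                dimnames = list(gene_coords$gene, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, ]
    gr <- GenomicRanges::GRanges(seg$chrom,
                                 IRanges::IRanges(seg$start + 1, seg$end))
    ## chromosomes absent from one side are legitimate (no overlap);
    ## silence the seqlevel-mismatch warning
    hits <- suppressWarnings(GenomicRanges::findOverlaps(genes, gr))
    if (!length(hits)) next
    ov <- IRanges::width(suppressWarnings(IRanges::pintersect(
      genes[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)])))
    w_lr <- seg$log_r[S4Vectors::subjectHits(hits)] * ov
    num <- tapply(w_lr, S4Vectors::queryHits(hits), sum)
    den <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(num)), s] <- as.numeric(num) / as.numeric(den)
  }
  out
}

#' Random-set null distribution for the meta-t statistic
#'
#' Draws seeded uniform random gene sets of a given size from the stat
#' table and computes their meta-t values, giving an empirical null
#' against which an observed set statistic can be judged (a guard against
#' results that would arise for arbitrary gene sets).
#'
#' @param stats A `gene_stat_table` or named t-statistic vector.
#' @param set_size Number of genes per random set (>= 2).
#' @param n_reps Number of random sets (>= 100).
#' @param seed Integer seed.
#' @return List of class `"meta_t_null"`: `meta_t` (numeric vector of
#'   null statistics) and `p_value(observed)`, a function returning the
#'   empirical two-sided p of an observed meta-t (add-one estimator).
#' @export
random_set_null <- function(stats, set_size, n_reps, seed) {
  stopifnot(set_size >= 2, n_reps >= 100)
  tv <- if (is.data.frame(stats)) setNames(stats$t, stats$gene) else stats
  tv <- tv[!is.na(tv)]
  ids <- names(tv)
  null <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      set_meta_t(tv, sample(ids, set_size))$meta_t
    }, numeric(1))
  })
  structure(list(
    meta_t = null,
    p_value = function(observed) {
      (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
    }), class = "meta_t_null")
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `p.adjust(method = "BH")`, exposed so every layer of
#' the pipeline corrects p-values the same way.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted FDR values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
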