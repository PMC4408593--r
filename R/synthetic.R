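## Seeded generators for every input the pipeline consumes: truth networks
## with planted rewired TFs, two-subtype expression, noisy motif prior and
## PPI, methylation with a global subtype shift, CNV segments, treatment
## experiments and promoter sequences.  All generators are pure functions
## of their parameters and seed.

#' Simulate a two-group regulatory truth
#'
#' Draws uniform random target sets per TF, then plants `n_rewired`
#' "rewired" TFs whose target sets differ between the two group truths:
#' each rewired TF loses a `rewire_fraction` of its targets in one group
#' (alternating which group is diminished, so both subtype-specific
#' subnetworks are populated), or, with `rewire_mode = "replace"`, has
#' that fraction replaced by fresh genes in the group_N truth.  The
#' default `"loss"` mode produces the out-degree asymmetry that the
#' downstream edge-enrichment statistic is designed to detect; the
#' degree-preserving `"replace"` mode rewires targeting without changing
#' out-degrees.  Non-rewired TFs have identical target sets in both
#' groups.
#'
#' Each targeted gene is also assigned a ground-truth
#' activation/repression class consistent with its targeting pattern
#' (`A+`/`A-` if targeted only in the group_A truth, `A+;N-`/`N+;A-` if
#' in both, `N-`/`N+` if only group_N; direction drawn 50/50), used to
#' plant class-level effects in the omics and treatment generators.
#'
#' @param n_tf,n_genes Numbers of TFs and genes.
#' @param n_rewired Number of rewired TFs (<= n_tf).
#' @param targets_per_tf Out-degree of every TF in its full truth.
#'   Default 75.
#' @param rewire_fraction Fraction of a rewired TF's targets affected
#'   (default 0.5; the planted sets always differ by >= 30% when
#'   `rewire_fraction >= 0.3`).
#' @param seed Integer seed.
#' @param rewire_mode `"loss"` (default) or `"replace"`; see above.
#' @return List of class `"synthetic_truth"`: `truth_a`, `truth_n`
#'   (binary TF-by-gene matrices), `rewired_tfs`, `true_class` (named
#'   vector over genes), `tf_ids`, `gene_ids`, and the generating
#'   parameters.
#' @export
simulate_truth <- function(n_tf, n_genes, n_rewired, targets_per_tf = 75,
                           rewire_fraction = 0.5, seed = 1,
                           rewire_mode = c("loss", "replace")) {
  rewire_mode <- match.arg(rewire_mode)
  if (n_rewired > n_tf) stop("n_rewired must not exceed n_tf")
  if (targets_per_tf > n_genes) stop("targets_per_tf must not exceed n_genes")
  if (rewire_fraction < 0 || rewire_fraction >= 1)
    stop("rewire_fraction must be in [0, 1)")
  tf_ids <- sprintf("TF%03d", seq_len(n_tf))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  with_seed(seed, {
    truth_a <- matrix(0, n_tf, n_genes, dimnames = list(tf_ids, gene_ids))
    for (i in seq_len(n_tf))
      truth_a[i, sample(n_genes, targets_per_tf)] <- 1
    truth_n <- truth_a
    rewired <- sort(sample(n_tf, n_rewired))
    n_flip <- round(rewire_fraction * targets_per_tf)
    for (k in seq_along(rewired)) {
      i <- rewired[k]
      tg <- which(truth_a[i, ] == 1)
      flip <- sample(tg, n_flip)
      if (rewire_mode == "replace") {
        fresh <- sample(which(truth_a[i, ] == 0), n_flip)
        truth_n[i, flip] <- 0
        truth_n[i, fresh] <- 1
      } else if (k %% 2 == 1) {
        truth_n[i, flip] <- 0      # group_A keeps more targets
      } else {
        truth_a[i, flip] <- 0      # group_N keeps more targets
      }
    }
    in_a <- colSums(truth_a) > 0
    in_n <- colSums(truth_n) > 0
    cls <- rep("none", n_genes)
    flip_sign <- runif(n_genes) < 0.5
    cls[in_a & !in_n] <- ifelse(flip_sign[in_a & !in_n], "A+", "A-")
    cls[in_a & in_n] <- ifelse(flip_sign[in_a & in_n], "A+;N-", "N+;A-")
    cls[!in_a & in_n] <- ifelse(flip_sign[!in_a & in_n], "N-", "N+")
    structure(list(truth_a = truth_a, truth_n = truth_n,
                   rewired_tfs = tf_ids[rewired],
                   true_class = setNames(cls, gene_ids),
                   tf_ids = tf_ids, gene_ids = gene_ids,
                   targets_per_tf = targets_per_tf,
                   rewire_fraction = rewire_fraction,
                   rewire_mode = rewire_mode, seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d TFs x %d genes, %d rewired (%s mode)\n",
              length(x$tf_ids), length(x$gene_ids), length(x$rewired_tfs),
              x$rewire_mode))
  invisible(x)
}

#' Simulate two-subtype expression from a truth network
#'
#' Linear-Gaussian regulation: each TF has a latent standard-normal
#' activity per sample; a regulated gene equals `beta_reg` times the
#' standardised mean activity of its group-truth regulators (unit
#' variance regardless of in-degree) plus Gaussian noise; unregulated
#' genes are pure noise.  Because rewired TFs keep identical marginal
#' activity across groups, the subtype difference lives entirely in the
#' targeting structure -- differential targeting drives differential
#' target co-expression without differential TF expression.
#'
#' @param truth A [simulate_truth()] object.
#' @param n_a,n_n Samples per group (>= 10 for the default study design).
#' @param beta_reg Regulatory effect size in noise-SD units (default 1).
#' @param noise_sd Residual SD (default 1).
#' @param seed Integer seed.
#' @return A [labeled_expression()] with genes `G*` and samples
#'   `A001..`/`N001..`.
#' @export
simulate_expression <- function(truth, n_a, n_n, beta_reg = 1,
                                noise_sd = 1, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_g <- length(truth$gene_ids); n_tf <- length(truth$tf_ids)
  samples <- c(sprintf("A%03d", seq_len(n_a)), sprintf("N%03d", seq_len(n_n)))
  labels <- setNames(rep(GROUP_LEVELS, c(n_a, n_n)), samples)
  with_seed(seed, {
    gen_group <- function(adj, n) {
      act <- matrix(rnorm(n_tf * n), n_tf, n)
      vals <- matrix(rnorm(n_g * n, sd = noise_sd), n_g, n)
      reg <- crossprod(adj, act) / sqrt(pmax(colSums(adj), 1))
      vals + beta_reg * reg * (colSums(adj) > 0)
    }
    va <- gen_group(truth$truth_a, n_a)
    vn <- gen_group(truth$truth_n, n_n)
    vals <- cbind(va, vn)
    dimnames(vals) <- list(truth$gene_ids, samples)
    labeled_expression(vals, labels)
  })
}

#' Simulate a noisy motif prior and PPI from a truth
#'
#' The motif prior is the union of the two group truths with edges
#' dropped at the false-negative rate and spurious edges added at the
#' false-positive rate (per non-edge).  The PPI is a random symmetric
#' graph at the requested density in which TF pairs that co-regulate
#' (share at least 25% of the smaller target set in either truth) always
#' interact; diagonal is 1.
#'
#' @param truth A [simulate_truth()] object.
#' @param fp_rate,fn_rate Edge noise rates in [0, 1).  Defaults 0.001
#'   and 0.05.
#' @param ppi_density Off-diagonal interaction density (default 0.05).
#' @param seed Integer seed.
#' @return List with elements `prior` ([motif_prior()]) and `ppi`
#'   ([ppi_matrix()]).
#' @export
simulate_prior_and_ppi <- function(truth, fp_rate = 0.001, fn_rate = 0.05,
                                   ppi_density = 0.05, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(c(fp_rate, fn_rate, ppi_density) < 0) ||
      any(c(fp_rate, fn_rate) >= 1))
    stop("rates must be in [0, 1)")
  with_seed(seed, {
    adj <- pmax(truth$truth_a, truth$truth_n)
    ones <- which(adj == 1); zeros <- which(adj == 0)
    if (fn_rate > 0)
      adj[ones[runif(length(ones)) < fn_rate]] <- 0
    if (fp_rate > 0)
      adj[zeros[runif(length(zeros)) < fp_rate]] <- 1
    n_tf <- length(truth$tf_ids)
    ppi <- matrix(0, n_tf, n_tf,
                  dimnames = list(truth$tf_ids, truth$tf_ids))
    rand <- matrix(rbinom(n_tf^2, 1, ppi_density), n_tf)
    ppi <- pmax(ppi, rand * upper.tri(rand))
    shared <- tcrossprod(truth$truth_a) + tcrossprod(truth$truth_n)
    deg <- truth$targets_per_tf
    corr_pairs <- shared >= 0.25 * deg
    ppi[corr_pairs & upper.tri(ppi)] <- 1
    ppi <- pmax(ppi, t(ppi))
    diag(ppi) <- 1
    list(prior = motif_prior(adj), ppi = ppi_matrix(ppi))
  })
}

#' Simulate methylation and CNV layers
#'
#' Methylation: standard-normal gene-by-sample values with a global
#' `+mu_meth` shift in every group_A sample (emulating a genome-wide
#' methylation increase in one subtype), minus `class_meth_offset` for
#' genes targeted by rewired TFs in the group_A truth (so those targets
#' gain comparatively less methylation).  CNV: per-sample segment tables
#' tiling a toy genome of 5 chromosomes; segment log R ratios are
#' Gaussian noise except over a planted region whose genes gain
#' `+cnv_effect` in group_A samples.
#'
#' @param truth A [simulate_truth()] object.
#' @param n_a,n_n Samples per group.
#' @param mu_meth Global group_A methylation shift (default 0.3).
#' @param class_meth_offset Offset subtracted for rewired-TF targets
#'   (default 0).
#' @param cnv_effect Planted segment log-R shift in group_A (default
#'   0.3).
#' @param seed Integer seed.
#' @return List: `methylation` ([labeled_expression()] of methylation
#'   values), `segments` (a `cnv_segment_table` covering all samples),
#'   `gene_coords` (data.frame `gene`, `chrom`, `start`, `end`),
#'   `cnv_genes` (ids inside the planted region), `labels`.
#' @export
simulate_omics <- function(truth, n_a, n_n, mu_meth = 0.3,
                           class_meth_offset = 0, cnv_effect = 0.3,
                           seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_g <- length(truth$gene_ids)
  samples <- c(sprintf("A%03d", seq_len(n_a)), sprintf("N%03d", seq_len(n_n)))
  labels <- setNames(rep(GROUP_LEVELS, c(n_a, n_n)), samples)
  with_seed(seed, {
    meth <- matrix(rnorm(n_g * (n_a + n_n)), n_g, n_a + n_n,
                   dimnames = list(truth$gene_ids, samples))
    meth[, seq_len(n_a)] <- meth[, seq_len(n_a)] + mu_meth
    rew_targets <- colSums(
      truth$truth_a[truth$rewired_tfs, , drop = FALSE]) > 0
    if (class_meth_offset != 0)
      meth[rew_targets, seq_len(n_a)] <-
        meth[rew_targets, seq_len(n_a)] - class_meth_offset

    ## toy genome: 5 chromosomes, genes laid down every 10 kb, 2 kb long
    chrom <- paste0("chr", rep(1:5, each = ceiling(n_g / 5))[seq_len(n_g)])
    offset <- (seq_len(n_g) - 1) %% ceiling(n_g / 5)
    gene_coords <- data.frame(gene = truth$gene_ids, chrom = chrom,
                              start = offset * 10000,
                              end = offset * 10000 + 2000,
                              stringsAsFactors = FALSE)
    chrom_len <- 10000 * ceiling(n_g / 5) + 10000
    ## planted region: first half of chr1
    cnv_genes <- gene_coords$gene[gene_coords$chrom == "chr1" &
                                    gene_coords$end <= chrom_len / 2]
    segs <- list()
    for (s in seq_along(samples)) {
      for (ch in paste0("chr", 1:5)) {
        brk <- sort(sample(seq(1000, chrom_len - 1000, by = 1000), 9))
        bounds <- c(0, brk, chrom_len)
        lr <- rnorm(length(bounds) - 1, sd = 0.1)
        seg <- data.frame(sample = samples[s], chrom = ch,
                          start = bounds[-length(bounds)], end = bounds[-1],
                          log_r = lr, stringsAsFactors = FALSE)
        if (ch == "chr1" && labels[s] == "group_A") {
          inside <- seg$start < chrom_len / 2
          seg$log_r[inside] <- seg$log_r[inside] + cnv_effect
        }
        segs[[length(segs) + 1]] <- seg
      }
    }
    list(methylation = labeled_expression(meth, labels),
         segments = cnv_segment_table(do.call(rbind, segs)),
         gene_coords = gene_coords, cnv_genes = cnv_genes, labels = labels)
  })
}

#' Simulate a treatment experiment with class-level shifts
#'
#' Control arrays are pure Gaussian noise; treated arrays add a
#' class-specific shift `delta` to all genes of each shifted class.
#'
#' @param classes A `gene_class_table` (observed or ground-truth).
#' @param shifted_classes Named numeric vector, e.g. `c("A+" = -0.5)`:
#'   expression shift applied to each named class in treated arrays.
#' @param n_treated,n_control Array counts (>= 5 each).
#' @param noise_sd Residual SD (default 1).
#' @param seed Integer seed.
#' @return List: `values` (gene-by-array matrix), `design` (data.frame
#'   `array`, `role`).
#' @export
simulate_treatment <- function(classes, shifted_classes, n_treated,
                               n_control, noise_sd = 1, seed = 1) {
  stopifnot(n_treated >= 5, n_control >= 5)
  genes <- classes$gene
  arrays <- c(sprintf("T%03d", seq_len(n_treated)),
              sprintf("C%03d", seq_len(n_control)))
  role <- rep(c("treated", "control"), c(n_treated, n_control))
  with_seed(seed, {
    vals <- matrix(rnorm(length(genes) * length(arrays), sd = noise_sd),
                   length(genes), length(arrays),
                   dimnames = list(genes, arrays))
    for (cl in names(shifted_classes)) {
      idx <- classes$class == cl
      vals[idx, role == "treated"] <-
        vals[idx, role == "treated"] + shifted_classes[[cl]]
    }
    list(values = vals,
         design = data.frame(array = arrays, role = role,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate promoter sequences with planted motif sites
#'
#' Generates i.i.d. background promoter contigs (one per gene) and
#' inserts a single exact consensus site of the designated motif at a
#' uniform random position of each planted gene's window.  The TSS is
#' placed so that the whole contig is the `[-upstream, +downstream)`
#' promoter window on the "+" strand.
#'
#' @param pwms List of [pwm()] objects.
#' @param n_genes Number of promoters.
#' @param planted Named character vector `gene_id -> motif_id`; names
#'   must be a subset of the generated gene ids `P0001..`.
#' @param window_len Contig length (default 1000; the TSS sits at
#'   position 750 so the window is upstream 750 / downstream 250).
#' @param base_freq Background base frequencies (A, C, G, T); default
#'   uniform.
#' @param seed Integer seed.
#' @return List: `sequences` (a `Biostrings::DNAStringSet`), `tss`
#'   (BED-like data.frame `chrom`, `start`, `end`, `gene`, `score`,
#'   `strand`), `planted_at` (named integer vector of 0-based insert
#'   offsets for planted genes).
#' @export
simulate_promoters <- function(pwms, n_genes, planted = character(),
                               window_len = 1000,
                               base_freq = rep(0.25, 4), seed = 1) {
  gene_ids <- sprintf("P%04d", seq_len(n_genes))
  if (length(planted) && !all(names(planted) %in% gene_ids))
    stop("planted genes must be among the generated gene ids")
  pwm_ids <- vapply(pwms, function(p) p$motif_id, character(1))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste(sample(bases, window_len, replace = TRUE, prob = base_freq),
            collapse = "")
    }, character(1))
    planted_at <- integer(0)
    for (g in names(planted)) {
      p <- pwms[[match(planted[[g]], pwm_ids)]]
      if (is.null(p)) stop("unknown motif id: ", planted[[g]])
      cons <- paste(bases[apply(p$probs, 1, which.max)], collapse = "")
      pos <- sample.int(window_len - nchar(cons) + 1, 1)  # 1-based
      i <- match(g, gene_ids)
      substr(seqs[i], pos, pos + nchar(cons) - 1) <- cons
      planted_at[g] <- pos - 1L
    }
    sequences <- Biostrings::DNAStringSet(setNames(seqs, gene_ids))
    tss <- data.frame(chrom = gene_ids, start = 750L, end = 751L,
                      gene = gene_ids, score = 0L, strand = "+",
                      stringsAsFactors = FALSE)
    list(sequences = sequences, tss = tss, planted_at = planted_at)
  })
}
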