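## Motif-prior construction: PWM log-likelihood-ratio scoring of promoter
## windows on both strands, with a per-motif score threshold calibrated by
## random sampling of the genomic background.

#' Position weight matrix
#'
#' @param motif_id Identifier of the motif.
#' @param probs Positions-by-4 matrix of base probabilities (columns A,
#'   C, G, T); each row must sum to 1 within 1e-9.
#' @param tf_ids Character vector of the TF name(s) the motif maps to
#'   (dimeric motifs map to several).
#' @return Object of class `"pwm"`.
#' @export
pwm <- function(motif_id, probs, tf_ids) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1) stop("PWM needs at least one position")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("each PWM row must sum to 1")
  if (!length(tf_ids)) stop("a PWM must map to at least one TF")
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, probs = probs,
                 tf_ids = as.character(tf_ids)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: %d positions -> TF(s) %s\n", x$motif_id,
              nrow(x$probs), paste(x$tf_ids, collapse = ", ")))
  invisible(x)
}

#' Read JASPAR-style PFM files
#'
#' Parses count matrices in JASPAR text format (a `>id name` header line
#' followed by four `A [ ... ]`-style rows, or four bare count rows) and
#' converts counts to probabilities with a +0.01 pseudo-count per cell.
#' Dimeric motif names containing `::` are split into multiple TF ids.
#'
#' @param path Path to a file holding one or more PFM records.
#' @param pseudo_count Added to every count cell before normalisation
#'   (default 0.01).
#' @return List of [pwm()] objects.
#' @export
read_jaspar_pfm <- function(path, pseudo_count = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PFM records (no '>' header) in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]]
    motif_id <- hdr[1]
    name <- if (length(hdr) > 1) hdr[2] else hdr[1]
    body <- lines[(starts[i] + 1):ends[i]]
    if (length(body) != 4)
      stop("PFM record ", motif_id, " must have 4 matrix rows")
    counts <- t(vapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("^[ACGTacgt]\\s*\\[|\\]", "",
                                           body[1])), "\\s+")[[1]]))))
    counts <- counts + pseudo_count
    probs <- t(counts) / colSums(counts)
    pwm(motif_id, probs, strsplit(name, "::")[[1]])
  })
}

#' Background nucleotide model
#'
#' @param freq Length-4 numeric (A, C, G, T), all positive, summing to 1.
#' @return Object of class `"background_model"`.
#' @export
background_model <- function(freq = rep(0.25, 4)) {
  freq <- as.numeric(freq)
  if (length(freq) != 4 || any(freq <= 0) || abs(sum(freq) - 1) > 1e-9)
    stop("background must be 4 positive frequencies summing to 1")
  structure(list(freq = setNames(freq, c("A", "C", "G", "T"))),
            class = "background_model")
}

#' Empirical background from a genome
#'
#' Genome-wide nucleotide frequencies (A, C, G, T; other letters
#' ignored).
#'
#' @param genome A `Biostrings::DNAStringSet`.
#' @return A [background_model()].
#' @export
background_from_genome <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                                          drop = FALSE])
  background_model(counts / sum(counts))
}

## Encode a DNA string as integers 1..4 (A,C,G,T); others NA.
.encode_dna <- function(s) {
  v <- strsplit(chartr("acgt", "ACGT", as.character(s)), "")[[1]]
  match(v, c("A", "C", "G", "T"))
}

#' Log-likelihood-ratio score of one site
#'
#' `sum over positions of log(p_motif(base) / p_background(base))`
#' (natural log).  A zero motif probability at an observed base gives
#' `-Inf` (the site can never pass a finite threshold).
#'
#' @param pwm A [pwm()] object.
#' @param site DNA string of exactly the PWM's length, containing only
#'   A/C/G/T.
#' @param bg A [background_model()].
#' @return Scalar score.
#' @export
score_site <- function(pwm, site, bg = background_model()) {
  code <- .encode_dna(site)
  if (length(code) != nrow(pwm$probs))
    stop("site length ", length(code), " != PWM length ", nrow(pwm$probs))
  if (anyNA(code)) stop("site may contain only A, C, G, T")
  lr <- log(pwm$probs) - rep(log(bg$freq), each = nrow(pwm$probs))
  sum(lr[cbind(seq_along(code), code)])
}

## Score every window start of an encoded sequence; windows containing N
## (NA codes) are skipped (score NA).  Returns a numeric vector of length
## length(code) - m + 1 (empty if shorter than the motif).
.scan_scores <- function(code, lr) {
  m <- nrow(lr)
  L <- length(code)
  if (L < m) return(numeric(0))
  n_win <- L - m + 1
  total <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  for (p in seq_len(m)) {
    idx <- code[p:(p + n_win - 1)]
    bad <- is.na(idx)
    ok <- ok & !bad
    contrib <- lr[p, ifelse(bad, 1L, idx)]
    total <- total + contrib
  }
  total[!ok] <- NA_real_
  total
}

## Log-ratio lookup matrix for a pwm under a background.
.log_ratio <- function(pwm, bg) {
  log(pwm$probs) - rep(log(bg$freq), each = nrow(pwm$probs))
}

#' Calibrate a per-motif score threshold on the genomic background
#'
#' Draws `n_samples` windows of the motif's length uniformly at random
#' from the genome (windows containing non-ACGT letters are redrawn),
#' scores them, and returns the empirical `(1 - p_cut)` quantile: a site
#' scoring strictly above the threshold is significant at `p < p_cut`
#' against the genomic background.  Deterministic given the seed.
#'
#' @param pwm A [pwm()] object.
#' @param genome A `Biostrings::DNAStringSet` of background sequence.
#' @param n_samples Number of background draws (default 1e6).
#' @param p_cut Significance level (default 1e-5).
#' @param seed Integer seed.
#' @param bg A [background_model()]; default the genome's empirical base
#'   frequencies.
#' @return Scalar threshold.  Warns when `n_samples * p_cut < 10` (the
#'   tail quantile is then unstable).
#' @export
calibrate_threshold <- function(pwm, genome, n_samples = 1e6,
                                p_cut = 1e-5, seed = 1,
                                bg = background_from_genome(genome)) {
  if (n_samples * p_cut < 10)
    warning("n_samples * p_cut < 10; threshold quantile is unstable")
  m <- nrow(pwm$probs)
  lens <- Biostrings::width(genome)
  if (!any(lens >= m)) stop("genome too short for the motif length")
  lr <- .log_ratio(pwm, bg)
  ## flatten contigs into one code vector, NA-padded so windows cannot
  ## straddle a contig boundary
  flat <- unlist(lapply(seq_along(genome), function(i)
    c(.encode_dna(genome[[i]]), rep(NA_integer_, m))))
  n_starts <- length(flat) - m + 1
  with_seed(seed, {
    scores <- numeric(n_samples)
    filled <- 0L
    while (filled < n_samples) {
      n_draw <- as.integer(min(2 * (n_samples - filled) + 1000, 200000))
      starts <- ceiling(runif(n_draw) * n_starts)
      idx <- outer(starts, 0:(m - 1), "+")
      code <- matrix(flat[idx], n_draw, m)
      ok <- !apply(is.na(code), 1, any)
      code[is.na(code)] <- 1L
      sc <- rowSums(matrix(lr[cbind(rep(seq_len(m), each = n_draw),
                                    as.vector(code))], n_draw, m))
      sc <- sc[ok]
      take <- min(length(sc), n_samples - filled)
      if (take > 0) scores[(filled + 1):(filled + take)] <- sc[seq_len(take)]
      filled <- filled + take
    }
    k <- max(1L, floor(n_samples * p_cut))
    sort(scores, decreasing = TRUE)[k]
  })
}

#' Promoter window set
#'
#' Reads a BED-like TSS table (`chrom`, `start`, `end`, `gene`, `score`,
#' `strand`; 0-based half-open) and attaches the promoter window.  The
#' TSS is `start` for "+" genes and `end - 1` for "-" genes; the window
#' spans `upstream` bases 5' of the TSS and `downstream` bases 3' of it
#' on the gene's strand.
#'
#' @param tss Data.frame in BED-like layout, or a path to such a TSV
#'   (no header).
#' @param upstream,downstream Window extent in bp (defaults 750 and
#'   250).
#' @return Data.frame of class `"promoter_set"`: `gene`, `chrom`,
#'   `strand`, `tss`, plus attributes `upstream`/`downstream`.
#' @export
promoter_set <- function(tss, upstream = 750, downstream = 250) {
  if (is.character(tss) && length(tss) == 1)
    tss <- read.delim(tss, header = FALSE, stringsAsFactors = FALSE)
  tss <- as.data.frame(tss)
  if (ncol(tss) < 6) stop("TSS table needs 6 BED columns")
  names(tss)[1:6] <- c("chrom", "start", "end", "gene", "score", "strand")
  if (!all(tss$strand %in% c("+", "-")))
    stop('strand must be "+" or "-"')
  if (upstream <= 0 || downstream <= 0)
    stop("window bounds must be positive")
  out <- data.frame(gene = as.character(tss$gene),
                    chrom = as.character(tss$chrom),
                    strand = tss$strand,
                    tss = ifelse(tss$strand == "+", tss$start, tss$end - 1),
                    stringsAsFactors = FALSE)
  if (any(out$tss < 0)) stop("TSS coordinates must be >= 0")
  .assert_unique(out$gene, "gene ids")
  attr(out, "upstream") <- upstream
  attr(out, "downstream") <- downstream
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Build the TF-to-gene motif prior by promoter scanning
#'
#' For every motif, calibrates a background score threshold with
#' [calibrate_threshold()] and scans each gene's promoter window on both
#' strands; the edge (TF, gene) is set for every TF the motif maps to
#' whenever any window start position scores strictly above the
#' threshold.  Multiple motifs mapping to one TF are combined by logical
#' OR.  TFs and genes absent from the expressed sets are dropped (counts
#' reported via `message`).  Windows truncated at contig boundaries are
#' scanned as far as the sequence allows; window positions containing
#' non-ACGT letters are skipped.
#'
#' @param pwms List of [pwm()] objects.
#' @param promoters A [promoter_set()].
#' @param genome A `Biostrings::DNAStringSet` holding the contigs named
#'   in the promoter table.
#' @param expressed_tfs,expressed_genes Ids retained in the output; by
#'   default all TFs named by the motifs and all promoter genes.
#' @param p_cut Background significance level (default 1e-5).
#' @param n_samples Background draws per motif (default 1e6).
#' @param seed Integer seed for calibration.
#' @param bg Optional [background_model()]; default empirical genome
#'   frequencies.
#' @param thresholds Optional named numeric vector (motif id ->
#'   threshold) bypassing calibration, e.g. to reuse thresholds
#'   calibrated on another assembly.
#' @return A [motif_prior()] over `expressed_tfs` x `expressed_genes`.
#' @export
build_motif_prior <- function(pwms, promoters, genome,
                              expressed_tfs = NULL, expressed_genes = NULL,
                              p_cut = 1e-5, n_samples = 1e6, seed = 1,
                              bg = background_from_genome(genome),
                              thresholds = NULL) {
  stopifnot(inherits(promoters, "promoter_set"))
  all_tfs <- sort(unique(unlist(lapply(pwms, function(p) p$tf_ids))))
  if (is.null(expressed_tfs)) expressed_tfs <- all_tfs
  if (is.null(expressed_genes)) expressed_genes <- promoters$gene
  up <- attr(promoters, "upstream"); down <- attr(promoters, "downstream")
  contig_names <- names(genome)
  genes <- promoters$gene
  adj <- matrix(0, length(all_tfs), length(genes),
                dimnames = list(all_tfs, genes))
  ## pre-extract promoter windows (strand-aware, 5'->3' on gene strand)
  windows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    ci <- match(promoters$chrom[g], contig_names)
    if (is.na(ci)) stop("contig not in genome: ", promoters$chrom[g])
    clen <- Biostrings::width(genome)[ci]
    tss <- promoters$tss[g]
    if (promoters$strand[g] == "+") {
      s0 <- tss - up; e0 <- tss + down          # [s0, e0) genomic
    } else {
      s0 <- tss - down + 1; e0 <- tss + up + 1
    }
    s0c <- max(s0, 0); e0c <- min(e0, clen)
    if (s0c != s0 || e0c != e0)
      message("promoter window truncated at contig boundary for gene ",
              genes[g])
    if (e0c <= s0c) { windows[[g]] <- Biostrings::DNAString(""); next }
    w <- Biostrings::subseq(genome[[ci]], start = s0c + 1, end = e0c)
    if (promoters$strand[g] == "-") w <- Biostrings::reverseComplement(w)
    windows[[g]] <- w
  }
  win_codes <- lapply(windows, .encode_dna)
  for (p in pwms) {
    thr <- if (!is.null(thresholds) && p$motif_id %in% names(thresholds)) {
      thresholds[[p$motif_id]]
    } else {
      calibrate_threshold(p, genome, n_samples = n_samples,
                          p_cut = p_cut, seed = seed, bg = bg)
    }
    lr <- .log_ratio(p, bg)
    lr_rc <- .log_ratio(reverse_complement_pwm(p), bg)
    for (g in seq_along(genes)) {
      code <- win_codes[[g]]
      hit <- any(.scan_scores(code, lr) > thr, na.rm = TRUE) ||
        any(.scan_scores(code, lr_rc) > thr, na.rm = TRUE)
      if (hit) adj[p$tf_ids, genes[g]] <- 1
    }
  }
  drop_tf <- setdiff(all_tfs, expressed_tfs)
  drop_gene <- setdiff(genes, expressed_genes)
  if (length(drop_tf))
    message(length(drop_tf), " TF(s) without expression dropped from prior")
  if (length(drop_gene))
    message(length(drop_gene), " gene(s) without expression dropped from prior")
  keep_tf <- intersect(all_tfs, expressed_tfs)
  keep_gene <- intersect(genes, expressed_genes)
  motif_prior(adj[keep_tf, keep_gene, drop = FALSE])
}

#' Reverse complement of a PWM
#'
#' @param x A [pwm()] object.
#' @return A [pwm()] scoring the reverse-complement strand.
#' @export
reverse_complement_pwm <- function(x) {
  probs <- x$probs[rev(seq_len(nrow(x$probs))), rev(1:4), drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  pwm(x$motif_id, probs, x$tf_ids)
}
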