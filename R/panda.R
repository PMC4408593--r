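## Message-passing network inference: iterative agreement-seeking between
## a binary motif prior (candidate TF->gene edges), TF-TF interaction
## evidence, and subtype-specific gene co-expression.  Edge weights are
## refined by two agreement signals -- how strongly a TF's interaction
## profile supports an edge ("responsibility") and how strongly the target
## gene's co-expression profile supports it ("availability") -- until the
## mean absolute change of the weight matrix falls below a tolerance.

#' Inference configuration
#'
#' @param alpha Update step in (0, 1]; the fraction of each iteration's
#'   agreement estimate blended into the evolving matrices.  Default 0.25.
#' @param tol Convergence threshold on the mean absolute change of the
#'   TF-by-gene weight matrix between iterations.  Default 1e-3.  An
#'   infinite tolerance skips the update entirely, returning the
#'   normalised prior.
#' @param max_iter Iteration cap; non-convergence returns the last weights
#'   with a warning.  Default 200.  Zero also skips the update.
#' @param damp_diagonal Stabilise the co-regulation and co-targeting
#'   co-updates by inflating their diagonals (see Details).  Default TRUE;
#'   switching it off exposes the raw co-update, which diverges on all but
#'   trivial inputs and is retained for illustration only.
#' @param anneal Growth rate of the diagonal inflation, in units of
#'   `alpha * iteration`.  Larger values anneal the co-updates faster,
#'   freezing the similarity structure earlier.  Default 5.
#' @details
#' The Tanimoto agreement of two vectors scales with their norms, so the
#' raw fixed-point iteration has positive feedback: each TF's edge block
#' can inflate without bound.  The standard remedy, used here, replaces the
#' diagonal of the TF-TF co-regulation and gene-gene co-targeting updates
#' with an exponentially growing multiple of the off-diagonal spread
#' (`column sd * n * exp(anneal * alpha * step)`).  As the diagonal grows
#' the agreement terms reduce to the identity map, annealing the iteration
#' into a fixed point.
#' @return A list of class `"panda_config"`.
#' @export
panda_config <- function(alpha = 0.25, tol = 1e-3, max_iter = 200,
                         damp_diagonal = TRUE, anneal = 5) {
  stopifnot(alpha > 0, alpha <= 1, tol > 0, max_iter >= 0, anneal > 0)
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter,
                 damp_diagonal = damp_diagonal, anneal = anneal),
            class = "panda_config")
}

#' Standardise an evidence matrix
#'
#' Returns `(Zrow + Zcol) / sqrt(2)` where `Zrow` is the entrywise row
#' z-score and `Zcol` the column z-score (sample, n-1, standard
#' deviations).  Rows or columns with zero variance contribute 0.  This
#' puts all three evidence channels (prior, interactions, co-expression)
#' on a common z-score scale before agreement-seeking.
#'
#' @param m Finite numeric matrix.
#' @return Matrix of the same shape (dimnames preserved).
#' @export
normalize_evidence <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(is.finite(m)))
  zr <- t(scale(t(m)))
  zc <- scale(m)
  zr[!is.finite(zr)] <- 0
  zc[!is.finite(zc)] <- 0
  matrix((as.vector(zr) + as.vector(zc)) / sqrt(2),
         nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Tanimoto agreement of two vectors
#'
#' `(x . y) / sqrt(||x||^2 + ||y||^2 - |x . y|)`, the continuous extension
#' of the Tanimoto set-overlap coefficient; 0 when the denominator is 0.
#' Unlike a correlation it scales with the vectors' magnitude, which is
#' what lets well-supported edges accumulate weight across iterations.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar agreement.
#' @export
tanimoto <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- sum(x * y)
  den <- sqrt(max(sum(x^2) + sum(y^2) - abs(d), 0))
  if (den == 0) return(0)
  d / den
}

## Tanimoto agreement between every row of X and every row of Y.
.tanimoto_rows <- function(X, Y) {
  D <- tcrossprod(X, Y)
  den <- sqrt(pmax(outer(rowSums(X^2), rowSums(Y^2), "+") - abs(D), 0))
  out <- D / den
  out[!is.finite(out)] <- 0
  out
}

## Replace the diagonal of a similarity update with an exponentially
## growing multiple of the off-diagonal column spread.
.damp_diagonal <- function(M, alpha, step, anneal) {
  n <- nrow(M)
  if (n < 2) {
    M[1, 1] <- max(abs(M[1, 1]), 1) * exp(anneal * alpha * step)
    return(M)
  }
  diag(M) <- NA
  if (n == 2) {
    ## too few off-diagonal entries for a spread estimate: use their
    ## magnitude so the annealing still dominates
    s <- pmax(abs(M[2, 1]), abs(M[1, 2]), 1)
  } else {
    s <- apply(M, 2, sd, na.rm = TRUE) * sqrt((n - 2) / (n - 1))
  }
  diag(M) <- s * n * exp(anneal * alpha * step)
  M
}

#' Infer a subtype-specific regulatory network
#'
#' Runs the message-passing iteration on one subtype's expression samples.
#' The three evidence channels are first standardised with
#' [normalize_evidence()]; each iteration then computes, for every
#' (TF i, gene j) pair, the responsibility `R_ij` (agreement between TF
#' i's interaction profile and gene j's incoming-edge profile) and the
#' availability `A_ij` (agreement between TF i's outgoing-edge profile and
#' gene j's co-expression profile), and blends `(R + A) / 2` into the
#' weight matrix with step `alpha`.  The interaction and co-expression
#' matrices are co-updated toward the network's co-regulation (TF-TF) and
#' co-targeting (gene-gene) agreement so that all three data types are
#' drawn toward consensus.
#'
#' @param prior A [motif_prior()].
#' @param ppi A [ppi_matrix()] over the same TFs.
#' @param expr A [labeled_expression()]; only the samples of `group` are
#'   used.  Genes must match the prior's columns.  At least 3 samples are
#'   required so Pearson correlation is defined.
#' @param group Which subtype's samples to use.
#' @param config A [panda_config()].
#' @return A [regulatory_network()] with weights in z-score units, plus
#'   attributes `iterations` (integer) and `convergence` (numeric vector
#'   of the mean absolute change per iteration).
#' @export
infer_network <- function(prior, ppi, expr, group = GROUP_LEVELS,
                          config = panda_config()) {
  stopifnot(inherits(prior, "motif_prior"), inherits(ppi, "ppi_matrix"),
            inherits(expr, "labeled_expression"),
            inherits(config, "panda_config"))
  group <- match.arg(group)
  if (!identical(rownames(prior$adjacency), rownames(ppi$adjacency)))
    stop("prior and PPI TF ids must be identical and in the same order")
  if (!identical(colnames(prior$adjacency), rownames(expr$values)))
    stop("prior gene ids must match the expression matrix rows")
  vals <- group_values(expr, group)
  if (ncol(vals) < 3) stop("need >= 3 samples in ", group)

  zero_var <- apply(vals, 1, sd) == 0
  if (any(zero_var))
    message(sum(zero_var), " zero-variance gene(s); correlations set to 0")
  C0 <- suppressWarnings(cor(t(vals)))
  C0[!is.finite(C0)] <- 0
  diag(C0) <- 1

  W <- normalize_evidence(prior$adjacency)
  P <- normalize_evidence(ppi$adjacency)
  C <- normalize_evidence(C0)

  if (config$max_iter == 0 || is.infinite(config$tol)) {
    net <- regulatory_network(W)
    attr(net, "iterations") <- 0L
    attr(net, "convergence") <- numeric(0)
    return(net)
  }

  alpha <- config$alpha
  deltas <- numeric(0)
  for (step in seq_len(config$max_iter)) {
    R <- .tanimoto_rows(P, t(W))        # responsibility, TF x gene
    A <- .tanimoto_rows(W, C)           # availability,  TF x gene (C symmetric)
    W_new <- (1 - alpha) * W + alpha * (R + A) / 2
    deltas[step] <- mean(abs(W_new - W))
    W <- W_new
    S <- .tanimoto_rows(W, W)           # co-regulation, TF x TF
    Q <- .tanimoto_rows(t(W), t(W))     # co-targeting, gene x gene
    if (config$damp_diagonal) {
      S <- .damp_diagonal(S, alpha, step, config$anneal)
      Q <- .damp_diagonal(Q, alpha, step, config$anneal)
    }
    P <- (1 - alpha) * P + alpha * S
    C <- (1 - alpha) * C + alpha * Q
    if (deltas[step] < config$tol) break
  }
  if (deltas[length(deltas)] >= config$tol)
    warning("did not converge in ", config$max_iter,
            " iterations (last mean |dW| = ",
            signif(deltas[length(deltas)], 3), ")")
  net <- regulatory_network(W)
  attr(net, "iterations") <- length(deltas)
  attr(net, "convergence") <- deltas
  net
}

#' Stability of inferred weights under prior jackknifing
#'
#' Repeatedly removes a fraction of motif-prior edges uniformly at random,
#' re-infers the network, and summarises how stable the edge weights are:
#' per-edge mean and sd across replicates, and each replicate's Spearman
#' rank correlation with the full-data network.
#'
#' @param prior,ppi,expr,group,config As in [infer_network()].
#' @param drop_fraction Fraction of prior edges removed per replicate, in
#'   (0, 1).
#' @param n_reps Number of jackknife replicates.
#' @param seed Integer seed; the report is deterministic given it.
#' @return A list of class `"stability_report"`: `edge_mean`, `edge_sd`
#'   (TF-by-gene matrices), `rank_cor` (numeric vector, one per
#'   replicate), `full` (the full-data [regulatory_network()]).
#' @export
jackknife_stability <- function(prior, ppi, expr, group = GROUP_LEVELS,
                                drop_fraction, n_reps, seed,
                                config = panda_config()) {
  stopifnot(drop_fraction > 0, drop_fraction < 1, n_reps >= 1)
  group <- match.arg(group)
  edges <- which(prior$adjacency == 1)
  if (length(edges) < 2) stop("prior must have at least 2 edges")
  n_drop <- floor(drop_fraction * length(edges))
  full <- infer_network(prior, ppi, expr, group, config)
  acc <- matrix(0, nrow(full$weights), ncol(full$weights))
  acc2 <- acc
  rank_cor <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      adj <- prior$adjacency
      if (n_drop > 0) adj[sample(edges, n_drop)] <- 0
      rep_prior <- structure(list(adjacency = adj), class = "motif_prior")
      net <- infer_network(rep_prior, ppi, expr, group, config)
      acc <- acc + net$weights
      acc2 <- acc2 + net$weights^2
      rank_cor[r] <- cor(as.vector(net$weights), as.vector(full$weights),
                         method = "spearman")
    }
  })
  edge_mean <- acc / n_reps
  edge_sd <- sqrt(pmax(acc2 / n_reps - edge_mean^2, 0))
  dimnames(edge_mean) <- dimnames(edge_sd) <- dimnames(full$weights)
  structure(list(edge_mean = edge_mean, edge_sd = edge_sd,
                 rank_cor = rank_cor, full = full),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %d replicates, median rank cor %.3f\n",
              length(x$rank_cor), median(x$rank_cor)))
  invisible(x)
}

## Evaluate an expression with a local, restorable RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
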