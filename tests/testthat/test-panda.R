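test_that("evidence normalisation matches the hand-computed convention", {
  ## constant matrix: zero variance everywhere -> all zeros
  expect_equal(normalize_evidence(matrix(3, 4, 5)),
               matrix(0, 4, 5), ignore_attr = TRUE)

  ## 2x2 case, sample-sd convention: entry (1,1) of [[1,2],[3,4]]
  ## Zrow = (1 - 1.5)/sd(c(1,2)) = -0.7071, Zcol = (1 - 2)/sd(c(1,3)) = -0.7071
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  z <- normalize_evidence(m)
  expect_equal(z[1, 1], (-1 / sqrt(2) - 1 / sqrt(2)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(z[1, 1], -1, tolerance = 1e-12)

  ## shift invariance
  expect_equal(normalize_evidence(m + 100), z, tolerance = 1e-12)
})

test_that("tanimoto agreement matches direct arithmetic", {
  expect_equal(tanimoto(c(1, 0), c(1, 0)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)  # zero denominator
})

## A deterministic 2 TF x 3 gene x 6 sample fixture used across blocks.
panda_fixture <- function() {
  prior <- motif_prior(matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
                              dimnames = list(c("T1", "T2"),
                                              c("g1", "g2", "g3"))))
  ppi <- ppi_matrix(matrix(c(1, 0.5, 0.5, 1), 2, 2,
                           dimnames = list(c("T1", "T2"), c("T1", "T2"))))
  set.seed(99)
  vals <- matrix(rnorm(18), 3, 6,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:6)))
  expr <- labeled_expression(
    vals, setNames(rep(c("group_A", "group_N"), each = 3), paste0("s", 1:6)))
  list(prior = prior, ppi = ppi, expr = expr)
}

test_that("with the update skipped the output is the normalised prior", {
  fx <- panda_fixture()
  skip_cfg <- panda_config(max_iter = 0)
  net <- infer_network(fx$prior, fx$ppi, fx$expr, "group_A", skip_cfg)
  expect_identical(net$weights, normalize_evidence(fx$prior$adjacency))
  ## infinite tolerance skips as well
  net2 <- infer_network(fx$prior, fx$ppi, fx$expr, "group_A",
                        panda_config(tol = Inf))
  expect_identical(net2$weights, net$weights)
})

test_that("a single update step matches an independent element-wise oracle", {
  fx <- panda_fixture()
  alpha <- 0.25
  net <- suppressWarnings(
    infer_network(fx$prior, fx$ppi, fx$expr, "group_A",
                  panda_config(alpha = alpha, tol = 1e-12, max_iter = 1)))

  ## oracle: scalar computation from the definitions, using only the
  ## exported vector-level tanimoto and normalisation
  W0 <- normalize_evidence(fx$prior$adjacency)
  P0 <- normalize_evidence(fx$ppi$adjacency)
  vals <- group_values(fx$expr, "group_A")
  C0 <- normalize_evidence(cor(t(vals)))
  W1 <- W0
  for (i in 1:2) for (j in 1:3) {
    r_ij <- tanimoto(P0[i, ], W0[, j])
    a_ij <- tanimoto(W0[i, ], C0[, j])
    W1[i, j] <- (1 - alpha) * W0[i, j] + alpha * (r_ij + a_ij) / 2
  }
  expect_lt(max(abs(net$weights - W1)), 1e-10)
  expect_warning(
    infer_network(fx$prior, fx$ppi, fx$expr, "group_A",
                  panda_config(tol = 1e-12, max_iter = 1)),
    "did not converge")
})

test_that("inference is deterministic and label-symmetric on shared data", {
  fx <- panda_fixture()
  cfg <- panda_config()
  n1 <- infer_network(fx$prior, fx$ppi, fx$expr, "group_A", cfg)
  n2 <- infer_network(fx$prior, fx$ppi, fx$expr, "group_A", cfg)
  expect_identical(n1$weights, n2$weights)

  ## identical expression in the two groups -> identical networks
  vals <- group_values(fx$expr, "group_A")
  both <- cbind(vals, vals)
  colnames(both) <- paste0("s", 1:6)
  expr_dup <- labeled_expression(
    both, setNames(rep(c("group_A", "group_N"), each = 3), paste0("s", 1:6)))
  na <- infer_network(fx$prior, fx$ppi, expr_dup, "group_A", cfg)
  nn <- infer_network(fx$prior, fx$ppi, expr_dup, "group_N", cfg)
  expect_identical(na$weights, nn$weights)
})

test_that("permuting gene order permutes the output columns identically", {
  set.seed(3)
  tr <- simulate_truth(6, 40, 2, targets_per_tf = 8, seed = 5)
  ex <- simulate_expression(tr, 12, 12, seed = 6)
  pp <- simulate_prior_and_ppi(tr, 0, 0, 0.2, seed = 7)
  cfg <- panda_config(max_iter = 5, tol = 1e-9)
  base <- suppressWarnings(infer_network(pp$prior, pp$ppi, ex, "group_A", cfg))

  perm <- sample(length(tr$gene_ids))
  prior_p <- motif_prior(pp$prior$adjacency[, perm])
  ex_p <- labeled_expression(ex$values[perm, ], ex$labels)
  perm_net <- suppressWarnings(infer_network(prior_p, pp$ppi, ex_p, "group_A", cfg))
  expect_equal(perm_net$weights, base$weights[, perm], tolerance = 1e-12)
})

test_that("convergence is monotone after the first iterations", {
  tr <- simulate_truth(10, 80, 2, targets_per_tf = 10, seed = 11)
  ex <- simulate_expression(tr, 15, 15, seed = 12)
  pp <- simulate_prior_and_ppi(tr, 0, 0, 0.2, seed = 13)
  net <- infer_network(pp$prior, pp$ppi, ex, "group_A", panda_config())
  deltas <- attr(net, "convergence")
  expect_gt(length(deltas), 3)
  later <- deltas[-(1:3)]
  if (length(later) > 1)
    expect_true(all(diff(later) <= 0.1 * later[-length(later)]))
  expect_lt(deltas[length(deltas)], 1e-3)
})

test_that("jackknife stability is seeded and degenerates correctly", {
  tr <- simulate_truth(8, 60, 2, targets_per_tf = 10, seed = 21)
  ex <- simulate_expression(tr, 12, 12, seed = 22)
  pp <- simulate_prior_and_ppi(tr, 0, 0, 0.2, seed = 23)
  cfg <- panda_config(max_iter = 5, tol = 1e-9)

  ## drop fraction small enough that zero edges are removed
  n_edges <- sum(pp$prior$adjacency)
  rep0 <- suppressWarnings(jackknife_stability(pp$prior, pp$ppi, ex, "group_A",
                              drop_fraction = 0.5 / n_edges, n_reps = 2,
                              seed = 1, config = cfg))
  expect_equal(rep0$edge_mean, rep0$full$weights, tolerance = 1e-12)
  expect_true(all(rep0$edge_sd < 1e-12))

  r1 <- suppressWarnings(
    jackknife_stability(pp$prior, pp$ppi, ex, "group_A", 0.1, 3, 42, cfg))
  r2 <- suppressWarnings(
    jackknife_stability(pp$prior, pp$ppi, ex, "group_A", 0.1, 3, 42, cfg))
  expect_identical(r1$edge_mean, r2$edge_mean)
  expect_identical(r1$rank_cor, r2$rank_cor)
})

test_that("jackknifed replicates stay rank-correlated with the full fit", {
  tr <- simulate_truth(20, 100, 3, targets_per_tf = 12, seed = 31)
  ex <- simulate_expression(tr, 20, 20, seed = 32)
  pp <- simulate_prior_and_ppi(tr, 0, 0, 0.1, seed = 33)
  rep10 <- jackknife_stability(pp$prior, pp$ppi, ex, "group_A",
                               drop_fraction = 0.1, n_reps = 10, seed = 5)
  expect_gt(median(rep10$rank_cor), 0.8)
})
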