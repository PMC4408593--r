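test_that("simulated truth respects requested structure and seed", {
  tr <- simulate_truth(10, 100, 3, targets_per_tf = 12, seed = 4)
  ## every TF keeps its full out-degree in at least one group truth, and
  ## non-rewired TFs in both
  expect_true(all(pmax(rowSums(tr$truth_a), rowSums(tr$truth_n)) == 12))
  non_rew <- setdiff(rownames(tr$truth_a), tr$rewired_tfs)
  expect_true(all(rowSums(tr$truth_a[non_rew, ]) == 12))
  expect_true(all(rowSums(tr$truth_n[non_rew, ]) == 12))
  expect_length(tr$rewired_tfs, 3)

  ## rewired TFs differ by >= 30% of targets; others are identical
  diff_frac <- rowSums(abs(tr$truth_a - tr$truth_n)) / 12
  expect_true(all(diff_frac[tr$rewired_tfs] >= 0.3))
  expect_true(all(diff_frac[setdiff(rownames(tr$truth_a),
                                    tr$rewired_tfs)] == 0))

  ## determinism / sensitivity
  expect_identical(simulate_truth(10, 100, 3, 12, seed = 4)$truth_a,
                   tr$truth_a)
  expect_false(identical(simulate_truth(10, 100, 3, 12, seed = 5)$truth_a,
                         tr$truth_a))

  ## no rewiring -> identical group truths
  tr0 <- simulate_truth(10, 100, 0, targets_per_tf = 12, seed = 4)
  expect_identical(tr0$truth_a, tr0$truth_n)

  ## replace mode keeps out-degrees on both sides
  trr <- simulate_truth(10, 100, 3, 12, seed = 4, rewire_mode = "replace")
  expect_identical(unname(rowSums(trr$truth_n)), rep(12, 10))
  expect_error(simulate_truth(5, 100, 9, 12), "n_rewired")
})

test_that("expression generator reproduces the attenuation law", {
  tr <- simulate_truth(20, 300, 0, targets_per_tf = 15, seed = 7)
  beta <- 1.2; noise <- 0.8
  ex <- simulate_expression(tr, 200, 10, beta_reg = beta,
                            noise_sd = noise, seed = 8)
  expect_identical(dim(ex$values), c(300L, 210L))
  expect_identical(simulate_expression(tr, 200, 10, beta, noise, 8)$values,
                   ex$values)

  ## cor(target, standardised regulator mean) ~ beta / sqrt(beta^2 + sd^2)
  vals <- group_values(ex, "group_A")
  ## reconstruct the regulator-mean signal from an independent draw of
  ## the same seeded stream: instead check across genes empirically via
  ## the co-target correlation implied by the model for a single shared
  ## regulator pair (exact closed form is checked on the margin below)
  expected <- beta / sqrt(beta^2 + noise^2)
  sds <- apply(vals, 1, sd)
  ## marginal variance of regulated genes is beta^2 + noise^2
  expect_equal(mean(sds[rowSums(t(tr$truth_a)) > 0]^2),
               beta^2 + noise^2, tolerance = 0.1)
  ## correlation between two genes regulated by exactly the same TF set
  ## equals the squared attenuation factor; pick such a pair if present
  reg_sets <- apply(tr$truth_a, 2, paste, collapse = "")
  dup <- which(duplicated(reg_sets) & colSums(tr$truth_a) > 0)
  if (length(dup)) {
    j <- dup[1]; i <- match(reg_sets[j], reg_sets)
    got <- cor(vals[i, ], vals[j, ])
    expect_equal(got, expected^2, tolerance = 0.12)
  }
})

test_that("prior and ppi noise rates are realised as requested", {
  tr <- simulate_truth(20, 400, 4, targets_per_tf = 20, seed = 9)
  clean <- simulate_prior_and_ppi(tr, 0, 0, 0.1, seed = 10)
  expect_identical(clean$prior$adjacency,
                   pmax(tr$truth_a, tr$truth_n))
  expect_identical(clean$ppi$adjacency, t(clean$ppi$adjacency))
  expect_identical(unname(diag(clean$ppi$adjacency)), rep(1, 20))

  fp <- 0.01; fn <- 0.2
  noisy <- simulate_prior_and_ppi(tr, fp, fn, 0.1, seed = 11)
  union_adj <- pmax(tr$truth_a, tr$truth_n)
  n1 <- sum(union_adj == 1); n0 <- sum(union_adj == 0)
  lost <- sum(union_adj == 1 & noisy$prior$adjacency == 0)
  gained <- sum(union_adj == 0 & noisy$prior$adjacency == 1)
  expect_lt(abs(lost - fn * n1), 3 * sqrt(n1 * fn * (1 - fn)) + 1)
  expect_lt(abs(gained - fp * n0), 3 * sqrt(n0 * fp * (1 - fp)) + 1)
})

test_that("omics generator plants recoverable methylation and CNV signal", {
  tr <- simulate_truth(10, 300, 2, targets_per_tf = 15, seed = 13)
  om <- simulate_omics(tr, n_a = 40, n_n = 40, mu_meth = 0.5,
                       cnv_effect = 0.4, seed = 14)

  meth_t <- per_gene_ttest(om$methylation)
  expect_gt(mean(meth_t$t), 0)           # global shift recovered

  om0 <- simulate_omics(tr, 40, 40, mu_meth = 0, cnv_effect = 0, seed = 15)
  t0 <- per_gene_ttest(om0$methylation)$t
  expect_lt(abs(mean(t0)), 3 / sqrt(length(t0)) + 0.05)

  ## CNV: genes inside the planted region carry a positive log-R shift
  vals <- cnv_gene_values(om$segments, om$gene_coords)
  cnv_t <- per_gene_ttest(vals, om$labels)
  in_reg <- cnv_t$gene %in% om$cnv_genes
  expect_gt(mean(cnv_t$t[in_reg], na.rm = TRUE), 1)
  expect_lt(abs(mean(cnv_t$t[!in_reg], na.rm = TRUE)), 0.5)
})

test_that("treatment generator is seeded and shifts only its classes", {
  classes <- data.frame(gene = sprintf("g%03d", 1:200),
                        class = factor(rep(c("A+", "none"), c(50, 150)),
                                       levels = regnetdiff:::GENE_CLASSES))
  class(classes) <- c("gene_class_table", "data.frame")
  tr1 <- simulate_treatment(classes, c("A+" = 1), 6, 6, seed = 17)
  tr2 <- simulate_treatment(classes, c("A+" = 1), 6, 6, seed = 17)
  expect_identical(tr1$values, tr2$values)
  shifted <- rowMeans(tr1$values[1:50, tr1$design$role == "treated"]) -
    rowMeans(tr1$values[1:50, tr1$design$role == "control"])
  rest <- rowMeans(tr1$values[51:200, tr1$design$role == "treated"]) -
    rowMeans(tr1$values[51:200, tr1$design$role == "control"])
  expect_gt(mean(shifted), 0.5)
  expect_lt(abs(mean(rest)), 0.3)
})

test_that("promoter generator plants exact consensus sites", {
  p <- strong_pwm()
  sim <- simulate_promoters(list(p), n_genes = 20,
                            planted = c(P0003 = "M1", P0010 = "M1"),
                            seed = 19)
  expect_length(sim$sequences, 20)
  expect_identical(simulate_promoters(list(p), 20,
                                      c(P0003 = "M1", P0010 = "M1"),
                                      seed = 19)$planted_at,
                   sim$planted_at)
  cons <- "ACGTACGTAC"
  for (g in names(sim$planted_at)) {
    s <- as.character(sim$sequences[[g]])
    at <- sim$planted_at[[g]] + 1
    expect_identical(substr(s, at, at + nchar(cons) - 1), cons)
  }
})
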