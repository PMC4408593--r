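test_that("edge probability is the standard normal CDF", {
  expect_equal(edge_probability(0), 0.5)
  expect_equal(edge_probability(3), 0.99865, tolerance = 1e-5)
  z <- seq(-4, 4, by = 0.5)
  p <- edge_probability(z)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

## wrap scalar weight pairs into 1x1 networks
net1 <- function(w, tf = "T1", gene = "g1") {
  regulatory_network(matrix(w, 1, 1, dimnames = list(tf, gene)))
}

test_that("the probability-product rule selects the documented edges", {
  ## strongly supported and different -> group_A edge
  sn <- extract_subnetworks(net1(3), net1(0), 0.8)
  expect_identical(n_edges(sn$group_A), 1L)
  expect_identical(n_edges(sn$group_N), 0L)
  expect_gt(pnorm(3) * pnorm(3), 0.8)  # 0.99730

  ## equal weights -> difference factor 0.5 -> neither set
  sn <- extract_subnetworks(net1(5), net1(5), 0.8)
  expect_identical(n_edges(sn$group_A) + n_edges(sn$group_N), 0L)

  ## supported and higher in group_N -> group_N edge
  sn <- extract_subnetworks(net1(-1), net1(2), 0.8)
  expect_identical(n_edges(sn$group_N), 1L)
  expect_equal(pnorm(2) * pnorm(3), 0.97593, tolerance = 1e-5)

  expect_error(extract_subnetworks(net1(1), net1(1), 1.2), "cutoff")
})

test_that("subnetworks are disjoint at 0.8 and nested across the sweep", {
  set.seed(17)
  for (rep in 1:10) {
    wa <- matrix(rnorm(20 * 30, sd = 2), 20, 30,
                 dimnames = list(sprintf("T%02d", 1:20),
                                 sprintf("g%02d", 1:30)))
    wn <- wa + matrix(rnorm(20 * 30, sd = 1.5), 20, 30)
    na <- regulatory_network(wa); nn <- regulatory_network(wn)

    sn <- extract_subnetworks(na, nn, 0.8)
    key <- function(es) paste(es$edges$tf, es$edges$gene)
    expect_length(intersect(key(sn$group_A), key(sn$group_N)), 0)

    prev_a <- prev_n <- NULL
    for (cut in seq(0.65, 0.95, by = 0.05)) {
      cur <- extract_subnetworks(na, nn, cut)
      if (!is.null(prev_a)) {
        expect_true(all(key(cur$group_A) %in% prev_a))
        expect_true(all(key(cur$group_N) %in% prev_n))
        expect_lte(n_edges(cur$group_A), length(prev_a))
      }
      prev_a <- key(cur$group_A); prev_n <- key(cur$group_N)
    }
  }
})

## small classification fixture: 2 TFs, 6 genes
class_fixture <- function() {
  tfs <- c("T1", "T2"); genes <- paste0("g", 1:6)
  ea <- edge_set("group_A",
                 data.frame(tf = c("T1", "T1", "T2"),
                            gene = c("g1", "g2", "g3")),
                 tfs, genes)
  en <- edge_set("group_N",
                 data.frame(tf = c("T2", "T2", "T1"),
                            gene = c("g3", "g4", "g5")),
                 tfs, genes)
  de <- c(g1 = 2.1, g2 = -0.4, g3 = 1.0, g4 = 0.5, g5 = -1.2, g6 = 3.0)
  list(ea = ea, en = en, de = de)
}

test_that("gene classes follow the targeting-by-direction cross", {
  fx <- class_fixture()
  cls <- classify_target_genes(fx$ea, fx$en, fx$de)
  got <- setNames(as.character(cls$class), cls$gene)
  expect_identical(got[["g1"]], "A+")     # A-only, t > 0
  expect_identical(got[["g2"]], "A-")     # A-only, t < 0
  expect_identical(got[["g3"]], "A+;N-")  # both, t > 0
  expect_identical(got[["g4"]], "N-")     # N-only, t > 0
  expect_identical(got[["g5"]], "N+")     # N-only, t < 0
  expect_identical(got[["g6"]], "none")   # untargeted

  ## both + t<0 -> N+;A-
  de2 <- fx$de; de2["g3"] <- -0.4
  cls2 <- classify_target_genes(fx$ea, fx$en, de2)
  expect_identical(as.character(cls2$class[cls2$gene == "g3"]), "N+;A-")

  ## a targeted gene missing from de is an error naming it
  expect_error(classify_target_genes(fx$ea, fx$en, fx$de[-3]), "g3")
})

test_that("class counts partition the targeted genes with nonzero t", {
  set.seed(23)
  for (rep in 1:5) {
    tfs <- sprintf("T%02d", 1:8); genes <- sprintf("g%03d", 1:60)
    mk <- function(lab) edge_set_from_matrix(
      matrix(rbinom(8 * 60, 1, 0.08), 8, 60,
             dimnames = list(tfs, genes)), lab)
    ea <- mk("group_A"); en <- mk("group_N")
    de <- setNames(rnorm(60), genes)
    de[sample(60, 5)] <- 0
    cls <- classify_target_genes(ea, en, de)
    targeted <- union(targeted_genes(ea), targeted_genes(en))
    n_classified <- sum(cls$class != "none")
    expect_identical(n_classified,
                     length(targeted[de[targeted] != 0]))

    ## swapping the networks mirrors every class
    swapped <- classify_target_genes(
      edge_set("group_A", en$edges, tfs, genes),
      edge_set("group_N", ea$edges, tfs, genes), -de)
    mirror <- c("A+" = "N+", "A-" = "N-", "A+;N-" = "N+;A-",
                "N+;A-" = "A+;N-", "N-" = "A-", "N+" = "A+",
                "none" = "none")
    expect_identical(unname(mirror[as.character(cls$class)]),
                     as.character(swapped$class))
  }
})

test_that("edge enrichment reproduces direct arithmetic", {
  tfs <- "T1"
  mk <- function(k, lab, n_extra, extra_tf = "TX") {
    genes <- sprintf("g%05d", seq_len(k + n_extra))
    edge_set(lab, data.frame(
      tf = rep(c("T1", extra_tf), c(k, n_extra)),
      gene = genes), c("T1", extra_tf), genes)
  }
  ## balanced case: E = 1
  rec <- tf_edge_enrichment(mk(10, "group_A", 90), mk(10, "group_N", 90),
                            min_edges = 1)
  expect_equal(rec$enrichment[rec$tf == "T1"], 1)

  ## subnetwork totals as in a genome-scale comparison
  rec <- tf_edge_enrichment(mk(30, "group_A", 12601),
                            mk(10, "group_N", 15725), min_edges = 20)
  expect_equal(rec$enrichment[rec$tf == "T1"], (30 / 10) / (12631 / 15735),
               tolerance = 1e-4)
  expect_equal(rec$enrichment[rec$tf == "T1"], 3.7372, tolerance = 1e-4)

  ## k_n = 0 gives an infinite enrichment with the flag set
  rec <- tf_edge_enrichment(mk(25, "group_A", 100), mk(0, "group_N", 120),
                            min_edges = 20)
  expect_true(is.infinite(rec$enrichment[rec$tf == "T1"]))
  expect_true(rec$e_infinite[rec$tf == "T1"])
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  ## spec-sized example first: k_A=3, k_N=1, n_A=5, n_N=5
  tfs <- c("T1", "TX")
  mk <- function(k, n_tot, lab) {
    genes <- sprintf("%s%04d", lab, seq_len(n_tot))
    edge_set(lab, data.frame(tf = rep(c("T1", "TX"), c(k, n_tot - k)),
                             gene = genes), tfs, genes)
  }
  rec <- tf_edge_enrichment(mk(3, 5, "group_A"), mk(1, 5, "group_N"),
                            min_edges = 1)
  expect_equal(rec$p[rec$tf == "T1"], 55 / 210, tolerance = 1e-12)
  expect_equal(rec$p[rec$tf == "T1"],
               hyper_upper_tail_oracle(3, 5, 5, 4), tolerance = 1e-12)
})

test_that("key TF selection applies both the enrichment and p bounds", {
  rec <- data.frame(tf = c("a", "b", "c", "d"),
                    enrichment = c(1.4, 0.5, 2.0, 1.8),
                    p = c(1e-9, 1e-4, 0.5, 1e-5))
  keys <- identify_key_tfs(rec)
  expect_identical(keys, c("d", "b"))  # sorted by p ascending
})

test_that("co-targeting enrichment matches the enumeration oracle", {
  ## n_universe = 20, n_tf1 = 5, n_tf2 = 6, n_both = 4
  genes <- sprintf("g%02d", 1:20)
  tfs <- c("T1", "T2", "TB")
  t1 <- genes[1:5]; t2 <- genes[c(2:5, 10, 11)]
  ea <- edge_set("group_A", data.frame(
    tf = c(rep("T1", 5), rep("T2", 6), rep("TB", 20)),
    gene = c(t1, t2, genes)), tfs, genes)
  en <- edge_set("group_N", data.frame(tf = "TB", gene = genes[1]),
                 tfs, genes)
  classes <- data.frame(gene = genes,
                        class = factor(rep("A+", 20),
                                       levels = regnetdiff:::GENE_CLASSES))
  class(classes) <- c("gene_class_table", "data.frame")
  rec <- cotargeting_enrichment(ea, en, classes, "A+",
                                tf_pairs = cbind("T1", "T2"))
  expect_identical(rec$n_universe, 20L)
  expect_identical(rec$n_tf1, 5L)
  expect_identical(rec$n_tf2, 6L)
  expect_identical(rec$n_both, 4L)
  expect_equal(rec$p, 216 / 15504, tolerance = 1e-12)
  expect_equal(rec$p, hyper_upper_tail_oracle(4, 6, 14, 5),
               tolerance = 1e-12)

  ## identical TFs are rejected; zero overlap is never near-significant
  expect_error(cotargeting_enrichment(ea, en, classes, "A+",
                                      tf_pairs = cbind("T1", "T1")),
               "distinct")
  t3 <- genes[12:16]
  ea2 <- edge_set("group_A", data.frame(
    tf = c(rep("T1", 5), rep("T2", 5), rep("TB", 20)),
    gene = c(t1, t3, genes)), tfs, genes)
  rec0 <- cotargeting_enrichment(ea2, en, classes, "A+",
                                 tf_pairs = cbind("T1", "T2"))
  expect_identical(rec0$n_both, 0L)
  expect_gt(rec0$p, 1e-3)
})
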