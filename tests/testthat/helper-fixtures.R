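## Shared fixture builders.  Everything is generated in code at test time;
## no binary data is stored.

## A tiny labelled expression object with known values.
tiny_expression <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   5, 5, 4, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("s1", "s2", "s3", "s4")))
  labeled_expression(vals, c(s1 = "group_A", s2 = "group_A",
                             s3 = "group_N", s4 = "group_N"))
}

## Write the tiny expression fixture as TSV files; returns the two paths.
write_tiny_expression_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mat <- file.path(dir, "expr.tsv")
  lab <- file.path(dir, "labels.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4",
               "g2\t2\t4\t6\t8",
               "g3\t5\t5\t4\t4"), mat)
  writeLines(c("s1\tgroup_A", "s2\tgroup_A", "s3\tgroup_N", "s4\tgroup_N"),
             lab)
  list(matrix = mat, labels = lab)
}

## A strong 10-bp PWM with probability ~1 on a fixed consensus.
strong_pwm <- function(id = "M1", tf = "TF1",
                       consensus = "ACGTACGTAC", p = 0.997) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], bases)
  probs <- matrix((1 - p) / 3, length(idx), 4)
  probs[cbind(seq_along(idx), idx)] <- p
  pwm(id, probs, tf)
}

## A PWM identical to the uniform background.
flat_pwm <- function(len = 6) {
  pwm("FLAT", matrix(0.25, len, 4), "TFFLAT")
}

## A random i.i.d. DNA genome as a DNAStringSet.
random_genome <- function(len = 1e5, seed = 1, name = "chrS") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  Biostrings::DNAStringSet(setNames(s, name))
}

## Build an edge_set quickly from a matrix of 0/1 (tf x gene).
edge_set_from_matrix <- function(mask, label, tf_ids = rownames(mask),
                                 gene_ids = colnames(mask)) {
  idx <- which(mask == 1, arr.ind = TRUE)
  edge_set(label,
           data.frame(tf = tf_ids[idx[, 1]], gene = gene_ids[idx[, 2]]),
           tf_ids = tf_ids, gene_ids = gene_ids)
}

## Exhaustive-enumeration oracle for the upper-tail hypergeometric
## probability: draw m = k_a + k_n edges from a labelled pool of n_a
## group_A and n_n group_N edges; P[# group_A drawn >= k_a].  Enumerates
## all C(n_a + n_n, m) draws explicitly -- independent of phyper.
hyper_upper_tail_oracle <- function(k_a, n_a, n_n, m) {
  pool <- c(rep(1, n_a), rep(0, n_n))
  draws <- combn(length(pool), m)
  hits <- colSums(matrix(pool[draws], nrow = m))
  mean(hits >= k_a)
}

## Independent step-up implementation of Benjamini-Hochberg adjusted
## values: sorted cumulative minima of p * n / rank.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * n / seq(n, 1)))[ro]
}
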