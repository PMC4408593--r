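## Network- and expression-based gene signatures, treatment/class
## association, drug-perturbation signatures from the concentration/
## tissue/batch linear model, and a permutation-calibrated connectivity
## ranking of drugs against a query signature.

#' Up/down gene signature
#'
#' @param up,down Disjoint, non-empty character vectors of gene ids.
#' @return List of class `"signature"` with elements `up` and `down`.
#' @export
signature_set <- function(up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (!length(up) || !length(down)) stop("up and down sets must be non-empty")
  if (length(intersect(up, down))) stop("up and down sets must be disjoint")
  structure(list(up = up, down = down), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature: %d up, %d down genes\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' Network-based class signature
#'
#' Builds a signature from the six-class table: up = genes of class
#' `A+` (activated with the group_A subnetwork), down = genes of class
#' `A-`.
#'
#' @param classes A `gene_class_table` from [classify_target_genes()].
#' @return A [signature_set()].
#' @export
build_class_signature <- function(classes) {
  up <- classes$gene[classes$class == "A+"]
  down <- classes$gene[classes$class == "A-"]
  if (!length(up)) stop("class A+ is empty; cannot build a signature")
  if (!length(down)) stop("class A- is empty; cannot build a signature")
  signature_set(up, down)
}

#' Expression-based signature of matched dimensions
#'
#' Selects the `n_up` most significant genes with positive t and the
#' `n_down` most significant with negative t from a differential
#' expression table, so a plain expression signature can be compared with
#' a network signature of identical dimensions.  Ties in p are broken by
#' `|t|` descending, then gene id.
#'
#' @param de A `gene_stat_table` from [per_gene_ttest()].
#' @param n_up,n_down Required set sizes.
#' @return A [signature_set()].
#' @export
build_expression_signature <- function(de, n_up, n_down) {
  de <- de[!is.na(de$t), ]
  pick <- function(side, k) {
    sub <- de[sign(de$t) == side, ]
    if (nrow(sub) < k)
      stop(sprintf("only %d genes with %s t; %d requested", nrow(sub),
                   if (side > 0) "positive" else "negative", k))
    sub <- sub[order(sub$p, -abs(sub$t), sub$gene), ]
    sub$gene[seq_len(k)]
  }
  signature_set(pick(1, n_up), pick(-1, n_down))
}

#' Association of a treatment contrast with the six gene classes
#'
#' For each activation/repression class, computes the [set_meta_t()] of
#' the class members' treatment-vs-control t-statistics against all other
#' genes.  A positive meta-t means class members increase in expression
#' upon treatment relative to the rest of the genome.
#'
#' @param treatment_de A `gene_stat_table` of treated-vs-control
#'   statistics (positive t = higher in treated samples).
#' @param classes A `gene_class_table`.
#' @return Data.frame, one row per class with >= 2 scorable genes:
#'   `set_id` (class), `n_set`, `n_rest`, `meta_t`, `p`, `direction`
#'   (`"up"`/`"down"` upon treatment).  Classes with fewer than 2 genes in
#'   the table are skipped with a warning.
#' @export
treatment_class_association <- function(treatment_de, classes) {
  res <- list()
  for (cl in setdiff(GENE_CLASSES, "none")) {
    members <- classes$gene[classes$class == cl]
    present <- intersect(members,
                         treatment_de$gene[!is.na(treatment_de$t)])
    if (length(present) < 2) {
      warning("class ", cl, " has fewer than 2 genes in the table; skipped")
      next
    }
    res[[cl]] <- set_meta_t(treatment_de, present, set_id = cl)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$direction <- ifelse(out$meta_t > 0, "up", "down")
  out
}

#' Design table for drug-response arrays
#'
#' @param design Data.frame with columns `array`, `drug`, `concentration`
#'   (>= 0; controls are 0), `tissue`, `batch`, `role`
#'   (`treated`/`control`).
#' @return Validated data.frame of class `"drug_design"`.
#' @export
drug_design <- function(design) {
  design <- as.data.frame(design)
  need <- c("array", "drug", "concentration", "tissue", "batch", "role")
  stopifnot(all(need %in% names(design)))
  if (any(design$concentration < 0)) stop("concentrations must be >= 0")
  if (!all(design$role %in% c("treated", "control")))
    stop("role must be 'treated' or 'control'")
  class(design) <- c("drug_design", "data.frame")
  design
}

#' Per-gene drug perturbation signature
#'
#' Restricts the expression matrix to one drug's treated arrays plus the
#' matched controls (concentration 0) and fits, per gene, the ordinary
#' least squares model
#' `G = b0 + bc * concentration + tissue + batch`
#' with reference-level coding for the categorical covariates.  The
#' perturbation signature is the concentration coefficient `bc` and its
#' two-sided coefficient-test p-value.  Covariates that are constant
#' across the drug's arrays are dropped (with a message); a rank-deficient
#' design after dropping is an error naming the aliased columns.
#'
#' @param expr Numeric gene-by-array matrix.
#' @param design A [drug_design()] covering the arrays.
#' @param drug Drug name to analyse.
#' @param log_concentration Model `log1p(concentration)` instead of raw
#'   concentration.  Default FALSE.
#' @return Data.frame of class `"drug_signature"`: `gene`, `beta_c`,
#'   `se`, `t`, `p`, with attribute `drug`.
#' @export
drug_perturbation_signature <- function(expr, design, drug,
                                        log_concentration = FALSE) {
  stopifnot(is.matrix(expr))
  design <- drug_design(design)
  sel <- design[design$drug == drug & design$role == "treated" |
                  design$role == "control", ]
  sel <- sel[sel$array %in% colnames(expr), ]
  if (!nrow(sel)) stop("no arrays found for drug ", drug)
  y <- expr[, sel$array, drop = FALSE]
  conc <- sel$concentration
  if (log_concentration) conc <- log1p(conc)
  if (length(unique(conc)) < 2)
    stop("concentration is constant across arrays; beta_c not identifiable")
  covars <- list(concentration = conc)
  for (v in c("tissue", "batch")) {
    if (length(unique(sel[[v]])) > 1) {
      covars[[v]] <- factor(sel[[v]])
    } else {
      message("covariate '", v, "' is constant for drug ", drug, "; dropped")
    }
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(covars))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(X) <= ncol(X))
    stop("not enough arrays to estimate the model")
  fit <- lm.fit(X, t(y))
  res <- as.matrix(fit$residuals)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  cc <- which(colnames(X) == "concentration")
  coefs <- as.matrix(fit$coefficients)
  beta_c <- coefs[cc, ]
  se <- sqrt(sigma2 * xtx_inv[cc, cc])
  t_stat <- beta_c / se
  p <- 2 * pt(-abs(t_stat), df)
  out <- data.frame(gene = rownames(expr), beta_c = unname(beta_c),
                    se = unname(se), t = unname(t_stat), p = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "drug") <- drug
  class(out) <- c("drug_signature", "data.frame")
  out
}

#' Connectivity-style ranking of drugs against a signature
#'
#' Scores each drug by how strongly its per-gene perturbation
#' coefficients oppose the query signature: with `r` the rank-normalised
#' `beta_c` within the drug's gene universe, the score is
#' `mean(r[down]) - mean(r[up])`, so a positive score means the drug
#' raises the signature's down genes and lowers its up genes (i.e.
#' reverses the signature).  Significance is an empirical one-sided
#' p-value from permuting which genes carry the up/down labels within
#' each drug signature (seeded).  This rank-difference score is this
#' package's own permutation-calibrated statistic; it follows the logic
#' of connectivity scoring but is not the Kolmogorov-Smirnov score used
#' by the original connectivity-map service.
#'
#' @param signature A [signature_set()].
#' @param drug_signatures Named list of `drug_signature` tables.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return Data.frame ranked by p ascending then score descending:
#'   `drug`, `n_up`, `n_down`, `score`, `p`.  Drugs whose gene universe
#'   misses the whole signature are skipped with a warning.
#' @export
connectivity_rank <- function(signature, drug_signatures, n_perm = 10000,
                              seed = 1) {
  stopifnot(inherits(signature, "signature"))
  rows <- list()
  with_seed(seed, {
    for (d in names(drug_signatures)) {
      ds <- drug_signatures[[d]]
      r <- rank(ds$beta_c) / (nrow(ds) + 1)
      names(r) <- ds$gene
      up <- intersect(signature$up, ds$gene)
      down <- intersect(signature$down, ds$gene)
      if (!length(up) || !length(down)) {
        warning("drug ", d, " shares no genes with the signature; skipped")
        next
      }
      score <- mean(r[down]) - mean(r[up])
      n_up <- length(up); n_down <- length(down)
      perm <- vapply(seq_len(n_perm), function(i) {
        lab <- sample(names(r), n_up + n_down)
        mean(r[lab[(n_up + 1):(n_up + n_down)]]) - mean(r[lab[1:n_up]])
      }, numeric(1))
      p <- (1 + sum(perm >= score)) / (n_perm + 1)
      rows[[d]] <- data.frame(drug = d, n_up = n_up, n_down = n_down,
                              score = score, p = p,
                              stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no drug shares genes with the signature")
  rownames(out) <- NULL
  out[order(out$p, -out$score), , drop = FALSE]
}
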