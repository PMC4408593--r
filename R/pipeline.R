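## End-to-end orchestration: run the full analysis from one configuration
## with deterministic, byte-identical re-runs and a manifest recording
## every stage, parameter and output checksum.

#' Pipeline configuration
#'
#' Collects the input paths and parameters of a full run.  Can be built
#' directly or loaded from a YAML file with the same field names.
#'
#' @param expr_path,labels_path Expression matrix and label TSVs (see
#'   [read_labeled_expression()]).
#' @param motif_path Motif prior edge-list TSV.
#' @param ppi_path TF-TF interaction edge-list TSV.
#' @param out_dir Output directory (created if missing).
#' @param meth_path,meth_labels_path Optional methylation matrix/labels.
#' @param cnv_path Optional seg-format CNV table.
#' @param gene_coords_path Optional gene coordinate TSV (`gene`, `chrom`,
#'   `start`, `end`) required with `cnv_path`.
#' @param alpha,tol,max_iter Inference parameters (see [panda_config()]).
#' @param cutoff Subnetwork probability-product cutoff (default 0.8).
#' @param e_cut,p_cut,min_edges Key-TF selection parameters (see
#'   [identify_key_tfs()] and [tf_edge_enrichment()]).
#' @param sweep Numeric vector of additional cutoffs reported in the
#'   manifest for the robustness sweep (default `seq(0.65, 0.95, 0.05)`).
#' @param seed Seed recorded for stochastic stages (the core pipeline is
#'   deterministic; the seed feeds optional randomised controls).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expr_path = NULL, labels_path = NULL,
                            motif_path = NULL, ppi_path = NULL,
                            out_dir = NULL,
                            meth_path = NULL, meth_labels_path = NULL,
                            cnv_path = NULL, gene_coords_path = NULL,
                            alpha = 0.25, tol = 1e-3, max_iter = 200,
                            cutoff = 0.8, e_cut = 1.5, p_cut = 1e-3,
                            min_edges = 20,
                            sweep = seq(0.65, 0.95, by = 0.05),
                            seed = 1) {
  cfg <- as.list(environment())
  required <- c("expr_path", "labels_path", "motif_path", "ppi_path",
                "out_dir")
  for (f in required)
    if (is.null(cfg[[f]]))
      stop("pipeline config is missing required field: ", f)
  required <- setdiff(required, "out_dir")
  for (f in required)
    if (!file.exists(cfg[[f]]))
      stop("pipeline input does not exist (", f, "): ", cfg[[f]])
  if (!is.null(cnv_path) && is.null(gene_coords_path))
    stop("cnv_path requires gene_coords_path")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full differential-network pipeline
#'
#' Stages, in order: read inputs; infer the group_A and group_N networks;
#' extract subtype-specific subnetworks; per-gene differential
#' expression; classify target genes; TF rewiring enrichment and key-TF
#' selection; per-key-TF target-set statistics (expression, plus
#' methylation and CNV when provided); network signature.  Every stage's
#' outputs are written as TSV under `out_dir` and recorded, with MD5
#' checksums and parameters, in a JSON manifest (`manifest.json`).
#' Re-running the same configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(parameters = unclass(config), stages = list())
  outputs <- character(0)
  stage <- function(name, fun) {
    say("[", name, "]")
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[length(outputs) + 1] <<- path
    path
  }

  expr <- stage("read_inputs", function() {
    read_labeled_expression(config$expr_path, config$labels_path)
  })
  prior <- read_edge_list(config$motif_path, "motif")
  ppi <- read_edge_list(config$ppi_path, "ppi")
  ## align universes: prior genes must match expression rows, and the
  ## PPI is reindexed to the prior's TF set (identity rows for TFs the
  ## interaction data does not cover)
  common_genes <- intersect(colnames(prior$adjacency), rownames(expr$values))
  prior <- motif_prior(prior$adjacency[, common_genes, drop = FALSE])
  expr <- labeled_expression(expr$values[common_genes, , drop = FALSE],
                             expr$labels)
  tfs <- rownames(prior$adjacency)
  ppi_full <- diag(length(tfs))
  dimnames(ppi_full) <- list(tfs, tfs)
  shared_tfs <- intersect(tfs, rownames(ppi$adjacency))
  ppi_full[shared_tfs, shared_tfs] <- ppi$adjacency[shared_tfs, shared_tfs]
  ppi <- ppi_matrix(ppi_full)
  pc <- panda_config(alpha = config$alpha, tol = config$tol,
                     max_iter = config$max_iter)

  net_a <- stage("infer_group_A", function()
    infer_network(prior, ppi, expr, "group_A", pc))
  net_n <- stage("infer_group_N", function()
    infer_network(prior, ppi, expr, "group_N", pc))
  write_network(net_a, file.path(config$out_dir, "network_group_A.tsv"))
  write_network(net_n, file.path(config$out_dir, "network_group_N.tsv"))
  outputs <- c(outputs, file.path(config$out_dir,
                                  c("network_group_A.tsv",
                                    "network_group_N.tsv")))

  subnets <- stage("extract_subnetworks", function()
    extract_subnetworks(net_a, net_n, config$cutoff))
  emit(subnets$group_A$edges, "edges_group_A.tsv")
  emit(subnets$group_N$edges, "edges_group_N.tsv")

  de <- stage("differential_expression", function() per_gene_ttest(expr))
  emit(de, "differential_expression.tsv")

  classes <- stage("classify_genes", function()
    classify_target_genes(subnets$group_A, subnets$group_N, de))
  emit(classes, "gene_classes.tsv")

  enrich <- stage("tf_enrichment", function()
    tf_edge_enrichment(subnets$group_A, subnets$group_N, config$min_edges))
  key_tfs <- identify_key_tfs(enrich, config$e_cut, config$p_cut)
  emit(enrich, "tf_enrichment.tsv")
  emit(data.frame(tf = key_tfs), "key_tfs.tsv")

  set_stats <- stage("target_set_statistics", function() {
    rows <- lapply(key_tfs, function(tf) {
      targets <- union(
        subnets$group_A$edges$gene[subnets$group_A$edges$tf == tf],
        subnets$group_N$edges$gene[subnets$group_N$edges$tf == tf])
      if (length(intersect(targets, de$gene[!is.na(de$t)])) < 2) return(NULL)
      set_meta_t(de, targets, set_id = tf)
    })
    do.call(rbind, rows)
  })
  if (!is.null(set_stats)) emit(set_stats, "target_set_expression.tsv")

  if (!is.null(config$meth_path)) {
    meth_stats <- stage("methylation", function() {
      meth <- read_labeled_expression(
        config$meth_path,
        if (is.null(config$meth_labels_path)) config$labels_path
        else config$meth_labels_path)
      per_gene_ttest(meth)
    })
    emit(meth_stats, "differential_methylation.tsv")
  }
  if (!is.null(config$cnv_path)) {
    cnv_stats <- stage("cnv", function() {
      segs <- read_cnv_segments(config$cnv_path)
      coords <- read.delim(config$gene_coords_path,
                           stringsAsFactors = FALSE)
      vals <- cnv_gene_values(segs, coords)
      per_gene_ttest(vals, expr$labels)
    })
    emit(cnv_stats, "differential_cnv.tsv")
  }

  sig <- stage("network_signature", function() {
    tryCatch(build_class_signature(classes), error = function(e) NULL)
  })
  if (!is.null(sig)) {
    emit(data.frame(gene = c(sig$up, sig$down),
                    direction = rep(c("up", "down"),
                                    c(length(sig$up), length(sig$down)))),
         "network_signature.tsv")
  }

  manifest$outputs <- lapply(outputs, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: ", length(manifest$stages), " stages, ",
      length(outputs), " output files")
  invisible(manifest)
}
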