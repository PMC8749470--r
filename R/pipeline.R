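#' Pipeline configuration
#'
#' Assembles and validates the end-to-end run configuration. Accepts either
#' explicit arguments or a YAML file (keys identical to the argument
#' names) via [read_pipeline_config()]. All referenced files must exist at
#' construction time.
#'
#' @param expression path to the expression input.
#' @param expression_fmt `"mtx10x"` or `"dense_tsv"`.
#' @param normalized whether the stored expression is already
#'   log-normalized.
#' @param network edge-list TSV path.
#' @param candidates candidate-list path.
#' @param labels optional label TSV path (else `markers` is required).
#' @param markers optional marker table path.
#' @param gene_sets optional GMT path.
#' @param out_dir report directory.
#' @param target_type,scale,de_alpha,lfc_min,selection_alpha,cor_method,cell_scope,k,linkage,seed_genes,universe_policy,summary_genes
#'   analysis settings, see [receptor_screen()].
#' @param seed RNG seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the config drives simulation).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, network, candidates,
                            out_dir,
                            expression_fmt = c("mtx10x", "dense_tsv"),
                            normalized = FALSE,
                            labels = NULL, markers = NULL, gene_sets = NULL,
                            target_type = "endothelial", scale = 1e4,
                            de_alpha = 0.05, lfc_min = 0.25,
                            selection_alpha = 0.05,
                            cor_method = "spearman",
                            cell_scope = "target_type",
                            k = 6, linkage = "average",
                            seed_genes = c("KDR", "FLT1"),
                            universe_policy = "clustered_genes",
                            summary_genes = NULL,
                            seed = 1) {
  expression_fmt <- match.arg(expression_fmt)
  cfg <- as.list(environment())
  for (key in c("expression", "network", "candidates", "labels", "markers",
                "gene_sets")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config path '%s' does not exist: %s", key, p))
  }
  if (is.null(cfg$labels) && is.null(cfg$markers))
    stop("config needs labels or markers")
  for (key in c("de_alpha", "lfc_min", "selection_alpha"))
    if (cfg[[key]] < 0 || (key != "lfc_min" && cfg[[key]] > 1))
      stop(sprintf("config threshold '%s' out of range", key))
  if (cfg$k < 1) stop("k must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full prioritization pipeline and write reports
#'
#' Reads every input named in the config, runs [receptor_screen()], and
#' writes TSV reports plus a JSON run manifest into `out_dir`:
#' `cell_type_labels.tsv`, `de_table.tsv`, `receptor_enrichment.tsv`,
#' `correlation_matrix.tsv`, `cluster_assignment.tsv`,
#' `cluster_enrichment.tsv`, `expression_summary.tsv` and `manifest.json`.
#' The manifest records the resolved config, package version, per-stage row
#' counts, collected warnings/notes and wall-clock timings, and is written
#' on handled failure as well (with the failed stage) before the error is
#' rethrown. Identical config and inputs give identical report files.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return the [receptor_screen()] object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("recnet")),
                   stages = list(), warnings = character(0))
  warns <- character(0)
  t_all <- proc.time()[["elapsed"]]
  stage <- "read_inputs"
  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) {
      manifest$failed_stage <<- stage
      manifest$error <<- error
    }
    manifest$warnings <<- warns
    manifest$wall_clock_total_s <<-
      round(proc.time()[["elapsed"]] - t_all, 3)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  res <- withCallingHandlers(
    tryCatch({
      t0 <- proc.time()[["elapsed"]]
      expr <- read_expression(config$expression, config$expression_fmt,
                              normalized = config$normalized)
      network <- read_network(config$network)
      candidates <- read_candidates(config$candidates)
      labels <- if (!is.null(config$labels)) read_labels(config$labels)
      markers <- if (!is.null(config$markers)) read_markers(config$markers)
      gene_sets <- if (!is.null(config$gene_sets))
        read_gmt(config$gene_sets)
      manifest$stages$read_inputs <- list(
        n_cells = nrow(expr$values), n_genes = ncol(expr$values),
        n_network_nodes = length(network_nodes(network)),
        n_candidates = nrow(candidates),
        wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3))

      stage <- "screen"
      t0 <- proc.time()[["elapsed"]]
      summary_genes <- if (!is.null(config$summary_genes))
        config$summary_genes else config$seed_genes
      fit <- receptor_screen(
        expr, network, candidates, labels = labels, markers = markers,
        gene_sets = gene_sets, target_type = config$target_type,
        scale = config$scale, de_alpha = config$de_alpha,
        lfc_min = config$lfc_min, selection_alpha = config$selection_alpha,
        cor_method = config$cor_method, cell_scope = config$cell_scope,
        k = config$k, linkage = config$linkage,
        seed_genes = config$seed_genes,
        universe_policy = config$universe_policy,
        summary_genes = summary_genes)
      manifest$stages$screen <- list(
        n_de = sum(fit$de$is_de), n_selected = length(fit$selected),
        seed_cluster = fit$seed_cluster,
        notes = fit$notes,
        wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3))

      stage <- "write_reports"
      t0 <- proc.time()[["elapsed"]]
      out <- config$out_dir
      write_tsv_report(fit$labels, file.path(out, "cell_type_labels.tsv"))
      write_tsv_report(fit$de, file.path(out, "de_table.tsv"))
      write_tsv_report(fit$enrichment,
                       file.path(out, "receptor_enrichment.tsv"))
      if (!is.null(fit$correlation)) {
        cm <- data.frame(gene = rownames(fit$correlation),
                         unclass(fit$correlation), check.names = FALSE)
        write_tsv_report(cm, file.path(out, "correlation_matrix.tsv"))
      }
      if (!is.null(fit$clusters)) {
        ca <- data.frame(gene = names(fit$clusters$cluster),
                         cluster = unname(fit$clusters$cluster),
                         in_seed_cluster = names(fit$clusters$cluster) %in%
                           fit$seed_cluster_genes)
        write_tsv_report(ca, file.path(out, "cluster_assignment.tsv"))
      }
      if (!is.null(fit$geneset_enrichment))
        write_tsv_report(fit$geneset_enrichment,
                         file.path(out, "cluster_enrichment.tsv"))
      if (!is.null(fit$summary))
        write_tsv_report(fit$summary,
                         file.path(out, "expression_summary.tsv"))
      manifest$stages$write_reports <- list(
        wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3))
      finish("ok")
      fit
    },
    error = function(e) {
      finish("failed", conditionMessage(e))
      stop(e)
    }),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warns <<- c(warns, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  invisible(res)
}
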