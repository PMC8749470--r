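#' Screen candidate receptors by network enrichment and co-expression
#'
#' The package's central fit. Runs the full prioritization chain on one
#' dataset: (1) log-normalize raw counts if needed; (2) obtain cell-type
#' labels, either supplied or assigned by marker scoring; (3) Wilcoxon
#' target-vs-rest differential expression; (4) hypergeometric enrichment of
#' DE genes in each candidate's direct network neighborhood, BH-selected;
#' (5) co-expression correlation of the selected candidates over
#' target-type cells; (6) agglomerative clustering (distance
#' `1 - correlation`) into `k` clusters; (7) location of the cluster
#' containing the seed receptors and (8) its hypergeometric gene-set
#' enrichment; plus (9) per-cell-type expression summaries of the genes of
#' interest.
#'
#' Stages 5-8 require at least two selected candidates (and a present seed
#' gene for 7-8); when the prerequisites fail the corresponding components
#' are `NULL` and a note is recorded, so null datasets fit cleanly.
#'
#' @param expr an [expression_matrix()]; raw counts are normalized with
#'   [normalize_log()].
#' @param network a [gene_network()].
#' @param candidates a [candidate_list()] or character vector.
#' @param labels optional data.frame `cell_id`/`cell_type`; required unless
#'   `markers` is given.
#' @param markers optional marker list for [assign_cell_types()].
#' @param gene_sets optional [read_gmt()]-style collection for the
#'   seed-cluster test.
#' @param target_type the cell type of interest (default endothelial).
#' @param scale normalization scale factor.
#' @param de_alpha,lfc_min differential-expression thresholds.
#' @param selection_alpha BH threshold for candidate selection.
#' @param cor_method,cell_scope correlation options, see
#'   [correlation_matrix()].
#' @param k number of co-expression clusters.
#' @param linkage agglomeration rule.
#' @param seed_genes seed receptors defining the cluster of interest.
#' @param universe_policy enrichment universe, see
#'   [cluster_geneset_enrichment()].
#' @param summary_genes genes for the per-type expression summary (default
#'   the seed genes).
#' @return object of class `receptor_screen` with components `de`,
#'   `enrichment`, `selected`, `correlation`, `clusters`, `seed_cluster`,
#'   `seed_cluster_genes`, `geneset_enrichment`, `summary`, `labels`,
#'   `notes` and `params`.
#' @export
receptor_screen <- function(expr, network, candidates,
                            labels = NULL, markers = NULL,
                            gene_sets = NULL,
                            target_type = "endothelial",
                            scale = 1e4,
                            de_alpha = 0.05, lfc_min = 0.25,
                            selection_alpha = 0.05,
                            cor_method = c("spearman", "pearson"),
                            cell_scope = c("target_type", "all"),
                            k = 6,
                            linkage = c("average", "complete", "single"),
                            seed_genes = c("KDR", "FLT1"),
                            universe_policy = c("clustered_genes",
                                                "scored_candidates"),
                            summary_genes = seed_genes) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(network, "gene_network"))
  cor_method <- match.arg(cor_method)
  cell_scope <- match.arg(cell_scope)
  linkage <- match.arg(linkage)
  universe_policy <- match.arg(universe_policy)
  if (is.character(candidates)) candidates <- candidate_list(candidates)
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)

  if (!expr$normalized) {
    expr <- normalize_log(expr, scale = scale)
    note(sprintf("raw counts log-normalized (scale %g)", scale))
  }
  if (is.null(labels)) {
    if (is.null(markers))
      stop("either labels or markers must be supplied")
    labels <- assign_cell_types(expr, markers)[, c("cell_id", "cell_type")]
    note("cell types assigned by marker scoring")
  }
  labels <- check_labels(expr, labels, min_types = 2L)

  de <- wilcoxon_de(expr, labels, target_type,
                    alpha = de_alpha, lfc_min = lfc_min)
  enrichment <- score_candidates(network, de, expr$gene_ids, candidates,
                                 selection_alpha = selection_alpha)
  selected <- enrichment$gene[enrichment$selected]

  correlation <- clusters <- seed_cluster <- seed_cluster_genes <-
    geneset_enrichment <- NULL
  if (length(intersect(selected, expr$gene_ids)) >= 2L) {
    correlation <- correlation_matrix(
      expr, selected, labels = labels, target_type = target_type,
      cell_scope = cell_scope, method = cor_method)
    k_eff <- min(k, nrow(correlation))
    if (k_eff < k)
      note(sprintf("k reduced from %d to %d (only %d genes clustered)",
                   k, k_eff, nrow(correlation)))
    clusters <- agglomerative_cluster(correlation, k = k_eff,
                                      linkage = linkage)
    if (any(toupper(seed_genes) %in% names(clusters$cluster))) {
      seed_cluster <- find_seed_cluster(clusters, seed_genes)
      seed_cluster_genes <-
        names(clusters$cluster)[clusters$cluster == seed_cluster]
      if (!is.null(gene_sets)) {
        res <- lapply(names(gene_sets), function(id) {
          tryCatch(
            cluster_geneset_enrichment(
              clusters, seed_cluster, gene_sets[[id]],
              universe_policy = universe_policy,
              candidate_universe = enrichment$gene, set_id = id),
            error = function(e) {
              note(sprintf("gene set %s skipped: %s", id,
                           conditionMessage(e)))
              NULL
            })
        })
        res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
        geneset_enrichment <- res
      }
    } else {
      note("no seed gene among clustered candidates; seed stages skipped")
    }
  } else {
    note("fewer than 2 selected candidates; clustering stages skipped")
  }

  summary_tab <- NULL
  present <- intersect(toupper(summary_genes), expr$gene_ids)
  if (length(present) > 0L)
    summary_tab <- summarize_expression(expr, labels, present)

  structure(list(
    de = de,
    enrichment = enrichment,
    selected = selected,
    correlation = correlation,
    clusters = clusters,
    seed_cluster = seed_cluster,
    seed_cluster_genes = seed_cluster_genes,
    geneset_enrichment = geneset_enrichment,
    summary = summary_tab,
    labels = labels,
    notes = notes,
    params = list(target_type = target_type, scale = scale,
                  de_alpha = de_alpha, lfc_min = lfc_min,
                  selection_alpha = selection_alpha,
                  cor_method = cor_method, cell_scope = cell_scope,
                  k = k, linkage = linkage, seed_genes = toupper(seed_genes),
                  universe_policy = universe_policy)),
    class = "receptor_screen")
}

#' @export
print.receptor_screen <- function(x, ...) {
  cat("receptor_screen\n")
  cat(sprintf("  DE genes (%s vs rest): %d of %d\n",
              x$params$target_type, sum(x$de$is_de), nrow(x$de)))
  cat(sprintf("  candidates selected: %d of %d (BH fdr < %g)\n",
              length(x$selected), nrow(x$enrichment),
              x$params$selection_alpha))
  if (!is.null(x$seed_cluster))
    cat(sprintf("  seed cluster (%s): cluster %d, %d genes\n",
                paste(x$params$seed_genes, collapse = "/"),
                x$seed_cluster, length(x$seed_cluster_genes)))
  if (!is.null(x$geneset_enrichment))
    for (i in seq_len(nrow(x$geneset_enrichment)))
      cat(sprintf("  seed-cluster enrichment %s: overlap %d/%d, p = %.3g\n",
                  x$geneset_enrichment$gene_set_id[[i]],
                  x$geneset_enrichment$overlap[[i]],
                  x$geneset_enrichment$cluster_size[[i]],
                  x$geneset_enrichment$p_value[[i]]))
  invisible(x)
}

#' @export
summary.receptor_screen <- function(object, ...) {
  print(object)
  if (!is.null(object$clusters)) {
    cat("\nCluster sizes:\n")
    print(table(cluster = object$clusters$cluster))
    if (!is.null(object$seed_cluster_genes)) {
      cat("\nSeed cluster members:\n")
      cat(" ", paste(sort(object$seed_cluster_genes), collapse = ", "), "\n")
    }
  }
  if (!is.null(object$summary)) {
    cat("\nPer-type expression of genes of interest:\n")
    print(object$summary, row.names = FALSE)
  }
  if (length(object$notes) > 0L) {
    cat("\nNotes:\n")
    for (n in object$notes) cat("  -", n, "\n")
  }
  invisible(object)
}

#' Heatmap of the selected-candidate correlation matrix
#'
#' Orders genes by the agglomerative dendrogram and draws the correlation
#' matrix as an image, with seed-cluster members marked.
#'
#' @param x a [receptor_screen()] result with clustering stages run.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted gene order.
#' @export
plot.receptor_screen <- function(x, ...) {
  if (is.null(x$correlation) || is.null(x$clusters))
    stop("nothing to plot: clustering stages were not run")
  ord <- x$clusters$tree$order
  M <- unclass(x$correlation)[ord, ord]
  n <- nrow(M)
  graphics::image(seq_len(n), seq_len(n), t(M[n:1, ]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  main = "co-expression of selected candidates", ...)
  lab <- colnames(M)
  in_seed <- lab %in% x$seed_cluster_genes
  graphics::axis(1, at = seq_len(n), labels = lab, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(lab), las = 2,
                 cex.axis = 0.6,
                 col.axis = "black")
  if (any(in_seed))
    graphics::mtext(side = 3, line = 0, cex = 0.7,
                    text = sprintf("seed cluster: %s",
                                   paste(lab[in_seed], collapse = ", ")))
  invisible(colnames(M))
}
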