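#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table. Used to score module recovery
#' against the planted truth.
#'
#' @param a,b vectors of cluster labels over the same items (matched by
#'   names when both are named).
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b) || anyNA(b))
    stop("labelings must cover the same items")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Score the full chain against a planted truth
#'
#' Runs the analysis stages on a simulated dataset and measures recovery of
#' the planted structure: marker-based label accuracy, planted-DE recall
#' and observed false discovery, candidate selection counts, module
#' recovery (ARI at `k = n_modules`), and the annotated-module enrichment
#' p-value in the seed cluster.
#'
#' Observed FDR is computed with the simulator's construction in mind:
#' planted DE genes are true positives and background genes are true nulls,
#' while marker genes and receptors — whose target-type distribution is
#' shifted by construction (type-specific elevation, module factors) — are
#' excluded from the false-positive count.
#'
#' @param sim output of [simulate_dataset()].
#' @param de_alpha,lfc_min,selection_alpha analysis thresholds, see
#'   [receptor_screen()].
#' @param use_truth_labels if `TRUE`, skip marker scoring and use the
#'   planted labels for the DE stage.
#' @return named list of metrics: `label_accuracy`, `de_recall`,
#'   `de_observed_fdr`, `n_de_flagged`, `n_true_selected`,
#'   `n_decoy_selected`, `selected_fraction`, `module_ari`,
#'   `seed_cluster_size`, `annotated_enrichment_p` (the last three `NA`
#'   when fewer than two candidates are selected).
#' @export
planted_truth_metrics <- function(sim, de_alpha = 0.05, lfc_min = 0.25,
                                  selection_alpha = 0.05,
                                  use_truth_labels = FALSE) {
  truth <- sim$truth
  target <- truth$target_type
  expr <- normalize_log(sim$expr)
  assigned <- assign_cell_types(expr, sim$markers)
  label_accuracy <- mean(assigned$cell_type == sim$labels$cell_type)
  labels <- if (use_truth_labels) sim$labels else
    assigned[, c("cell_id", "cell_type")]

  de <- wilcoxon_de(expr, labels, target,
                    alpha = de_alpha, lfc_min = lfc_min)
  flagged <- de$gene[de$is_de]
  shifted_by_construction <- c(unlist(sim$markers, use.names = FALSE),
                               truth$true_receptors, truth$decoy_receptors)
  nulls <- setdiff(de$gene, c(truth$de_genes, shifted_by_construction))
  fp <- length(intersect(flagged, nulls))
  tp <- length(intersect(flagged, truth$de_genes))
  de_recall <- mean(truth$de_genes %in% flagged)
  de_observed_fdr <- if (fp + tp == 0) 0 else fp / (fp + tp)

  scored <- score_candidates(sim$network, de, expr$gene_ids,
                             sim$candidates,
                             selection_alpha = selection_alpha)
  selected <- scored$gene[scored$selected]
  n_true_selected <- length(intersect(selected, truth$true_receptors))
  n_decoy_selected <- length(intersect(selected, truth$decoy_receptors))

  module_ari <- seed_cluster_size <- annotated_enrichment_p <- NA_real_
  k_modules <- sim$params$n_modules
  true_present <- intersect(truth$true_receptors, expr$gene_ids)
  if (length(true_present) > k_modules) {
    cm_true <- correlation_matrix(expr, true_present, labels = sim$labels,
                                  target_type = target)
    cl_true <- agglomerative_cluster(cm_true, k = k_modules)
    module_ari <- adjusted_rand_index(
      cl_true$cluster, truth$receptor_modules[names(cl_true$cluster)])
  }
  if (length(selected) >= 2L) {
    cm <- correlation_matrix(expr, selected, labels = sim$labels,
                             target_type = target)
    cl <- agglomerative_cluster(cm, k = min(k_modules, nrow(cm)))
    seeds <- intersect(truth$annotated_receptors, names(cl$cluster))
    if (length(seeds) > 0L) {
      sc <- find_seed_cluster(cl, seeds[[1L]])
      seed_cluster_size <- sum(cl$cluster == sc)
      set <- sim$gene_sets[[truth$annotated_set_id]]
      annotated_enrichment_p <- tryCatch(
        cluster_geneset_enrichment(cl, sc, set,
                                   set_id = truth$annotated_set_id)$p_value,
        error = function(e) NA_real_)
    }
  }
  list(label_accuracy = label_accuracy,
       de_recall = de_recall,
       de_observed_fdr = de_observed_fdr,
       n_de_flagged = length(flagged),
       n_true_selected = n_true_selected,
       n_decoy_selected = n_decoy_selected,
       selected_fraction = length(selected) / nrow(scored),
       module_ari = module_ari,
       seed_cluster_size = seed_cluster_size,
       annotated_enrichment_p = annotated_enrichment_p)
}
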