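#' Single-cell co-expression correlation matrix
#'
#' Pairwise correlation of the selected genes across a chosen cell subset —
#' by default the cells of the target type, since the candidates were
#' selected for target-type signal. Genes with zero variance in scope get
#' correlation 0 with all other genes (diagonal stays 1) and are flagged.
#'
#' @param expr normalized [expression_matrix()].
#' @param genes genes to correlate (>= 2 must be present in the matrix).
#' @param labels data.frame with `cell_id`, `cell_type`; required when
#'   `cell_scope = "target_type"`.
#' @param target_type cell type defining the scope.
#' @param cell_scope `"target_type"` or `"all"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return a symmetric matrix of class `correlation_matrix` with attributes
#'   `method`, `cell_scope` and `zero_variance` (flagged genes).
#' @export
correlation_matrix <- function(expr, genes, labels = NULL, target_type = NULL,
                               cell_scope = c("target_type", "all"),
                               method = c("spearman", "pearson")) {
  stopifnot(inherits(expr, "expression_matrix"))
  cell_scope <- match.arg(cell_scope)
  method <- match.arg(method)
  genes <- intersect(toupper(genes), expr$gene_ids)
  if (length(genes) < 2L)
    stop("need at least 2 genes present in the matrix")
  if (cell_scope == "target_type") {
    if (is.null(labels) || is.null(target_type))
      stop("labels and target_type required for cell_scope = 'target_type'")
    labels <- check_labels(expr, labels)
    cells <- labels$cell_id[labels$cell_type == target_type]
  } else {
    cells <- expr$cell_ids
  }
  if (length(cells) < 3L)
    stop("need at least 3 cells in scope")
  X <- expr$values[cells, genes, drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  flat <- colnames(X)[sds == 0]
  C <- suppressWarnings(stats::cor(X, method = method))
  C[is.na(C)] <- 0
  diag(C) <- 1
  if (length(flat) > 0L)
    warning(sprintf("%d zero-variance gene(s) set to correlation 0: %s",
                    length(flat), paste(flat, collapse = ", ")),
            call. = FALSE)
  structure(C, method = method, cell_scope = cell_scope,
            zero_variance = flat, class = c("correlation_matrix", "matrix"))
}

#' Agglomerative clustering on correlation distance
#'
#' Hierarchical agglomerative clustering of genes with distance
#' `d = 1 - correlation` and the chosen linkage (default average), cut to
#' exactly `k` clusters. Deterministic for a fixed input.
#'
#' @param corr a [correlation_matrix()] (or plain symmetric matrix with
#'   dimnames).
#' @param k number of clusters; `1 <= k <=` number of genes.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector, ids 1..k), `k`, `linkage` and the `hclust` tree.
#' @export
agglomerative_cluster <- function(corr, k = 6,
                                  linkage = c("average", "complete",
                                              "single")) {
  linkage <- match.arg(linkage)
  M <- unclass(corr)
  if (!is.matrix(M) || nrow(M) != ncol(M) || is.null(rownames(M)))
    stop("corr must be a square matrix with gene names")
  n <- nrow(M)
  if (k < 1 || k > n)
    stop(sprintf("k must lie in 1..%d", n))
  d <- stats::as.dist(1 - M)
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, k = as.integer(k), linkage = linkage,
                 tree = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d genes in %d clusters (%s linkage)\n",
              length(x$cluster), x$k, x$linkage))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Locate the cluster containing the seed receptors
#'
#' Returns the cluster holding the seed genes (default interest: the VEGF
#' receptors). If the present seeds are split across clusters, the cluster
#' holding the majority of them wins, ties broken by the earliest-listed
#' seed, with a warning.
#'
#' @param assignment a [agglomerative_cluster()] result.
#' @param seeds character vector of seed gene symbols, in priority order.
#' @return a single cluster id (integer).
#' @export
find_seed_cluster <- function(assignment, seeds = c("KDR", "FLT1")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  seeds <- toupper(seeds)
  present <- seeds[seeds %in% names(assignment$cluster)]
  if (length(present) == 0L)
    stop("no seed gene present in the cluster assignment")
  cls <- assignment$cluster[present]
  if (length(unique(cls)) == 1L) return(unname(cls[[1L]]))
  warning(sprintf("seed genes split across clusters (%s); using majority",
                  paste(sprintf("%s=%d", present, cls), collapse = ", ")),
          call. = FALSE)
  tab <- table(cls)
  winners <- as.integer(names(tab)[tab == max(tab)])
  # earliest seed whose cluster is among the winners
  unname(cls[[which(cls %in% winners)[[1L]]]])
}

#' Gene-set enrichment of one cluster
#'
#' Hypergeometric over-representation of a gene set in a cluster. The
#' universe is either the clustered genes (default) or all scored
#' candidates, mirroring the ambiguity in how such enrichments are
#' reported; both are exposed.
#'
#' @param assignment a [agglomerative_cluster()] result.
#' @param cluster_id cluster to test.
#' @param gene_set character vector of set members.
#' @param universe_policy `"clustered_genes"` or `"scored_candidates"`.
#' @param candidate_universe character vector of all scored candidates,
#'   required for the `"scored_candidates"` policy.
#' @param set_id optional label carried into the result.
#' @return one-row data.frame of class `enrichment_result` with
#'   `cluster_id`, `gene_set_id`, `cluster_size`, `universe_size`,
#'   `set_size_in_universe`, `overlap`, `p_value`.
#' @export
cluster_geneset_enrichment <- function(assignment, cluster_id, gene_set,
                                       universe_policy = c("clustered_genes",
                                                           "scored_candidates"),
                                       candidate_universe = NULL,
                                       set_id = NA_character_) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  universe_policy <- match.arg(universe_policy)
  gene_set <- toupper(gene_set)
  universe <- if (universe_policy == "clustered_genes") {
    names(assignment$cluster)
  } else {
    if (is.null(candidate_universe))
      stop("candidate_universe required for policy 'scored_candidates'")
    unique(toupper(candidate_universe))
  }
  members <- names(assignment$cluster)[assignment$cluster == cluster_id]
  if (length(members) == 0L)
    stop(sprintf("cluster %s is empty", cluster_id))
  members <- intersect(members, universe)
  K <- length(intersect(gene_set, universe))
  if (K == 0L)
    stop("gene set does not intersect the universe")
  k <- length(intersect(members, gene_set))
  res <- data.frame(cluster_id = as.integer(cluster_id),
                    gene_set_id = set_id,
                    cluster_size = length(members),
                    universe_size = length(universe),
                    set_size_in_universe = K,
                    overlap = k,
                    p_value = hypergeom_upper_tail(k, K, length(members),
                                                   length(universe)),
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}
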