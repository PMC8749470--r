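#' Assign cell types by marker scoring
#'
#' Each cell is labeled with the type whose marker score is maximal, the
#' score being the mean of z-scored (across all cells) marker-gene
#' expression. Marker genes absent from the matrix or with zero variance
#' are skipped; a type with no usable markers is dropped with a warning.
#' Ties go to the earliest type in the marker-table order. Cells with zero
#' expression across every usable marker gene carry no evidence: they get
#' the tie-break label (first type) and are flagged low-confidence.
#'
#' @param expr normalized [expression_matrix()].
#' @param markers named list: cell type -> marker gene symbols
#'   (see [read_markers()]).
#' @return data.frame with `cell_id`, `cell_type`, `score`,
#'   `low_confidence`.
#' @export
assign_cell_types <- function(expr, markers) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!expr$normalized)
    stop("marker scoring requires log-normalized values")
  if (!is.list(markers) || is.null(names(markers)))
    stop("markers must be a named list of gene vectors")
  usable <- list()
  for (ty in names(markers)) {
    g <- intersect(toupper(markers[[ty]]), expr$gene_ids)
    g <- g[apply(expr$values[, g, drop = FALSE], 2L, stats::sd) > 0]
    if (length(g) == 0L) {
      warning(sprintf("cell type '%s' dropped: no usable marker genes", ty),
              call. = FALSE)
    } else {
      usable[[ty]] <- g
    }
  }
  if (length(usable) < 2L)
    stop("need at least 2 cell types with usable marker genes")
  all_markers <- unique(unlist(usable))
  Z <- scale(expr$values[, all_markers, drop = FALSE])
  scores <- vapply(usable, function(g)
    rowMeans(Z[, g, drop = FALSE]), numeric(nrow(Z)))
  best <- max.col(scores, ties.method = "first")
  n_ties <- sum(apply(scores, 1L, function(s) sum(s == max(s)) > 1L))
  if (n_ties > 0L)
    message(sprintf("%d cell(s) with tied marker scores labeled by type order",
                    n_ties))
  no_evidence <- rowSums(expr$values[, all_markers, drop = FALSE]) == 0
  best[no_evidence] <- 1L
  if (any(no_evidence))
    message(sprintf(
      "%d cell(s) with zero marker expression flagged low-confidence",
      sum(no_evidence)))
  data.frame(cell_id = expr$cell_ids,
             cell_type = names(usable)[best],
             score = scores[cbind(seq_len(nrow(scores)), best)],
             low_confidence = no_evidence,
             stringsAsFactors = FALSE)
}

#' Per-cell-type expression summaries
#'
#' For each requested gene and each cell type: the number of cells, the
#' fraction of cells expressing the gene (value strictly above
#' `detection_threshold`, default 0), and the mean normalized expression.
#' These are the statistics behind per-type violin summaries such as
#' "expressed in 10% of pericytes".
#'
#' @param expr normalized [expression_matrix()].
#' @param labels data.frame with `cell_id`, `cell_type`.
#' @param genes genes to summarize; absent genes are reported and skipped.
#' @param detection_threshold value a cell must exceed to count as
#'   expressing.
#' @return data.frame with `gene`, `cell_type`, `n_cells`,
#'   `fraction_expressing`, `mean_normalized_expression`.
#' @export
summarize_expression <- function(expr, labels, genes,
                                 detection_threshold = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  labels <- check_labels(expr, labels)
  genes <- toupper(genes)
  absent <- setdiff(genes, expr$gene_ids)
  if (length(absent) > 0L)
    warning(sprintf("gene(s) absent from matrix skipped: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  genes <- intersect(genes, expr$gene_ids)
  if (length(genes) == 0L) stop("no requested gene present in the matrix")
  types <- unique(labels$cell_type)
  rows <- vector("list", length(genes) * length(types))
  i <- 0L
  for (g in genes) {
    for (ty in types) {
      cells <- labels$cell_id[labels$cell_type == ty]
      v <- expr$values[cells, g]
      i <- i + 1L
      rows[[i]] <- data.frame(
        gene = g, cell_type = ty, n_cells = length(cells),
        fraction_expressing = mean(v > detection_threshold),
        mean_normalized_expression = mean(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
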