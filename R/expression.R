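#' Expression matrix container
#'
#' An `expression_matrix` holds a cells-by-genes matrix of non-negative,
#' finite values together with a flag saying whether the values are raw UMI
#' counts (`normalized = FALSE`) or log-scale normalized (`normalized = TRUE`).
#' Cell barcodes are row names, uppercased gene symbols are column names; both
#' must be unique.
#'
#' @param values numeric matrix, cells as rows, genes as columns; dimnames
#'   required.
#' @param normalized logical flag; `TRUE` means log-scale normalized values.
#' @return an object of class `expression_matrix` with elements `values`,
#'   `cell_ids`, `gene_ids` and `normalized`.
#' @export
expression_matrix <- function(values, normalized) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry cell ids (rownames) and gene ids (colnames)")
  colnames(values) <- toupper(colnames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids after case-folding; resolve before construction")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (!is.logical(normalized) || length(normalized) != 1L || is.na(normalized))
    stop("`normalized` must be TRUE or FALSE")
  structure(
    list(values = values,
         cell_ids = rownames(values),
         gene_ids = colnames(values),
         normalized = normalized),
    class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "log-normalized" else "raw counts"))
  invisible(x)
}

# Collapse duplicate gene symbols: keep the column with the largest total,
# ties broken by first occurrence.
resolve_duplicate_genes <- function(values) {
  genes <- colnames(values)
  if (!anyDuplicated(genes)) return(values)
  totals <- colSums(values)
  ord <- order(genes, -totals, seq_along(genes))
  keep <- ord[!duplicated(genes[ord])]
  keep <- sort(keep)
  dropped <- length(genes) - length(keep)
  warning(sprintf(
    "%d duplicate gene symbol column(s) dropped (kept highest-total copy)",
    dropped), call. = FALSE)
  values[, keep, drop = FALSE]
}

#' Read an expression matrix
#'
#' Reads either a 10x-convention MatrixMarket triplet (a directory holding
#' `matrix.mtx`, `barcodes.tsv` and `features.tsv`/`genes.tsv`; features are
#' rows on disk, gene symbol taken from column 2 of the features file) or a
#' dense TSV with ids in the first column. Orientation is normalized to
#' cells-as-rows; for dense TSV it is auto-detected from the header corner
#' token (`gene`/`feature`/`symbol` vs `cell`/`barcode`) and can be forced.
#'
#' @param path directory (mtx10x) or file (dense_tsv).
#' @param fmt `"mtx10x"` or `"dense_tsv"`.
#' @param normalized logical; whether the stored values are already log-scale
#'   normalized. The reader never guesses.
#' @param orientation for dense TSV: `"auto"`, `"genes_as_rows"` or
#'   `"cells_as_rows"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, fmt = c("mtx10x", "dense_tsv"),
                            normalized,
                            orientation = c("auto", "genes_as_rows",
                                            "cells_as_rows")) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (fmt == "mtx10x") {
    vals <- read_mtx10x(path)
  } else {
    vals <- read_dense_tsv(path, orientation)
  }
  colnames(vals) <- toupper(colnames(vals))
  vals <- resolve_duplicate_genes(vals)
  expression_matrix(vals, normalized = normalized)
}

find_sidecar <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("none of %s found in %s",
               paste(candidates, collapse = "/"), dir))
}

read_mtx10x <- function(path) {
  if (!dir.exists(path))
    stop(sprintf("mtx10x path is not a directory: %s", path))
  mtx <- find_sidecar(path, c("matrix.mtx"))
  bc  <- find_sidecar(path, c("barcodes.tsv"))
  ft  <- find_sidecar(path, c("features.tsv", "genes.tsv"))
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  barcodes <- barcodes[nzchar(barcodes)]
  feat <- utils::read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  symbols <- if (ncol(feat) >= 2L) feat[[2L]] else feat[[1L]]
  # 10x convention: features (genes) are rows, cells are columns
  if (nrow(m) != length(symbols))
    stop(sprintf("matrix declares %d features but features file has %d",
                 nrow(m), length(symbols)))
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix declares %d cells but barcodes file has %d",
                 ncol(m), length(barcodes)))
  dimnames(m) <- list(symbols, barcodes)
  t(m)
}

read_dense_tsv <- function(path, orientation = "auto") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("dense TSV needs an id column plus data columns")
  corner <- tolower(names(df)[1L])
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in dense TSV")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  rows_are <- switch(orientation,
    genes_as_rows = "genes",
    cells_as_rows = "cells",
    auto = {
      if (corner %in% c("gene", "genes", "gene_id", "symbol", "feature"))
        "genes"
      else if (corner %in% c("cell", "cells", "cell_id", "barcode"))
        "cells"
      else {
        warning(sprintf(
          "corner token '%s' not recognised; assuming genes as rows",
          names(df)[1L]), call. = FALSE)
        "genes"
      }
    })
  if (rows_are == "genes") t(m) else m
}

#' Write an expression matrix
#'
#' Writes either a dense TSV (cells as rows, corner column `cell_id`) or a
#' 10x-convention MatrixMarket triplet into a directory.
#'
#' @param expr an [expression_matrix()].
#' @param path output file (dense_tsv) or directory (mtx10x).
#' @param fmt `"dense_tsv"` or `"mtx10x"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, fmt = c("dense_tsv", "mtx10x")) {
  stopifnot(inherits(expr, "expression_matrix"))
  fmt <- match.arg(fmt)
  if (fmt == "dense_tsv") {
    df <- data.frame(cell_id = expr$cell_ids, expr$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sm <- Matrix::Matrix(t(expr$values), sparse = TRUE)
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    writeLines(expr$cell_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(
      data.frame(id = expr$gene_ids, symbol = expr$gene_ids),
      file.path(path, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Log-normalize raw counts
#'
#' Per cell, counts are scaled to `scale` total (default 10,000) and
#' transformed with the natural `log1p`: `log(1 + scale * c / sum(c))`. Cells
#' with zero total counts are left all-zero and reported with a warning.
#'
#' @param expr an [expression_matrix()] with `normalized = FALSE`.
#' @param scale per-cell library size target.
#' @return an [expression_matrix()] with `normalized = TRUE`.
#' @export
normalize_log <- function(expr, scale = 1e4) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$normalized)
    stop("input is already normalized")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive number")
  totals <- rowSums(expr$values)
  zero <- totals == 0
  if (any(zero))
    warning(sprintf("%d all-zero cell(s) left unnormalized", sum(zero)),
            call. = FALSE)
  denom <- ifelse(zero, 1, totals)
  out <- log1p(expr$values / denom * scale)
  out[zero, ] <- 0
  expression_matrix(out, normalized = TRUE)
}
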