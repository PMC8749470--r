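#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols. Symbols are uppercased; empty sets and lines with
#' fewer than three fields are format errors.
#'
#' @param path GMT file.
#' @return a named list of character vectors (class `gene_set_collection`)
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file")
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description, members", i))
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT set '%s' has no members", f[[1L]]))
    sets[[f[[1L]]]] <- members
    descs[[f[[1L]]]] <- f[[2L]]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidate receptor/TF list
#'
#' One symbol per line, or two tab-separated columns `symbol<TAB>role` with
#' role in `receptor`, `TF`, `unknown`. Symbols are uppercased and
#' deduplicated keeping first occurrence.
#'
#' @param path candidate file.
#' @return data.frame with columns `symbol` and `role`
#'   (class `candidate_list`).
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty candidate file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  symbol <- toupper(vapply(parts, `[[`, character(1), 1L))
  role <- vapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(p[[2L]])) p[[2L]] else "unknown"
  }, character(1))
  role <- c(receptor = "receptor", tf = "TF",
            unknown = "unknown")[tolower(role)]
  if (anyNA(role)) stop("candidate role must be receptor, TF or unknown")
  keep <- !duplicated(symbol)
  candidate_list(symbol[keep], role[keep])
}

#' Construct a candidate list
#' @param symbol character vector of gene symbols.
#' @param role roles (`receptor`, `TF`, `unknown`), recycled if length 1.
#' @return data.frame of class `candidate_list`.
#' @export
candidate_list <- function(symbol, role = "unknown") {
  symbol <- toupper(symbol)
  if (anyDuplicated(symbol)) {
    keep <- !duplicated(symbol)
    symbol <- symbol[keep]
    if (length(role) > 1L) role <- role[keep]
  }
  df <- data.frame(symbol = symbol,
                   role = rep_len(role, length(symbol)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("candidate_list", "data.frame")
  df
}

#' Write a candidate list
#' @param candidates a [candidate_list()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-cell type labels
#'
#' Two tab-separated columns: cell barcode, cell-type name. A header row is
#' tolerated when the first field is `cell_id`, `cell` or `barcode`.
#'
#' @param path label TSV.
#' @return data.frame with columns `cell_id`, `cell_type`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("label file must have two columns")
  if (tolower(df[1L, 1L]) %in% c("cell_id", "cell", "barcode"))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty label file")
  out <- data.frame(cell_id = df[[1L]], cell_type = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$cell_id)) stop("duplicate cell ids in label file")
  rownames(out) <- NULL
  out
}

#' Write per-cell type labels
#' @param labels data.frame with `cell_id`, `cell_type`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("cell_id", "cell_type")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Attach-time validation shared by everything that pairs labels with a matrix:
# every labeled barcode must exist in the matrix, and only labeled cells are
# used downstream.
check_labels <- function(expr, labels, min_types = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.data.frame(labels) ||
      !all(c("cell_id", "cell_type") %in% names(labels)))
    stop("labels must be a data.frame with cell_id and cell_type")
  if (nrow(labels) == 0L) stop("empty label set")
  missing <- setdiff(labels$cell_id, expr$cell_ids)
  if (length(missing) > 0L)
    stop(sprintf("%d labeled cell id(s) absent from the matrix (e.g. %s)",
                 length(missing), missing[[1L]]))
  if (length(unique(labels$cell_type)) < min_types)
    stop(sprintf("need at least %d distinct cell types", min_types))
  labels
}

#' Read a marker table for cell typing
#'
#' Either a GMT file (set name = cell type) or a two-column TSV
#' `cell_type<TAB>marker_gene` with one marker per row.
#'
#' @param path marker file.
#' @return named list: cell type -> character vector of marker symbols.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    return(lapply(unclass(sets), identity))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("marker TSV must have two columns: type, gene")
  if (tolower(df[1L, 1L]) %in% c("cell_type", "type"))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty marker file")
  split(toupper(df[[2L]]), factor(df[[1L]], levels = unique(df[[1L]])))
}
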