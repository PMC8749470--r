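#' Undirected gene interaction network
#'
#' Thin wrapper over an undirected, simple (no self-loops, no multi-edges)
#' igraph object whose vertices are uppercased gene symbols. This is the
#' container for composite functional networks such as the Parsimonious
#' Composite Network used for receptor neighborhood queries.
#'
#' @param edges two-column character matrix or data.frame of gene symbols.
#' @return an object of class `gene_network`.
#' @export
gene_network <- function(edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(edges) <- "character"
  edges <- toupper(trimws(edges))
  keep <- nzchar(edges[, 1L]) & nzchar(edges[, 2L]) & edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L)
    stop("network is empty after removing self-loops and blank rows")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d undirected edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Read a gene network from an edge-list TSV
#'
#' Expects two tab-separated symbol columns; extra columns are ignored. Edges
#' are deduplicated irrespective of orientation and self-loops dropped.
#'
#' @param path edge-list file.
#' @return a [gene_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse edge list %s: %s",
                                     path, conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("edge list must have at least one row and two columns")
  gene_network(df[, 1:2])
}

#' Write a gene network as an edge-list TSV
#' @param net a [gene_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_edgelist(net$graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene symbols present in a network
#' @param net a [gene_network()].
#' @return character vector of vertex names.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::V(net$graph)$name
}

#' Direct neighbors of a gene
#'
#' Returns the set of genes adjacent to `gene`; empty if the gene is not in
#' the network.
#'
#' @param net a [gene_network()].
#' @param gene a single gene symbol (case-insensitive).
#' @return character vector (a set: unique, no self).
#' @export
network_neighbors <- function(net, gene) {
  stopifnot(inherits(net, "gene_network"), length(gene) == 1L)
  gene <- toupper(gene)
  if (!gene %in% igraph::V(net$graph)$name) return(character(0))
  names(igraph::neighbors(net$graph, gene))
}
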