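#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes without
#' replacement from a universe of `N` containing `K` successes. This is the
#' over-representation p-value used both for receptor neighborhood
#' enrichment and for the seed-cluster gene-set test.
#'
#' @param k observed overlap.
#' @param K successes in the universe.
#' @param n draws (e.g. neighborhood or cluster size).
#' @param N universe size.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("k, K, n, N must be non-negative integers")
  if (k > min(K, n) || K > N || n > N)
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  min(1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Score candidate receptors/TFs by neighborhood DE enrichment
#'
#' For each candidate gene, tests whether its direct network neighbors are
#' over-represented for differentially expressed genes. The universe for a
#' candidate is the set of genes present in both the expression matrix and
#' the network, minus the candidate itself; the DE set is intersected with
#' that universe. Candidates whose in-universe neighborhood is empty are
#' reported with p = 1 and excluded from the BH adjustment.
#'
#' @param network a [gene_network()].
#' @param de_table output of [wilcoxon_de()] (uses the `is_de` flag).
#' @param expr_genes character vector of genes measured in the expression
#'   matrix.
#' @param candidates a [candidate_list()] or character vector of symbols.
#' @param selection_alpha BH FDR threshold for the `selected` flag.
#' @return data.frame with one row per candidate: `gene`, `role`,
#'   `neighborhood_size_in_universe`, `de_overlap`, `p_value`, `fdr`
#'   (NA when excluded), `selected`.
#' @export
score_candidates <- function(network, de_table, expr_genes, candidates,
                             selection_alpha = 0.05) {
  stopifnot(inherits(network, "gene_network"))
  if (!is.data.frame(de_table) || !all(c("gene", "is_de") %in% names(de_table)))
    stop("de_table must have columns gene and is_de")
  if (is.character(candidates)) candidates <- candidate_list(candidates)
  expr_genes <- toupper(expr_genes)
  base_universe <- intersect(expr_genes, network_nodes(network))
  if (length(base_universe) == 0L)
    stop("empty universe: no genes shared by expression matrix and network")
  de_genes <- intersect(toupper(de_table$gene[de_table$is_de]), base_universe)

  syms <- candidates$symbol
  n_cand <- length(syms)
  nsize <- integer(n_cand)
  overlap <- integer(n_cand)
  pval <- numeric(n_cand)
  for (i in seq_len(n_cand)) {
    uni <- setdiff(base_universe, syms[[i]])
    nb <- intersect(network_neighbors(network, syms[[i]]), uni)
    K <- length(setdiff(de_genes, syms[[i]]))
    nsize[[i]] <- length(nb)
    overlap[[i]] <- length(intersect(nb, de_genes))
    pval[[i]] <- if (nsize[[i]] == 0L) 1 else
      hypergeom_upper_tail(overlap[[i]], K, nsize[[i]], length(uni))
  }
  scored <- nsize > 0L
  if (any(!scored))
    message(sprintf(
      "%d candidate(s) with no in-universe neighbors excluded from BH",
      sum(!scored)))
  fdr <- rep(NA_real_, n_cand)
  if (any(scored)) fdr[scored] <- bh_adjust(pval[scored])
  data.frame(gene = syms,
             role = candidates$role,
             neighborhood_size_in_universe = nsize,
             de_overlap = overlap,
             p_value = pval,
             fdr = fdr,
             selected = !is.na(fdr) & fdr < selection_alpha,
             stringsAsFactors = FALSE)
}
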