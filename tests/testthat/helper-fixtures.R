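# Fixtures are built in code at test time; nothing is read from disk except
# files these helpers write into tempdirs.

# A tiny expression matrix with explicit values (cells x genes).
tiny_expr <- function(values, normalized = TRUE,
                      cells = sprintf("C%d", seq_len(nrow(values))),
                      genes = sprintf("G%d", seq_len(ncol(values)))) {
  storage.mode(values) <- "double"
  dimnames(values) <- list(cells, genes)
  expression_matrix(values, normalized = normalized)
}

tiny_labels <- function(cells, types) {
  data.frame(cell_id = cells, cell_type = types, stringsAsFactors = FALSE)
}

# Reduced-scale simulation for fast property tests; study-scale defaults are
# exercised in test-acceptance.R.
small_params <- function(seed = 1, ...) {
  args <- list(
    n_cells_per_type = c(endothelial = 200, pericyte = 200,
                         fibroblast = 200, macrophage = 200, RPE = 200),
    n_genes = 600,
    n_marker_genes_per_type = 5,
    n_de_genes = 25,
    n_true_receptors = 9,
    n_decoy_receptors = 18,
    neighborhood_size = 12,
    neighborhood_de_fraction_true = 0.7,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_params, args)
}

# Independent brute-force hypergeometric upper tail over binomial
# coefficients; the oracle for every enrichment p-value in the suite.
brute_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-group Wilcoxon through the package on a one-gene matrix, so the
# public API is exercised rather than internals.
de_p_for <- function(x, y, exact = NULL) {
  vals <- matrix(c(x, y), ncol = 1)
  expr <- tiny_expr(vals, cells = sprintf("C%d", seq_along(c(x, y))))
  labels <- tiny_labels(expr$cell_ids,
                        rep(c("target", "rest"), c(length(x), length(y))))
  wilcoxon_de(expr, labels, "target", exact = exact)$p_value[[1L]]
}
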