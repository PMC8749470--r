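#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1, input order preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Exact two-sided rank-sum p by enumeration of all group assignments of the
# observed (mid-)ranks. The rank-sum null distribution is symmetric about
# n1*(N+1)/2 even under ties, so the two-sided p is the probability of a
# deviation at least as large as observed.
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  combs <- utils::combn(N, n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# Normal-approximation two-sided rank-sum p with tie correction and
# continuity correction. Returns 1 for constant pooled samples.
approx_ranksum_p <- function(r, grp, tie_term) {
  n1 <- sum(grp)
  n2 <- length(r) - n1
  N <- n1 + n2
  w <- sum(r[grp])
  mu <- n1 * (N + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  d <- w - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Target-vs-rest Wilcoxon differential expression
#'
#' Two-sided Wilcoxon rank-sum test of each gene in cells of `target_type`
#' against all other labeled cells, on log-normalized values. The p-value
#' uses the normal approximation with tie and continuity correction; when
#' both groups have at most 8 cells the exact null distribution is
#' enumerated instead. The fold change is computed on de-logged means with
#' pseudocount 1: `log2((mean(expm1 x_t) + 1) / (mean(expm1 x_r) + 1))`.
#' Genes constant across all labeled cells get p = 1 by convention.
#'
#' @param expr normalized [expression_matrix()].
#' @param labels data.frame with `cell_id`, `cell_type`; every id must exist
#'   in the matrix. Only labeled cells are tested.
#' @param target_type cell type forming the target group (>= 3 cells; the
#'   rest group also needs >= 3 cells).
#' @param alpha FDR threshold for the `is_de` flag.
#' @param lfc_min minimum `|log2 fold change|` for the `is_de` flag.
#' @param exact `NULL` (default) enumerates the exact null distribution
#'   when both groups have at most 8 cells and uses the normal
#'   approximation otherwise; `TRUE`/`FALSE` force a branch.
#' @return data.frame with columns `gene`, `log2_fold_change`, `p_value`,
#'   `fdr`, `is_de` (one row per gene, matrix column order).
#' @export
wilcoxon_de <- function(expr, labels, target_type, alpha = 0.05,
                        lfc_min = 0.25, exact = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!expr$normalized)
    stop("differential expression requires log-normalized values")
  labels <- check_labels(expr, labels, min_types = 2L)
  if (!target_type %in% labels$cell_type)
    stop(sprintf("target type '%s' absent from labels", target_type))
  X <- expr$values[labels$cell_id, , drop = FALSE]
  grp <- labels$cell_type == target_type
  n1 <- sum(grp)
  n2 <- sum(!grp)
  if (n1 < 3L || n2 < 3L)
    stop("need at least 3 cells in both the target and the rest group")

  if (is.null(exact)) exact <- n1 <= 8L && n2 <= 8L
  if (exact && (n1 > 12L || n2 > 12L))
    stop("exact enumeration is limited to groups of at most 12 cells")
  n_genes <- ncol(X)
  p <- numeric(n_genes)
  lfc <- numeric(n_genes)
  n_const <- 0L
  for (j in seq_len(n_genes)) {
    x <- X[, j]
    if (all(x == x[[1L]])) {
      p[[j]] <- 1
      lfc[[j]] <- 0
      n_const <- n_const + 1L
      next
    }
    if (exact) {
      p[[j]] <- exact_ranksum_p(x[grp], x[!grp])
    } else {
      r <- rank(x)
      tl <- rle(sort(x))$lengths
      p[[j]] <- approx_ranksum_p(r, grp, sum(tl^3 - tl))
    }
    m1 <- mean(expm1(x[grp]))
    m2 <- mean(expm1(x[!grp]))
    lfc[[j]] <- log2((m1 + 1) / (m2 + 1))
  }
  if (n_const > 0L)
    message(sprintf("%d constant gene(s) assigned p = 1", n_const))
  fdr <- bh_adjust(p)
  data.frame(gene = colnames(X),
             log2_fold_change = lfc,
             p_value = p,
             fdr = fdr,
             is_de = fdr < alpha & abs(lfc) >= lfc_min,
             stringsAsFactors = FALSE)
}
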