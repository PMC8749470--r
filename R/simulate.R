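#' Parameters for the planted-truth simulator
#'
#' Defaults describe the desk-scale study conditions: five cell types of 400
#' cells, 2,000 genes, 100 genes upregulated two-fold in the endothelial
#' (first) type, 15 true receptors whose 20-gene network neighborhoods are
#' half planted-DE genes, 45 decoys at 5 percent, and 3 latent co-expression
#' modules among the true receptors.
#'
#' @param n_cells_per_type named integer vector, cell type -> cell count;
#'   the first type is the DE target.
#' @param n_genes total genes (receptors + markers + DE + background).
#' @param n_marker_genes_per_type markers elevated in their own type.
#' @param n_de_genes genes upregulated in the target type.
#' @param de_log2fc log2 fold elevation of DE genes in the target type
#'   (0 gives a null dataset with no planted separation).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param n_true_receptors,n_decoy_receptors candidate counts.
#' @param neighborhood_size neighbors wired to each candidate.
#' @param neighborhood_de_fraction_true,neighborhood_de_fraction_decoy
#'   fraction of each neighborhood drawn from the planted DE genes.
#' @param n_modules latent co-expression modules among true receptors.
#' @param module_factor_sd sd of the per-cell module factor on the log-mean
#'   scale (target-type cells only).
#' @param annotated_module_index module covered by the annotated gene set.
#' @param background_degree mean degree of the random background network
#'   over non-receptor genes.
#' @param base_mean_meanlog,base_mean_sdlog log-normal baseline mean
#'   parameters for non-receptor genes.
#' @param marker_base_mean,marker_log2fc marker baseline mean and log2 fold
#'   elevation in the marker's own type.
#' @param receptor_base_mean baseline mean of receptor genes (all types).
#' @param seed RNG seed; identical seed gives bit-identical output.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(
    n_cells_per_type = c(endothelial = 400, pericyte = 400,
                         fibroblast = 400, macrophage = 400, RPE = 400),
    n_genes = 2000,
    n_marker_genes_per_type = 10,
    n_de_genes = 100,
    de_log2fc = 1,
    nb_dispersion = 0.3,
    n_true_receptors = 15,
    n_decoy_receptors = 45,
    neighborhood_size = 20,
    neighborhood_de_fraction_true = 0.5,
    neighborhood_de_fraction_decoy = 0.05,
    n_modules = 3,
    module_factor_sd = 0.8,
    annotated_module_index = 1,
    background_degree = 4,
    base_mean_meanlog = log(1),
    base_mean_sdlog = 0.7,
    marker_base_mean = 0.5,
    marker_log2fc = 3,
    receptor_base_mean = 3,
    seed = 1) {
  p <- as.list(environment())
  counts <- c(p$n_cells_per_type, p$n_genes, p$n_marker_genes_per_type,
              p$n_de_genes, p$n_true_receptors, p$n_decoy_receptors,
              p$neighborhood_size, p$n_modules)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers")
  if (is.null(names(p$n_cells_per_type)) ||
      length(p$n_cells_per_type) < 2L)
    stop("n_cells_per_type must be a named vector with >= 2 types")
  fr <- c(p$neighborhood_de_fraction_true, p$neighborhood_de_fraction_decoy)
  if (any(fr < 0) || any(fr > 1))
    stop("neighborhood DE fractions must lie in [0, 1]")
  if (p$de_log2fc < 0) stop("de_log2fc must be >= 0")
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (p$module_factor_sd < 0) stop("module_factor_sd must be >= 0")
  if (p$annotated_module_index < 1 ||
      p$annotated_module_index > p$n_modules)
    stop("annotated_module_index must lie in 1..n_modules")
  n_special <- p$n_true_receptors + p$n_decoy_receptors +
    p$n_marker_genes_per_type * length(p$n_cells_per_type) + p$n_de_genes
  if (p$n_genes <= n_special)
    stop(sprintf("n_genes must exceed %d (receptors + markers + DE genes)",
                 n_special))
  if (p$neighborhood_size >
      p$n_genes - p$n_true_receptors - p$n_decoy_receptors)
    stop("neighborhood_size exceeds the number of non-receptor genes")
  structure(p, class = "simulation_params")
}

# Role-based gene naming; the first receptors of the annotated module take
# the seed-receptor names KDR and FLT1 so the pipeline's default seeds apply
# to synthetic data unchanged.
simulate_gene_roles <- function(p) {
  types <- names(p$n_cells_per_type)
  n_rec <- p$n_true_receptors + p$n_decoy_receptors
  modules <- rep(seq_len(p$n_modules),
                 length.out = 0)  # placeholder, replaced below
  sizes <- diff(floor(seq(0, p$n_true_receptors, length.out = p$n_modules + 1)))
  modules <- rep(seq_len(p$n_modules), times = sizes)
  true_names <- sprintf("RCPT%02d", seq_len(p$n_true_receptors))
  in_ann <- which(modules == p$annotated_module_index)
  seed_names <- c("KDR", "FLT1")
  for (j in seq_len(min(2L, length(in_ann))))
    true_names[in_ann[[j]]] <- seed_names[[j]]
  decoy_names <- sprintf("DCOY%02d", seq_len(p$n_decoy_receptors))
  marker_names <- unlist(lapply(seq_along(types), function(t)
    sprintf("MARKER%d_%02d", t, seq_len(p$n_marker_genes_per_type))))
  n_bg <- p$n_genes - n_rec - length(marker_names) - p$n_de_genes
  de_names <- sprintf("DEG%04d", seq_len(p$n_de_genes))
  bg_names <- sprintf("BG%05d", seq_len(n_bg))
  list(true = true_names, decoy = decoy_names,
       modules = stats::setNames(modules, true_names),
       markers = matrix(marker_names, ncol = length(types),
                        dimnames = list(NULL, types)),
       de = de_names, bg = bg_names)
}

#' Simulate a planted-truth dataset
#'
#' Draws a raw-count cells-by-genes matrix from a negative binomial with
#' gene-level log-normal baseline means: markers are elevated
#' `2^marker_log2fc`-fold in their own type, DE genes `2^de_log2fc`-fold in
#' the target (first) type, and true receptors in the same module share a
#' per-target-cell latent factor applied on the log-mean scale (mean
#' `-sd^2/2` so the factor is mean-one multiplicative). The gene network is
#' an Erdős–Rényi background over non-receptor genes with each candidate's
#' neighborhood wired explicitly: `round(neighborhood_size * fraction)`
#' planted DE genes plus non-DE fill. The gene-set collection holds one set
#' covering exactly the receptors of the annotated module.
#'
#' @param params a [simulation_params()].
#' @return list with `expr` (raw-count [expression_matrix()]), `labels`,
#'   `network`, `gene_sets`, `candidates`, `markers` and `truth` (planted DE
#'   genes, receptor sets, module map, annotated set id).
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)
  roles <- simulate_gene_roles(p)
  types <- names(p$n_cells_per_type)
  target <- types[[1L]]
  genes <- c(roles$true, roles$decoy, as.vector(roles$markers),
             roles$de, roles$bg)
  n_genes <- length(genes)
  cell_type <- rep(types, times = p$n_cells_per_type)
  n_cells <- length(cell_type)
  cell_ids <- sprintf("CELL%05d", seq_len(n_cells))

  base <- stats::setNames(numeric(n_genes), genes)
  base[c(roles$true, roles$decoy)] <- p$receptor_base_mean
  base[as.vector(roles$markers)] <- p$marker_base_mean
  nrand <- length(roles$de) + length(roles$bg)
  base[c(roles$de, roles$bg)] <-
    stats::rlnorm(nrand, p$base_mean_meanlog, p$base_mean_sdlog)

  # cells x genes matrix of log-means
  logmu <- matrix(rep(log(base), each = n_cells), nrow = n_cells,
                  dimnames = list(cell_ids, genes))
  for (t in seq_along(types)) {
    own <- cell_type == types[[t]]
    logmu[own, roles$markers[, t]] <-
      logmu[own, roles$markers[, t]] + p$marker_log2fc * log(2)
  }
  in_target <- cell_type == target
  logmu[in_target, roles$de] <- logmu[in_target, roles$de] +
    p$de_log2fc * log(2)
  if (p$module_factor_sd > 0) {
    for (m in seq_len(p$n_modules)) {
      members <- names(roles$modules)[roles$modules == m]
      f <- stats::rnorm(sum(in_target), -p$module_factor_sd^2 / 2,
                        p$module_factor_sd)
      logmu[in_target, members] <- logmu[in_target, members] + f
    }
  }
  counts <- matrix(
    stats::rnbinom(length(logmu), mu = exp(logmu), size = 1 / p$nb_dispersion),
    nrow = n_cells, dimnames = dimnames(logmu))
  mode(counts) <- "numeric"
  expr <- expression_matrix(counts, normalized = FALSE)
  labels <- data.frame(cell_id = cell_ids, cell_type = cell_type,
                       stringsAsFactors = FALSE)

  network <- simulate_network(p, roles)
  ann_receptors <- names(roles$modules)[roles$modules ==
                                          p$annotated_module_index]
  gene_sets <- structure(
    list(ANGIOGENESIS_SYNTH = ann_receptors),
    descriptions = c(ANGIOGENESIS_SYNTH =
                       "synthetic annotation covering the annotated module"),
    class = "gene_set_collection")
  candidates <- candidate_list(c(roles$true, roles$decoy), role = "receptor")
  marker_list <- lapply(seq_along(types), function(t) roles$markers[, t])
  names(marker_list) <- types

  truth <- list(de_genes = roles$de,
                true_receptors = roles$true,
                decoy_receptors = roles$decoy,
                receptor_modules = roles$modules,
                annotated_set_id = "ANGIOGENESIS_SYNTH",
                annotated_receptors = ann_receptors,
                target_type = target)
  list(expr = expr, labels = labels, network = network,
       gene_sets = gene_sets, candidates = candidates,
       markers = marker_list, truth = truth, params = p)
}

simulate_network <- function(p, roles) {
  receptors <- c(roles$true, roles$decoy)
  non_receptor <- c(as.vector(roles$markers), roles$de, roles$bg)
  non_de <- setdiff(non_receptor, roles$de)
  if (p$neighborhood_size > length(non_receptor))
    stop("neighborhood_size exceeds the number of non-receptor genes")
  n_de_true <- round(p$neighborhood_size * p$neighborhood_de_fraction_true)
  n_de_decoy <- round(p$neighborhood_size * p$neighborhood_de_fraction_decoy)
  if (max(n_de_true, n_de_decoy) > length(roles$de))
    stop("neighborhood DE demand exceeds the number of planted DE genes")
  if (p$neighborhood_size - min(n_de_true, n_de_decoy) > length(non_de))
    stop("neighborhood non-DE demand exceeds available non-DE genes")
  edges <- vector("list", length(receptors) + 1L)
  for (i in seq_along(receptors)) {
    n_de_nb <- if (receptors[[i]] %in% roles$true) n_de_true else n_de_decoy
    nb <- c(sample(roles$de, n_de_nb),
            sample(non_de, p$neighborhood_size - n_de_nb))
    edges[[i]] <- cbind(receptors[[i]], nb)
  }
  # Erdős–Rényi background among non-receptor genes keeps neighborhood
  # composition the only candidate-level signal.
  n_bg_edges <- round(length(non_receptor) * p$background_degree / 2)
  g <- igraph::sample_gnm(length(non_receptor), n_bg_edges)
  el <- igraph::as_edgelist(g)
  edges[[length(edges)]] <- cbind(non_receptor[el[, 1L]],
                                  non_receptor[el[, 2L]])
  gene_network(do.call(rbind, edges))
}

#' Write a simulated dataset to disk
#'
#' Emits every piece in the package's file dialects: the count matrix
#' (mtx10x triplet or dense TSV), `labels.tsv`, `network.tsv`,
#' `gene_sets.gmt`, `candidates.tsv`, `markers.tsv` and a plain-text
#' `truth.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param fmt expression format, `"mtx10x"` or `"dense_tsv"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, fmt = c("mtx10x", "dense_tsv")) {
  fmt <- match.arg(fmt)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (fmt == "mtx10x") {
    write_expression(sim$expr, file.path(dir, "expression"), "mtx10x")
  } else {
    write_expression(sim$expr, file.path(dir, "expression.tsv"), "dense_tsv")
  }
  write_labels(sim$labels, file.path(dir, "labels.tsv"))
  write_network(sim$network, file.path(dir, "network.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_candidates(sim$candidates, file.path(dir, "candidates.tsv"))
  mk <- data.frame(
    cell_type = rep(names(sim$markers), lengths(sim$markers)),
    gene = unlist(sim$markers, use.names = FALSE))
  utils::write.table(mk, file.path(dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- sim$truth
  truth$receptor_modules <- as.list(truth$receptor_modules)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
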