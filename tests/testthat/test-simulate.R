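test_that("identical seeds give bit-identical datasets", {
  a <- simulate_dataset(small_params(seed = 7))
  b <- simulate_dataset(small_params(seed = 7))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_identical(igraph::as_edgelist(a$network$graph),
                   igraph::as_edgelist(b$network$graph))
  c <- simulate_dataset(small_params(seed = 8))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("neighborhood wiring follows the planted fractions exactly", {
  sim <- simulate_dataset(small_params(
    seed = 2, neighborhood_de_fraction_true = 1,
    neighborhood_de_fraction_decoy = 0))
  de <- sim$truth$de_genes
  for (r in sim$truth$true_receptors) {
    nb <- network_neighbors(sim$network, r)
    expect_length(nb, sim$params$neighborhood_size)
    expect_true(all(nb %in% de))
  }
  for (r in sim$truth$decoy_receptors)
    expect_length(intersect(network_neighbors(sim$network, r), de), 0)
})

test_that("planted DE genes show the intended fold change in target cells", {
  # two-fold in log2 units of 2 -> target/rest count-mean ratio near 4
  p <- simulation_params(
    n_cells_per_type = c(endothelial = 500, pericyte = 500,
                         fibroblast = 500, macrophage = 500),
    n_genes = 600, n_de_genes = 50, de_log2fc = 2,
    n_true_receptors = 9, n_decoy_receptors = 18,
    neighborhood_size = 10, n_marker_genes_per_type = 5, seed = 11)
  sim <- simulate_dataset(p)
  tgt <- sim$labels$cell_type == "endothelial"
  ratios <- colMeans(sim$expr$values[tgt, sim$truth$de_genes]) /
    colMeans(sim$expr$values[!tgt, sim$truth$de_genes])
  expect_true(all(ratios >= 3 & ratios <= 5.3))
  expect_equal(mean(ratios), 4, tolerance = 0.15)
})

test_that("a null generator plants no separation in truly null genes", {
  # type-I control of the whole simulate -> normalize -> DE chain; markers
  # and receptors are excluded because their target-type distribution is
  # shifted by construction
  rates <- vapply(1:20, function(s) {
    sim <- simulate_dataset(small_params(seed = 100 + s, de_log2fc = 0))
    expr <- normalize_log(sim$expr)
    de <- wilcoxon_de(expr, sim$labels, "endothelial")
    null_genes <- c(sim$truth$de_genes,
                    grep("^BG", de$gene, value = TRUE))
    mean(de$is_de[de$gene %in% null_genes])
  }, numeric(1))
  expect_lte(mean(rates), 0.07)
})

test_that("module factors create real within-module co-expression", {
  gaps <- vapply(1:10, function(s) {
    sim <- simulate_dataset(small_params(seed = 200 + s,
                                         module_factor_sd = 0.5))
    expr <- normalize_log(sim$expr)
    cm <- correlation_matrix(expr, sim$truth$true_receptors,
                             labels = sim$labels,
                             target_type = "endothelial")
    mod <- sim$truth$receptor_modules[rownames(cm)]
    same <- outer(mod, mod, "==") & upper.tri(cm)
    diff <- !outer(mod, mod, "==") & upper.tri(cm)
    mean(cm[same]) - mean(cm[diff])
  }, numeric(1))
  expect_true(all(gaps > 0))
})

test_that("parameter validation rejects impossible designs", {
  expect_error(small_params(neighborhood_size = 10000), "exceeds")
  expect_error(small_params(neighborhood_de_fraction_true = 1.2), "fractions")
  expect_error(small_params(annotated_module_index = 9), "annotated_module")
  expect_error(small_params(n_genes = 50), "exceed")
  expect_error(small_params(de_log2fc = -1), "de_log2fc")
})

test_that("seed receptors are planted in the annotated module", {
  sim <- simulate_dataset(small_params(seed = 5))
  mod <- sim$truth$receptor_modules
  expect_true(all(c("KDR", "FLT1") %in% names(mod)))
  expect_equal(unname(mod[c("KDR", "FLT1")]),
               rep(sim$params$annotated_module_index, 2))
  expect_setequal(sim$gene_sets[[sim$truth$annotated_set_id]],
                  sim$truth$annotated_receptors)
  expect_length(intersect(sim$truth$true_receptors,
                          sim$truth$decoy_receptors), 0)
})

test_that("written datasets read back into equivalent objects", {
  sim <- simulate_dataset(small_params(
    seed = 3,
    n_cells_per_type = c(endothelial = 30, pericyte = 30),
    n_genes = 120, n_de_genes = 15, n_true_receptors = 6,
    n_decoy_receptors = 6, neighborhood_size = 6))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir, fmt = "mtx10x")
  expr <- read_expression(file.path(dir, "expression"), "mtx10x", FALSE)
  expect_identical(expr$values, sim$expr$values)
  labels <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(labels, sim$labels)
  net <- read_network(file.path(dir, "network.tsv"))
  expect_setequal(network_neighbors(net, "KDR"),
                  network_neighbors(sim$network, "KDR"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$de_genes, sim$truth$de_genes)
})
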