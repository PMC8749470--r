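screen_sim <- function(seed = 7) simulate_dataset(small_params(seed = seed))

test_that("the full screen recovers the planted seed module", {
  sim <- screen_sim()
  fit <- receptor_screen(
    sim$expr, sim$network, sim$candidates, labels = sim$labels,
    gene_sets = sim$gene_sets, target_type = "endothelial",
    k = sim$params$n_modules)
  truth <- sim$truth
  expect_true(all(truth$true_receptors %in% fit$selected))
  expect_lte(length(intersect(fit$selected, truth$decoy_receptors)), 2)
  # the cluster holding KDR/FLT1 contains the whole annotated module
  expect_true(all(truth$annotated_receptors %in% fit$seed_cluster_genes))
  expect_lt(fit$geneset_enrichment$p_value, 0.05)
  # summaries cover the seed genes in every type
  expect_setequal(unique(fit$summary$gene), c("KDR", "FLT1"))
  expect_equal(nrow(fit$summary), 2 * length(unique(sim$labels$cell_type)))
  expect_output(print(fit), "seed cluster")
  expect_output(summary(fit), "Seed cluster members")
})

test_that("marker-derived labels give the same screen as planted labels", {
  sim <- screen_sim(seed = 12)
  fit_markers <- receptor_screen(
    sim$expr, sim$network, sim$candidates, markers = sim$markers,
    gene_sets = sim$gene_sets, k = sim$params$n_modules)
  fit_truth <- receptor_screen(
    sim$expr, sim$network, sim$candidates, labels = sim$labels,
    gene_sets = sim$gene_sets, k = sim$params$n_modules)
  expect_setequal(fit_markers$selected, fit_truth$selected)
  expect_true("cell types assigned by marker scoring" %in% fit_markers$notes)
})

test_that("null data passes through with clustering stages skipped", {
  sim <- simulate_dataset(small_params(seed = 30, de_log2fc = 0,
                                       module_factor_sd = 0))
  fit <- receptor_screen(sim$expr, sim$network, sim$candidates,
                         labels = sim$labels, gene_sets = sim$gene_sets)
  expect_lte(length(fit$selected), 1)
  expect_null(fit$clusters)
  expect_null(fit$geneset_enrichment)
  expect_true(any(grepl("clustering stages skipped", fit$notes)))
})

test_that("planted-truth metrics summarize recovery of every stage", {
  m <- planted_truth_metrics(screen_sim(seed = 3))
  expect_gte(m$label_accuracy, 0.95)
  expect_gte(m$de_recall, 0.9)
  # at this reduced scale library-size composition inflates the observed
  # FDR well above the BH level; the study-scale bound is asserted in the
  # acceptance suite
  expect_lte(m$de_observed_fdr, 0.5)
  expect_equal(m$n_true_selected, 9)
  expect_lte(m$n_decoy_selected, 2)
  expect_gte(m$module_ari, 0.8)
  expect_lt(m$annotated_enrichment_p, 0.05)
})

write_pipeline_inputs <- function(dir, seed = 21) {
  sim <- simulate_dataset(small_params(seed = seed))
  write_dataset(sim, dir, fmt = "dense_tsv")
  list(sim = sim,
       cfg = function(out) pipeline_config(
         expression = file.path(dir, "expression.tsv"),
         expression_fmt = "dense_tsv",
         network = file.path(dir, "network.tsv"),
         candidates = file.path(dir, "candidates.tsv"),
         labels = file.path(dir, "labels.tsv"),
         gene_sets = file.path(dir, "gene_sets.gmt"),
         out_dir = out, k = 3, seed = 99))
}

test_that("the pipeline writes complete reports deterministically", {
  dir <- withr::local_tempdir()
  inputs <- write_pipeline_inputs(dir)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  fit <- run_pipeline(inputs$cfg(out1))
  run_pipeline(inputs$cfg(out2))
  reports <- c("cell_type_labels.tsv", "de_table.tsv",
               "receptor_enrichment.tsv", "correlation_matrix.tsv",
               "cluster_assignment.tsv", "cluster_enrichment.tsv",
               "expression_summary.tsv")
  for (f in reports) {
    expect_true(file.exists(file.path(out1, f)), info = f)
    expect_identical(readBin(file.path(out1, f), "raw",
                             file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw",
                             file.size(file.path(out2, f))),
                     info = f)
  }
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$status, "ok")
  expect_equal(manifest$stages$screen$n_selected, length(fit$selected))
  # every reported number is recomputable from the written intermediates
  de <- utils::read.delim(file.path(out1, "de_table.tsv"))
  expect_equal(sum(de$is_de), manifest$stages$screen$n_de)
})

test_that("bad configs fail fast, failed runs still leave a manifest", {
  dir <- withr::local_tempdir()
  inputs <- write_pipeline_inputs(dir, seed = 22)
  expect_error(
    pipeline_config(expression = file.path(dir, "expression.tsv"),
                    expression_fmt = "dense_tsv",
                    network = file.path(dir, "no_such_network.tsv"),
                    candidates = file.path(dir, "candidates.tsv"),
                    labels = file.path(dir, "labels.tsv"),
                    out_dir = file.path(dir, "out")),
    "does not exist")
  cfg <- inputs$cfg(file.path(dir, "failed_run"))
  cfg$target_type <- "no_such_type"
  expect_error(run_pipeline(cfg), "absent")
  manifest <- jsonlite::read_json(file.path(dir, "failed_run",
                                            "manifest.json"))
  expect_equal(manifest$status, "failed")
  expect_equal(manifest$failed_stage, "screen")
})

test_that("YAML configs round-trip through the pipeline", {
  dir <- withr::local_tempdir()
  inputs <- write_pipeline_inputs(dir, seed = 23)
  yml <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    expression = file.path(dir, "expression.tsv"),
    expression_fmt = "dense_tsv",
    network = file.path(dir, "network.tsv"),
    candidates = file.path(dir, "candidates.tsv"),
    labels = file.path(dir, "labels.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    out_dir = file.path(dir, "yaml_out"), k = 3), yml)
  fit <- run_pipeline(yml)
  expect_s3_class(fit, "receptor_screen")
  expect_true(file.exists(file.path(dir, "yaml_out", "manifest.json")))
})
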