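test_that("correlation matrices match hand-computed rank correlations", {
  vals <- cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1), c(1, 3, 2))
  expr <- tiny_expr(vals, genes = c("GA", "GB", "GC", "GD"))
  cm <- correlation_matrix(expr, c("GA", "GB", "GC", "GD"),
                           cell_scope = "all")
  expect_equal(cm["GA", "GB"], 1)
  expect_equal(cm["GA", "GC"], -1)
  # ranks (1,2,3) vs (1,3,2): 1 - 6*2/(3*8) = 0.5
  expect_equal(cm["GA", "GD"], 0.5)
  expect_equal(unclass(cm), t(unclass(cm)), tolerance = 1e-12)
  expect_equal(diag(unclass(cm)), c(GA = 1, GB = 1, GC = 1, GD = 1))
})

test_that("zero-variance genes are flagged and zeroed, scope is honored", {
  vals <- cbind(c(1, 2, 3, 4), c(2, 2, 2, 9), c(4, 3, 2, 1))
  expr <- tiny_expr(vals, genes = c("GA", "GB", "GC"))
  labels <- tiny_labels(expr$cell_ids, c("ec", "ec", "ec", "other"))
  expect_warning(
    cm <- correlation_matrix(expr, c("GA", "GB", "GC"), labels = labels,
                             target_type = "ec"),
    "zero-variance")
  expect_equal(attr(cm, "zero_variance"), "GB")
  expect_equal(cm["GA", "GB"], 0)
  expect_equal(cm["GB", "GB"], 1)
  expect_equal(cm["GA", "GC"], -1)  # computed over the 3 ec cells only
  expect_error(correlation_matrix(expr, "GA", cell_scope = "all"),
               "at least 2 genes")
})

test_that("average-linkage merges follow the hand-executed trace", {
  # d(AB)=0.1 < d(CD)=0.2; then d({A,B},{C,D}) = mean(0.5,0.9,0.6,0.8) = 0.7
  M <- matrix(1, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  M["A", "B"] <- M["B", "A"] <- 0.9
  M["A", "C"] <- M["C", "A"] <- 0.5
  M["A", "D"] <- M["D", "A"] <- 0.1
  M["B", "C"] <- M["C", "B"] <- 0.4
  M["B", "D"] <- M["D", "B"] <- 0.2
  M["C", "D"] <- M["D", "C"] <- 0.8
  cl <- agglomerative_cluster(M, k = 2)
  expect_equal(cl$tree$height, c(0.1, 0.2, 0.7))
  expect_equal(cl$tree$merge, rbind(c(-1, -2), c(-3, -4), c(1, 2)))
  expect_equal(unname(cl$cluster), c(1, 1, 2, 2))
})

test_that("block-structured correlation is split into its blocks", {
  M <- diag(6)
  M[1:3, 1:3] <- 1
  M[4:6, 4:6] <- 1
  dimnames(M) <- list(sprintf("G%d", 1:6), sprintf("G%d", 1:6))
  cl <- agglomerative_cluster(M, k = 2)
  expect_length(unique(cl$cluster[1:3]), 1)
  expect_length(unique(cl$cluster[4:6]), 1)
  expect_false(cl$cluster[1] == cl$cluster[4])
  singles <- agglomerative_cluster(M, k = 6)
  expect_equal(sort(unname(singles$cluster)), 1:6)
  expect_error(agglomerative_cluster(M, k = 7), "k must lie")
})

test_that("linkage heights are nonnegative and nondecreasing", {
  set.seed(12)
  for (i in 1:5) {
    X <- matrix(rnorm(200), 20, dimnames = list(NULL, sprintf("G%d", 1:10)))
    M <- cor(X)
    cl <- agglomerative_cluster(M, k = 3)
    expect_true(all(cl$tree$height >= -1e-12))
    expect_true(all(diff(cl$tree$height) >= -1e-12))
    expect_equal(length(unique(cl$cluster)), 3)
  }
})

test_that("clustering is invariant to gene order away from ties", {
  set.seed(40)
  X <- matrix(rnorm(300), 30, dimnames = list(NULL, sprintf("G%d", 1:10)))
  M <- cor(X)
  cl <- agglomerative_cluster(M, k = 4)
  perm <- sample(nrow(M))
  cl_p <- agglomerative_cluster(M[perm, perm], k = 4)
  expect_equal(adjusted_rand_index(cl$cluster,
                                   cl_p$cluster[names(cl$cluster)]), 1)
})

test_that("the seed cluster is located with the stated precedence", {
  cl <- structure(list(cluster = c(KDR = 3L, FLT1 = 3L, LIFR = 1L),
                       k = 3L, linkage = "average", tree = NULL),
                  class = "cluster_assignment")
  expect_equal(find_seed_cluster(cl, c("KDR", "FLT1")), 3)
  split <- structure(list(cluster = c(KDR = 2L, FLT1 = 5L), k = 5L,
                          linkage = "average", tree = NULL),
                     class = "cluster_assignment")
  expect_warning(id <- find_seed_cluster(split, c("KDR", "FLT1")), "split")
  expect_equal(id, 2)  # tie -> earliest seed's cluster
  maj <- structure(list(cluster = c(KDR = 2L, FLT1 = 5L, NRP1 = 5L), k = 5L,
                        linkage = "average", tree = NULL),
                   class = "cluster_assignment")
  expect_warning(id2 <- find_seed_cluster(maj, c("KDR", "FLT1", "NRP1")),
                 "split")
  expect_equal(id2, 5)  # majority beats seed order
  expect_error(find_seed_cluster(cl, "ABSENT"), "no seed")
})

test_that("cluster gene-set enrichment equals the brute-force tail", {
  genes <- sprintf("G%02d", 1:60)
  assign <- structure(list(
    cluster = stats::setNames(rep(c(1L, 2L, 3L), c(18, 22, 20)), genes),
    k = 3L, linkage = "average", tree = NULL),
    class = "cluster_assignment")
  # set covers 20 of the 60 clustered genes, 15 inside cluster 1
  set <- c(genes[1:15], genes[50:54])
  res <- cluster_geneset_enrichment(assign, 1, set)
  expect_equal(res$overlap, 15)
  expect_equal(res$cluster_size, 18)
  expect_equal(res$set_size_in_universe, 20)
  expect_equal(res$p_value, brute_hyper_tail(15, 20, 18, 60),
               tolerance = 1e-10)
  # degenerate cases
  whole <- structure(list(cluster = stats::setNames(rep(1L, 10), genes[1:10]),
                          k = 1L, linkage = "average", tree = NULL),
                     class = "cluster_assignment")
  expect_equal(cluster_geneset_enrichment(whole, 1, genes[1:4])$p_value, 1)
  expect_equal(cluster_geneset_enrichment(assign, 2, genes[1:10])$p_value, 1)
  expect_error(cluster_geneset_enrichment(assign, 1, "ZZZ"),
               "does not intersect")
  # wider universe: all scored candidates
  res2 <- cluster_geneset_enrichment(assign, 1, set,
                                     universe_policy = "scored_candidates",
                                     candidate_universe = c(genes, "EXTRA"))
  expect_equal(res2$universe_size, 61)
  expect_equal(res2$p_value, brute_hyper_tail(15, 20, 18, 61),
               tolerance = 1e-10)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:10) {
    a <- sample(3, 40, replace = TRUE)
    b <- sample(4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
})
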