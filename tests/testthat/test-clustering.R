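test_that("the missing-value filter applies the 30% rule exactly", {
  mat <- matrix(1, 3, 8, dimnames = list(c("a", "b", "c"), condition_levels()))
  mat["a", 1:3] <- NA  # 37.5% -> removed
  mat["b", 1:2] <- NA  # 25%   -> retained
  out <- filter_missing(mat, 0.30)
  expect_setequal(rownames(out), c("b", "c"))
  expect_equal(out["c", ], mat["c", ])  # untouched values
  expect_error(filter_missing(matrix(NA_real_, 2, 8), 0.3), "pipeline error")
})

test_that("K is chosen at the largest relative dendrogram gap", {
  set.seed(31)
  blobs <- rbind(matrix(rnorm(30 * 8, 0, 0.1), 30),
                 matrix(rnorm(30 * 8, 20, 0.1), 30),
                 matrix(rnorm(30 * 8, -20, 0.1), 30))
  rownames(blobs) <- sprintf("g%03d", 1:90)
  expect_equal(choose_k(blobs), 3)
  # exhaustive oracle over the same scan
  hc <- hclust(dist(blobs), "average")
  h <- hc$height
  ks <- 2:15
  expect_equal(choose_k(blobs), ks[which.max(h[90 - ks + 1] / h[90 - ks])])
  expect_equal(choose_k(blobs), choose_k(blobs))  # deterministic
  flat <- matrix(1, 25, 8, dimnames = list(sprintf("g%02d", 1:25), NULL))
  expect_warning(kflat <- choose_k(flat), "degenerate")
  expect_equal(kflat, 2)
})

test_that("the K-means runs are seeded, exact on separated blobs and label-complete", {
  set.seed(5)
  two <- rbind(matrix(rnorm(10 * 8, 0, 0.1), 10),
               matrix(rnorm(10 * 8, 10, 0.1), 10))
  rownames(two) <- sprintf("g%02d", 1:20)
  l <- kmeans_run(two, 2, seed = 3)
  expect_equal(adjusted_rand_index(l, rep(1:2, each = 10)), 1)
  expect_identical(l, kmeans_run(two, 2, seed = 3))
  expect_equal(unname(kmeans_run(two, 1, seed = 1)), rep(1L, 20))
  expect_error(kmeans_run(two, 25, seed = 1), "input error")
  # cross-check against the reference implementation on a clean instance
  ref <- kmeans(two, centers = 2, nstart = 5)$cluster
  expect_equal(adjusted_rand_index(l, ref), 1)
})

test_that("consensus of identical runs returns that partition with none unclustered", {
  lab <- setNames(rep(1:3, each = 5), sprintf("g%02d", 1:15))
  agg <- consensus_aggregate(replicate(5, lab, simplify = FALSE), 0.6)
  expect_equal(adjusted_rand_index(agg$cluster, lab), 1)
  expect_false(anyNA(agg$cluster))
  expect_true(all(diag(agg$cooccurrence) == 1))
})

test_that("a gene co-clustered in only 2 of 5 runs is unclustered", {
  ids <- sprintf("g%02d", 1:11)
  with1 <- setNames(c(rep(1L, 5), rep(2L, 5), 1L), ids)
  with2 <- with1; with2["g11"] <- 2L
  alone <- with1; alone["g11"] <- 3L
  runs <- list(with1, with1, with2, with2, alone)
  agg <- consensus_aggregate(runs, 0.6)
  expect_true(is.na(agg$cluster["g11"]))  # 0.4 < 0.6 with either group
  expect_false(anyNA(agg$cluster[setdiff(ids, "g11")]))
})

test_that("consensus is invariant to run order and errors on inconsistent gene sets", {
  set.seed(12)
  mat <- impute_zero(rbind(matrix(rnorm(40, 0, 0.3), 5),
                           matrix(rnorm(40, 4, 0.3), 5)))
  rownames(mat) <- sprintf("g%02d", 1:10)
  runs <- lapply(1:5, function(s) kmeans_run(mat, 2, seed = s))
  a <- consensus_aggregate(runs, 0.6)
  b <- consensus_aggregate(rev(runs), 0.6)
  expect_identical(a$cluster, b$cluster)
  bad <- runs; names(bad[[2]])[1] <- "zz"
  expect_error(consensus_aggregate(bad, 0.6), "inconsistent")
})

test_that("raising the co-occurrence threshold never decreases the unclustered count", {
  set.seed(23)
  cfg <- synthetic_config(n_genes = 300, n_regulated = 150, seed = 23)
  prof <- generate_profiles(cfg)
  reg <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  mat <- impute_zero(prof$matrix[reg, ])
  runs <- lapply(1:5, function(s) kmeans_run(mat, 9, seed = s))
  uncl <- sapply(seq(0.2, 0.95, by = 0.15), function(th)
    sum(is.na(consensus_aggregate(runs, th)$cluster)))
  expect_true(all(diff(uncl) >= 0))
})

test_that("assigned plus unclustered genes always add up to the matrix genes", {
  cfg <- synthetic_config(n_genes = 300, n_regulated = 150, seed = 29)
  prof <- generate_profiles(cfg)
  reg <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  cc <- consensus_cluster(prof$matrix[reg, ], seed = 2)
  expect_equal(sum(!is.na(cc$cluster)) + sum(is.na(cc$cluster)), length(reg))
  expect_equal(nrow(cc$assignment), length(reg))
})

test_that("cluster directions follow the extremum sign and report exact-zero ties", {
  expect_equal(classify_direction(c(0, 0.2, 1.5, 2.0, 0, 0, 0, 0)), "up")
  expect_equal(classify_direction(c(-0.1, -1.2, 0, 0, 0, 0, 0, 0)), "down")
  expect_error(classify_direction(rep(0, 8)), "tie error")
  # archetype-generated clusters carry the archetype signs (noise-free)
  cfg <- synthetic_config(n_genes = 200, n_regulated = 150, noise_sd = 0)
  prof <- generate_profiles(cfg)
  reg <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  cc <- consensus_cluster(prof$matrix[reg, ], seed = 3, K = 9)
  arch_dir <- apply(default_archetypes(), 1, classify_direction)
  for (k in rownames(cc$profiles)) {
    members <- names(cc$cluster)[!is.na(cc$cluster) & cc$cluster == as.integer(k)]
    true_arch <- unique(prof$true_cluster[members])
    expect_length(true_arch, 1)
    expect_equal(unname(cc$directions[k]), unname(arch_dir[true_arch]))
  }
})

test_that("consensus clustering recovers the archetype partition on default data", {
  cfg <- synthetic_config(seed = 301)
  prof <- generate_profiles(cfg)
  reg <- names(prof$true_cluster)[!is.na(prof$true_cluster)]
  cc <- consensus_cluster(prof$matrix[reg, ], seed = 301)
  expect_gte(adjusted_rand_index(prof$true_cluster[reg], cc$cluster), 0.9)
})

test_that("the in-package ARI agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(44)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
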