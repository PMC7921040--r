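test_that("feature matrices are built, scaled and missing-aware", {
  g <- tiny_grid(n = 16, elements = c("12C", "79Br"))
  g$intensity[["12C"]][c(3, 9)] <- NA

  fm <- build_features(g, feature_spec(c("79Br", "12C"), include_xy = TRUE))
  expect_equal(ncol(fm$features), 4)
  expect_equal(fm$excluded, c(3L, 9L))
  expect_equal(nrow(fm$features), 14)
  expect_false(anyNA(fm$features))
  # population z-score: mean 0, sd 1
  for (j in 1:4) {
    expect_lt(abs(mean(fm$features[, j])), 1e-12)
    expect_lt(abs(sqrt(mean((fm$features[, j])^2)) - 1), 1e-12)
  }

  g2 <- tiny_grid(n = 8)
  g2$intensity$A <- rep(5, 8)
  expect_warning(fm2 <- build_features(g2, feature_spec(c("A", "B"))),
                 class = "elemap_constant_feature_warning")
  expect_true(all(fm2$features[, "A"] == 0))

  expect_error_class(build_features(g, feature_spec("nope")),
                     "elemap_config_error")
  expect_error_class(feature_spec(character(), include_xy = FALSE),
                     "elemap_config_error")
})

test_that("cluster dispatch validates algorithms and mandatory parameters", {
  X <- three_blobs(1)
  expect_error_class(cluster_pixels(X, "optics", list()), "elemap_config_error")
  err <- tryCatch(cluster_pixels(X, "dbscan", list(eps = 1)), error = identity)
  expect_s3_class(err, "elemap_config_error")
  expect_match(conditionMessage(err), "min_samples")
  expect_error_class(cluster_pixels(X, "hdbscan", list()), "elemap_config_error")

  one <- cluster_pixels(X, "kmeans", list(n_clusters = 1), seed = 1)
  expect_true(all(one$labels == 0L))
})

test_that("kmeans separates planted blobs and is bit-reproducible", {
  X <- three_blobs(4, sep = 40, sd = 1)  # ~20 sigma separation, 2 blobs case
  truth <- rep(1:3, each = 100)
  cl <- cluster_pixels(X, "kmeans", list(n_clusters = 3), seed = 9)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1.0)
  cl2 <- cluster_pixels(X, "kmeans", list(n_clusters = 3), seed = 9)
  expect_identical(cl$labels, cl2$labels)
  cl3 <- cluster_pixels(X, "kmeans", list(n_clusters = 3), seed = 10)
  expect_equal(mclust::adjustedRandIndex(cl3$labels, cl$labels), 1.0)
})

test_that("density algorithms reproduce the sklearn oracle partition", {
  # two tight blobs of 20 plus 5 far outliers; expected structure computed
  # independently with scikit-learn DBSCAN/HDBSCAN on the same fixture
  with_seed_local(42, {
    X <- rbind(matrix(rnorm(40, 0, .3), ncol = 2),
               matrix(rnorm(40, 10, .3), ncol = 2),
               matrix(runif(10, 30, 60), ncol = 2))
  })
  truth <- c(rep(1, 20), rep(2, 20), rep(3, 5))
  db <- cluster_pixels(X, "dbscan", list(eps = 1.5, min_samples = 4))
  expect_equal(sort(unique(db$labels)), c(-1L, 0L, 1L))
  expect_equal(sum(db$labels == -1L), 5)
  expect_equal(mclust::adjustedRandIndex(db$labels[1:40], truth[1:40]), 1.0)

  hd <- cluster_pixels(X, "hdbscan", list(min_cluster_size = 7))
  expect_equal(sort(unique(hd$labels)), c(-1L, 0L, 1L))
  expect_equal(sum(hd$labels == -1L), 5)
  expect_equal(mclust::adjustedRandIndex(hd$labels[1:40], truth[1:40]), 1.0)

  # determinism of the density path
  expect_identical(hd$labels,
                   cluster_pixels(X, "hdbscan", list(min_cluster_size = 7))$labels)
})

test_that("mean shift, affinity propagation and spectral find two clean blobs", {
  with_seed_local(8, {
    X <- rbind(matrix(rnorm(60, 0, .4), ncol = 2),
               matrix(rnorm(60, 12, .4), ncol = 2))
  })
  truth <- rep(1:2, each = 30)
  ms <- cluster_pixels(X, "meanshift", list(bandwidth = 3))
  expect_equal(mclust::adjustedRandIndex(ms$labels, truth), 1.0)

  ap <- cluster_pixels(X, "affinity_propagation", list(damping = 0.9), seed = 1)
  expect_equal(mclust::adjustedRandIndex(ap$labels, truth), 1.0)

  sp <- cluster_pixels(X, "spectral", list(n_clusters = 2), seed = 1)
  expect_equal(mclust::adjustedRandIndex(sp$labels, truth), 1.0)
})

test_that("excluded pixels stay excluded through clustering and export", {
  g <- tiny_grid(n = 20)
  g$intensity$A[c(2, 17)] <- NA
  fm <- build_features(g, feature_spec("A"))
  cl <- cluster_pixels(fm, "kmeans", list(n_clusters = 2), seed = 1)
  expect_true(all(is.na(cl$labels[c(2, 17)])))
  expect_equal(sum(is.na(cl$labels)), 2)
  path <- withr_tempfile(".csv")
  write_labels_csv(cl, g, path)
  df <- utils::read.csv(path, colClasses = "character")
  expect_equal(sum(df$label == "excluded"), 2)
})

test_that("elbow rule recovers a planted k and handles forced ranges", {
  forced <- elbow_k(three_blobs(1), 4, 4, seed = 1)
  expect_equal(forced$chosen_k, 4L)
  expect_length(forced$inertia, 1)

  hits <- vapply(1:20, function(s) {
    elbow_k(three_blobs(s), 1, 8, seed = s)$chosen_k == 3L
  }, logical(1))
  expect_gte(sum(hits), 18)

  # inertia is non-increasing in k (best-of-10 restarts)
  e <- elbow_k(three_blobs(2), 1, 8, seed = 2)
  expect_true(all(diff(e$inertia) <= 1e-9))
})

test_that("canonical relabeling orders clusters by reference intensity", {
  ds <- render_scene(synth_scene(seed = 6))
  fm <- build_features(ds$grid, feature_spec("12C"))
  cl <- cluster_pixels(fm, "kmeans", list(n_clusters = 4), seed = 6)
  can <- canonical_relabel(cl, ds$grid, "12C")
  means <- vapply(0:3, function(c) {
    mean(ds$grid$intensity[["12C"]][!is.na(can$labels) & can$labels == c])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # relabeling is a fixpoint
  again <- canonical_relabel(can, ds$grid, "12C")
  expect_identical(again$labels, can$labels)

  # permutation invariance: any renumbering canonicalizes identically
  for (seed in 1:5) {
    perm <- with_seed_local(seed, sample(0:3))
    shuffled <- cl
    shuffled$labels <- perm[cl$labels + 1L]
    expect_identical(canonical_relabel(shuffled, ds$grid, "12C")$labels,
                     can$labels)
  }

  # noise pixels stay -1
  lab <- cluster_labels(c(-1L, -1L, 0L, 1L, 1L), "fixture")
  g5 <- pixel_grid((0:4) * 35, rep(0, 5), data.frame(R = c(9, 9, 5, 1, 1)))
  expect_equal(canonical_relabel(lab, g5, "R")$labels[1:2], c(-1L, -1L))
})
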