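two_blob_fixture <- function() {
  planted_clusters(30, list(c(0.1, 0.4, 0.4, 0.1), c(0.4, 0.1, 0.1, 0.4)),
                   length = 2000, seed = 1)
}

test_that("k-means recovers planted composition clusters and edge cases", {
  fx <- two_blob_fixture()
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  res <- kmeans_cluster(m, 2, seed = 1)
  expect_equal(ari(res$labels, fx$labels), 1.0)
  expect_true(all(res$labels %in% 0:1))
  expect_equal(length(res$labels), 60L)

  one <- kmeans_cluster(m, 1, seed = 1)
  expect_true(all(one$labels == 0L))
  expect_equal(unname(one$centers[1, ]), unname(colMeans(m$values)),
               tolerance = 1e-12)

  sub <- m; sub$values <- m$values[1:5, ]
  all_own <- kmeans_cluster(sub, 5, seed = 1)
  expect_equal(sort(all_own$labels), 0:4)   # each point its own cluster
  expect_error(kmeans_cluster(sub, 6, seed = 1),
               class = "motifclust_usage_error")
  expect_error(kmeans_cluster(sub, 0, seed = 1),
               class = "motifclust_usage_error")
})

test_that("k-means labelling is deterministic given the seed", {
  fx <- two_blob_fixture()
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  expect_identical(kmeans_cluster(m, 2, seed = 3)$labels,
                   kmeans_cluster(m, 2, seed = 3)$labels)
})

test_that("PCA projection: variance fractions, rank-1 data, duplication", {
  # points on a line: one component carries all variance
  line <- outer(1:6, c(1, -2, 0.5))
  dimnames(line) <- list(paste0("r", 1:6), paste0("c", 1:3))
  pr <- pca_project(line, 2)
  expect_equal(pr$explained_variance[1], 1.0, tolerance = 1e-9)

  set.seed(4)
  v <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  full <- pca_project(v, 5)
  expect_true(all(diff(full$explained_variance) <= 1e-12))
  expect_equal(sum(full$explained_variance), 1, tolerance = 1e-9)
  # completeness: reconstruction from all components equals centered input
  centered <- scale(v, scale = FALSE)
  expect_equal(unname(full$embedding %*% t(full$rotation)),
               unname(centered), tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated dataset keeps the same components
  dup <- rbind(v, v)
  rownames(dup) <- paste0("r", 1:16)
  pdup <- pca_project(dup, 3)
  expect_equal(abs(pdup$rotation), abs(pca_project(v, 3)$rotation),
               tolerance = 1e-9)
  expect_error(pca_project(v, 6), class = "motifclust_usage_error")
})

test_that("pca_kmeans separates planted clusters and keeps the embedding", {
  fx <- two_blob_fixture()
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  res <- pca_kmeans(m, 2, seed = 1)
  expect_equal(ari(res$labels, fx$labels), 1.0)
  expect_equal(dim(res$embedding), c(60L, 2L))
  expect_equal(res$method, "pca_kmeans")
  one <- pca_kmeans(m, 1, seed = 1)
  expect_equal(one$n_clusters, 1L)
  expect_false(is.null(one$embedding))
})

test_that("five separated compositions are recovered with k = 5", {
  fx <- planted_clusters(20, list(c(0.55, 0.15, 0.15, 0.15),
                                  c(0.15, 0.55, 0.15, 0.15),
                                  c(0.15, 0.15, 0.55, 0.15),
                                  c(0.15, 0.15, 0.15, 0.55),
                                  c(0.25, 0.25, 0.25, 0.25)),
                         length = 2000, seed = 2)
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  res <- pca_kmeans(m, 5, seed = 1)
  expect_gte(ari(res$labels, fx$labels), 0.95)
})

test_that("mean shift finds the cluster count from the data", {
  fx <- two_blob_fixture()
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  res <- meanshift_cluster(m, seed = 1)
  expect_equal(res$n_clusters, 2L)
  expect_equal(ari(res$labels, fx$labels), 1.0)
  expect_gt(res$params$bandwidth, 0)

  # huge bandwidth: one kernel covers everything
  huge <- meanshift_cluster(m, bandwidth = 1e6)
  expect_equal(huge$n_clusters, 1L)
  # tiny bandwidth on distinct points: every point a mode
  set.seed(8)
  pts <- matrix(runif(20), 10, 2)
  tiny <- meanshift_cluster(pts, bandwidth = 1e-9)
  expect_equal(tiny$n_clusters, 10L)
  # identical points: single cluster with a warning
  same <- matrix(1, 5, 3)
  expect_warning(res1 <- meanshift_cluster(same), "identical")
  expect_equal(res1$n_clusters, 1L)
  expect_error(meanshift_cluster(m, bandwidth = -1),
               class = "motifclust_usage_error")
})

test_that("clustermap ordering: permutations, duplicates adjacent, monotone heights", {
  set.seed(12)
  v <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  v[3, ] <- v[1, ]   # exact duplicate rows
  cm <- clustermap(v, linkage = "single")
  expect_setequal(cm$row_order, 1:8)
  expect_setequal(cm$col_order, 1:5)
  pos <- match(c(1, 3), cm$row_order)
  expect_equal(abs(diff(pos)), 1L)              # duplicates adjacent
  expect_equal(cm$row_merges$height[1], 0)      # merged first at height 0
  expect_true(all(diff(cm$row_merges$height) >= -1e-12))

  two <- clustermap(v[1:2, 1:2])
  expect_setequal(two$row_order, 1:2)
  expect_setequal(two$col_order, 1:2)
  expect_error(clustermap(v[1, , drop = FALSE]),
               class = "motifclust_usage_error")
  vbad <- v; vbad[2, 2] <- NA
  expect_error(clustermap(vbad), class = "motifclust_computation_error")
})

test_that("single-linkage merge heights equal brute-force MST edge weights", {
  for (seed in c(12, 99)) {
    set.seed(seed)
    v <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
    cm <- clustermap(v, linkage = "single")
    expect_equal(sort(cm$row_merges$height),
                 prim_mst_weights(dist(v)), tolerance = 1e-9)
  }
})

test_that("k-means inertia never increases across Lloyd iterations", {
  fx <- two_blob_fixture()
  v <- build_matrix(fx$records, basis = "frequency", ks = 2)$values
  set.seed(3)
  centers <- v[sample(nrow(v), 3), ]
  inertia <- c()
  for (it in 1:10) {
    d2 <- sapply(seq_len(nrow(centers)), function(j)
      colSums((t(v) - centers[j, ])^2))
    lab <- apply(d2, 1, which.min)
    inertia <- c(inertia, sum(d2[cbind(seq_len(nrow(v)), lab)]))
    for (j in unique(lab)) centers[j, ] <- colMeans(v[lab == j, , drop = FALSE])
  }
  expect_true(all(diff(inertia) <= 1e-9))
})
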