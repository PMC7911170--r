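as_values <- function(matrix) {
  v <- if (inherits(matrix, "feature_matrix")) matrix$values else as.matrix(matrix)
  if (!is.numeric(v) || !all(is.finite(v))) {
    abort_motif("matrix must be numeric and finite", "computation")
  }
  v
}

new_clustering_result <- function(method, labels, centers, params,
                                  ids = NULL, embedding = NULL,
                                  explained_variance = NULL) {
  structure(list(method = method, labels = as.integer(labels),
                 n_clusters = length(unique(labels)), centers = centers,
                 embedding = embedding,
                 explained_variance = explained_variance,
                 params = params, ids = ids),
            class = "clustering_result")
}

#' K-means clustering of a feature matrix
#'
#' Runs [stats::kmeans()] (Lloyd-style iterations, 10 random restarts, best
#' within-cluster sum of squares kept) on the matrix rows. Labels are
#' 0-based and deterministic given the seed.
#'
#' @param matrix A `feature_matrix` or numeric matrix (rows = sequences).
#' @param k Number of clusters, `1 <= k <=` number of rows.
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts.
#' @return A `clustering_result`: `method`, `labels` (0-based), `n_clusters`,
#'   `centers`, `params`, `ids`.
#' @export
kmeans_cluster <- function(matrix, k, seed = 0L, nstart = 10L) {
  v <- as_values(matrix)
  if (length(k) != 1L || k < 1L || k > nrow(v)) {
    abort_motif(sprintf("k must be in [1, %d]", nrow(v)))
  }
  set.seed(seed)
  km <- if (k == nrow(v)) {
    # every point its own cluster: closed form, avoids degenerate sampling
    list(cluster = seq_len(nrow(v)), centers = v)
  } else {
    stats::kmeans(v, centers = k, nstart = nstart, iter.max = 100L)
  }
  new_clustering_result("kmeans", km$cluster - 1L, km$centers,
                        params = list(k = as.integer(k), seed = seed,
                                      nstart = nstart),
                        ids = rownames(v))
}

#' Principal component projection
#'
#' Column-centered PCA via [stats::prcomp()]. For determinism each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param matrix A `feature_matrix` or numeric matrix.
#' @param n_components Number of components, at most `min(rows, cols)`.
#' @return List with `embedding` (rows x n_components score matrix),
#'   `rotation` (loadings) and `explained_variance` (non-increasing
#'   fractions of total variance, one per component).
#' @export
pca_project <- function(matrix, n_components = 2L) {
  v <- as_values(matrix)
  if (n_components < 1L || n_components > min(dim(v))) {
    abort_motif(sprintf("n_components must be in [1, %d]", min(dim(v))))
  }
  p <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  p$rotation[, flip] <- -p$rotation[, flip]
  p$x[, flip] <- -p$x[, flip]
  idx <- seq_len(n_components)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(embedding = p$x[, idx, drop = FALSE],
       rotation = p$rotation[, idx, drop = FALSE],
       explained_variance = ev[idx])
}

#' PCA followed by K-means
#'
#' Max-abs normalizes the matrix (if not already normalized), projects onto
#' the leading principal components, and runs K-means in the reduced space.
#' The 2-D embedding is kept on the result for scatter plotting.
#'
#' @inheritParams kmeans_cluster
#' @param n_components Number of principal components to cluster in.
#' @return A `clustering_result` with an `embedding` field.
#' @export
pca_kmeans <- function(matrix, k, n_components = 2L, seed = 0L) {
  if (inherits(matrix, "feature_matrix") && !matrix$normalized) {
    matrix <- maxabs_normalize(matrix)
  }
  pr <- pca_project(matrix, n_components)
  res <- kmeans_cluster(pr$embedding, k, seed = seed)
  res$method <- "pca_kmeans"
  res$embedding <- pr$embedding[, seq_len(min(2L, n_components)), drop = FALSE]
  res$explained_variance <- pr$explained_variance
  res$params <- c(res$params, list(n_components = as.integer(n_components)))
  res
}

# mean distance to each point's floor(quantile * n)-th nearest neighbour
estimate_bandwidth <- function(v, quantile = 0.3) {
  d <- as.matrix(stats::dist(v))
  kth <- max(1L, floor(quantile * nrow(v)))
  mean(apply(d, 1L, function(r) sort(r)[kth + 1L]))
}

#' Mean-shift clustering with automatic bandwidth
#'
#' Flat-kernel mean shift: every point is shifted iteratively to the mean of
#' all points within one bandwidth until convergence (tolerance
#' `1e-3 * bandwidth`, at most 300 iterations); converged modes closer than
#' one bandwidth are merged (most-populated first) and points are assigned
#' to the nearest surviving mode. The number of clusters emerges from the
#' kernel density rather than being user-set. When `bandwidth` is absent it
#' is estimated as the mean distance to each point's `floor(0.3 n)`-th
#' nearest neighbour.
#'
#' @inheritParams kmeans_cluster
#' @param bandwidth Optional positive kernel radius; estimated when `NULL`.
#' @param quantile Nearest-neighbour quantile for the bandwidth estimate.
#' @param max_iter Iteration cap per seed point.
#' @return A `clustering_result` (`method = "meanshift"`); `params` records
#'   the bandwidth actually used.
#' @export
meanshift_cluster <- function(matrix, bandwidth = NULL, seed = 0L,
                              quantile = 0.3, max_iter = 300L) {
  v <- as_values(matrix)
  if (nrow(v) == 0L) abort_motif("matrix has no rows")
  if (!is.null(bandwidth) && bandwidth <= 0) {
    abort_motif("bandwidth must be positive")
  }
  bw <- bandwidth %||% estimate_bandwidth(v, quantile)
  if (bw == 0) {
    warning("zero bandwidth estimate (all points identical): one cluster",
            call. = FALSE)
    return(new_clustering_result(
      "meanshift", rep(0L, nrow(v)), v[1L, , drop = FALSE],
      params = list(bandwidth = 0, quantile = quantile, seed = seed),
      ids = rownames(v)))
  }
  tol <- 1e-3 * bw
  modes <- v
  support <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    for (iter in seq_len(max_iter)) {
      d2 <- colSums((t(v) - x)^2)
      within <- d2 <= bw^2
      new_x <- colMeans(v[within, , drop = FALSE])
      if (sqrt(sum((new_x - x)^2)) < tol) { x <- new_x; break }
      x <- new_x
    }
    modes[i, ] <- x
    support[i] <- sum(colSums((t(v) - x)^2) <= bw^2)
  }
  # merge modes closer than one bandwidth, highest support first
  ord <- order(-support, seq_along(support))  # ties: earliest point wins
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        min(sqrt(rowSums(sweep(modes[kept, , drop = FALSE], 2L,
                               modes[i, ])^2))) > bw) {
      kept <- c(kept, i)
    }
  }
  centers <- modes[kept, , drop = FALSE]
  labels <- apply(v, 1L, function(x) {
    which.min(colSums((t(centers) - x)^2)) - 1L
  })
  # re-index so every label in [0, n_clusters) occurs
  used <- sort(unique(labels))
  labels <- match(labels, used) - 1L
  centers <- centers[used + 1L, , drop = FALSE]
  rownames(centers) <- NULL
  new_clustering_result("meanshift", labels, centers,
                        params = list(bandwidth = bw, quantile = quantile,
                                      seed = seed),
                        ids = rownames(v))
}

#' Hierarchical clustermap ordering of rows and columns
#'
#' Agglomerative hierarchical clustering ([stats::hclust()]) of the matrix
#' rows and of the matrix columns, giving the permutations and merge records
#' that a clustered heatmap draws. Single linkage is mathematically
#' equivalent to building a minimum spanning tree of the pairwise distance
#' graph: its merge heights are the sorted MST edge weights. Average linkage
#' is the conventional clustermap default.
#'
#' @param matrix A `feature_matrix` or numeric matrix with >= 2 rows and
#'   >= 2 columns.
#' @param metric Distance metric name accepted by [stats::dist()]
#'   (default `"euclidean"`).
#' @param linkage `"average"` (default) or `"single"`.
#' @return A `clustermap_result`: `row_order`/`col_order` (1-based leaf
#'   permutations), `row_merges`/`col_merges` (data frames with columns
#'   `a`, `b` — hclust-style merge indices — and `height`),
#'   `row_hclust`/`col_hclust`, `metric`, `linkage`.
#' @export
clustermap <- function(matrix, metric = "euclidean",
                       linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  v <- as_values(matrix)
  if (nrow(v) < 2L || ncol(v) < 2L) {
    abort_motif("clustermap needs at least 2 rows and 2 columns")
  }
  hc_rows <- stats::hclust(stats::dist(v, method = metric), method = linkage)
  hc_cols <- stats::hclust(stats::dist(t(v), method = metric), method = linkage)
  merges <- function(hc) data.frame(a = hc$merge[, 1L], b = hc$merge[, 2L],
                                    height = hc$height)
  structure(list(row_order = hc_rows$order, col_order = hc_cols$order,
                 row_merges = merges(hc_rows), col_merges = merges(hc_cols),
                 row_hclust = hc_rows, col_hclust = hc_cols,
                 metric = metric, linkage = linkage,
                 dim = dim(v)),
            class = "clustermap_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("%s clustering: %d points in %d cluster(s)\n",
              x$method, length(x$labels), x$n_clusters))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
print.clustermap_result <- function(x, ...) {
  cat(sprintf("clustermap ordering (%s distance, %s linkage): %d rows x %d cols\n",
              x$metric, x$linkage, x$dim[1], x$dim[2]))
  invisible(x)
}
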