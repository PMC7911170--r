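expect_valid_image <- function(path) {
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
  ext <- tolower(sub(".*\\.", "", path))
  head <- readBin(path, "raw", 8)
  if (ext == "png") {
    expect_identical(head[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))
  } else if (ext == "pdf") {
    expect_identical(rawToChar(head[1:4]), "%PDF")
  }
}

small_matrix <- function(n = 4, basis = "frequency", ks = 2) {
  recs <- generate_iid(n, 400, seed = 21)
  build_matrix(recs, basis = basis, ks = ks)
}

test_that("plot_spec validates its output extension", {
  expect_s3_class(plot_spec("heatmap", "a.png"), "plot_spec")
  expect_error(plot_spec("heatmap", "a.bmp"), class = "motifclust_usage_error")
})

test_that("bar3d renders small matrices and guards against illegible ones", {
  m <- select_motifs(small_matrix(), names = c("AA", "AT", "GT", "TT"))
  path <- tempfile(fileext = ".png")
  before <- m
  plot_bar3d(m, plot_spec("bar3d", path, title = "demo"))
  expect_valid_image(path)
  expect_identical(m, before)               # input not mutated

  one <- m; one$values <- m$values[1, 1, drop = FALSE]
  p1 <- tempfile(fileext = ".pdf")
  plot_bar3d(one, plot_spec("bar3d", p1))
  expect_valid_image(p1)

  big <- motifclust:::new_feature_matrix(
    matrix(1, 60, 10, dimnames = list(paste0("s", 1:60), paste0("m", 1:10))),
    "frequency")
  expect_error(plot_bar3d(big, plot_spec("bar3d", tempfile(fileext = ".png"))),
               "subset")
  # ... but the override renders it
  pbig <- tempfile(fileext = ".png")
  plot_bar3d(big, plot_spec("bar3d", pbig), override = TRUE)
  expect_valid_image(pbig)
})

test_that("heatmap renders, keeps labels faithful, and rejects bad input", {
  m <- small_matrix(3, basis = "dratio", ks = 3)
  path <- tempfile(fileext = ".png")
  out <- plot_heatmap(m, plot_spec("heatmap", path))
  expect_valid_image(path)
  built <- ggplot2::ggplot_build(out$plot)
  expect_setequal(levels(out$plot$data$motif), colnames(m$values))
  expect_setequal(levels(out$plot$data$sequence), rownames(m$values))

  const <- motifclust:::new_feature_matrix(
    matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("m", 1:3))),
    "frequency")
  pc <- tempfile(fileext = ".png")
  plot_heatmap(const, plot_spec("heatmap", pc))   # degenerate range is fine
  expect_valid_image(pc)

  bad <- const; bad$values[1, 1] <- NaN
  expect_error(plot_heatmap(bad, plot_spec("heatmap", pc)),
               class = "motifclust_computation_error")
})

test_that("clustermap plot permutes by the precomputed ordering", {
  fx <- planted_clusters(4, list(c(0.1, 0.4, 0.4, 0.1), c(0.4, 0.1, 0.1, 0.4)),
                         length = 1000, seed = 3)
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  cm <- clustermap(m)
  path <- tempfile(fileext = ".png")
  plot_clustermap(cm, m, plot_spec("clustermap", path))
  expect_valid_image(path)
  # planted groups are contiguous in the leaf order
  leaf_labels <- fx$labels[cm$row_order]
  expect_equal(sum(diff(leaf_labels) != 0), 1L)

  other <- small_matrix(3)
  expect_error(plot_clustermap(cm, other, plot_spec("clustermap", path)),
               class = "motifclust_usage_error")
})

test_that("pca scatter needs an embedding and shows one legend entry per cluster", {
  fx <- planted_clusters(10, list(c(0.1, 0.4, 0.4, 0.1), c(0.4, 0.1, 0.1, 0.4)),
                         length = 1000, seed = 5)
  m <- build_matrix(fx$records, basis = "frequency", ks = 2)
  res <- pca_kmeans(m, 2, seed = 1)
  path <- tempfile(fileext = ".png")
  out <- plot_pca_scatter(res, plot_spec("pca_scatter", path))
  expect_valid_image(path)
  expect_equal(nlevels(out$plot$data$cluster), 2L)

  one <- pca_kmeans(m, 1, seed = 1)
  p1 <- tempfile(fileext = ".png")
  out1 <- plot_pca_scatter(one, plot_spec("pca_scatter", p1))
  expect_equal(nlevels(out1$plot$data$cluster), 1L)

  km <- kmeans_cluster(m, 2, seed = 1)
  expect_error(plot_pca_scatter(km, plot_spec("pca_scatter", path)),
               "pca_kmeans")
})
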