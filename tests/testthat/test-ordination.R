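random_clr <- function(D = 10, S = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(D * S, 5), nrow = D,
                dimnames = list(sprintf("f%02d", 1:D),
                                sprintf("s%02d", 1:S)))
    clr_transform(m)
  })
}

test_that("pca matches a covariance-eigendecomposition oracle", {
  for (seed in 1:6) {
    cm <- random_clr(D = 10, S = 6, seed = seed)
    pca <- pca_clr(cm)
    X <- t(unclass(cm))
    Xc <- sweep(X, 2, colMeans(X), "-")
    lam <- eigen(stats::cov(Xc), symmetric = TRUE)$values
    ve_oracle <- lam / sum(lam)
    k <- min(length(pca$variance_explained), sum(lam > 1e-12 * lam[1]))
    expect_equal(pca$variance_explained[1:k], ve_oracle[1:k],
                 tolerance = 1e-8)
    expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-9)
    expect_true(all(diff(pca$singular_values) <= 1e-12))
    # CLR + centering leaves at most min(n-1, D-1) real dimensions
    thresh <- 1e-8 * pca$singular_values[1]
    expect_lte(sum(pca$singular_values > thresh),
               min(ncol(cm) - 1, nrow(cm) - 1))
    # form biplot reconstructs the centered matrix
    expect_equal(pca$scores %*% t(pca$loadings), Xc, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("pca handles degenerate sample layouts", {
  cm <- random_clr(D = 6, S = 2, seed = 3)
  pca <- pca_clr(cm)
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-9)

  m <- withr::with_seed(4, matrix(stats::rgamma(12, 5), nrow = 4))
  m <- cbind(m, m[, 1])  # duplicated sample
  colnames(m) <- sprintf("s%d", 1:4); rownames(m) <- sprintf("f%d", 1:4)
  pca2 <- pca_clr(clr_transform(m))
  expect_equal(pca2$scores["s1", ], pca2$scores["s4", ], tolerance = 1e-8)

  one <- matrix(1:4, ncol = 1, dimnames = list(sprintf("f%d", 1:4), "s1"))
  expect_error(pca_clr(structure(one, class = c("clr_matrix", "matrix"))),
               "2 samples")
})

test_that("aitchison distances equal euclidean distances on the clr matrix", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(stats::rgamma(40, 3), nrow = 8,
                            dimnames = list(sprintf("f%d", 1:8),
                                            sprintf("s%d", 1:5))))
    d1 <- sample_distance_matrix(m, metric = "aitchison")
    d2 <- sample_distance_matrix(clr_transform(m), metric = "euclidean_clr")
    expect_equal(as.matrix(d1), as.matrix(d2), tolerance = 1e-10)
    # pairwise definitional check
    expect_equal(as.matrix(d1)["s1", "s2"],
                 aitchison_distance(m[, 1], m[, 2]), tolerance = 1e-10)
  }
  tab <- random_count_table(D = 4, S = 3, seed = 1)
  tab$counts[1, 1] <- 0
  expect_error(sample_distance_matrix(tab, metric = "aitchison"),
               "zero handling")
})

test_that("jaccard presence distance is 1 for disjoint feature sets", {
  m <- matrix(c(5, 0, 3, 0, 0, 2, 0, 4), nrow = 4,
              dimnames = list(sprintf("f%d", 1:4), c("s1", "s2")))
  d <- sample_distance_matrix(count_table(m + 0), metric = "jaccard_presence")
  expect_equal(as.matrix(d)["s1", "s2"], 1)
  # identical samples at distance zero
  m2 <- cbind(s1 = c(1, 2, 0), s2 = c(1, 2, 0))
  rownames(m2) <- sprintf("f%d", 1:3)
  d2 <- sample_distance_matrix(count_table(m2), metric = "jaccard_presence")
  expect_equal(as.matrix(d2)["s1", "s2"], 0)
})

test_that("hierarchical clustering follows the named linkage", {
  d <- matrix(0, 3, 3, dimnames = list(c("p1", "p2", "p3"),
                                       c("p1", "p2", "p3")))
  d["p1", "p2"] <- d["p2", "p1"] <- 1
  d["p1", "p3"] <- d["p3", "p1"] <- 2
  d["p2", "p3"] <- d["p3", "p2"] <- 3
  single <- hierarchical_cluster(d, linkage = "single")
  expect_equal(single$hclust$height, c(1, 2))
  expect_equal(sort(single$hclust$merge[1, ]), c(-2, -1))
  complete <- hierarchical_cluster(d, linkage = "complete")
  expect_equal(complete$hclust$height, c(1, 3))

  # identical points merge at height zero
  dz <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hz <- hierarchical_cluster(dz, linkage = "average")
  expect_equal(hz$hclust$height[1], 0)

  bad <- d; bad["p1", "p2"] <- 9
  expect_error(hierarchical_cluster(bad), "symmetric")
  neg <- d; neg["p1", "p2"] <- neg["p2", "p1"] <- -1
  expect_error(hierarchical_cluster(neg), "non-negative")
})

test_that("merge heights are monotone for the standard linkages", {
  for (seed in 1:5) {
    cm <- random_clr(D = 8, S = 7, seed = seed + 20)
    d <- sample_distance_matrix(cm, metric = "euclidean_clr")
    for (lk in c("single", "complete", "average")) {
      h <- hierarchical_cluster(d, linkage = lk)$hclust$height
      expect_true(all(diff(h) >= -1e-12))
      expect_length(h, 6L)  # n - 1 merges
    }
  }
})

test_that("dendrograms export as parseable newick", {
  cm <- random_clr(D = 6, S = 5, seed = 8)
  dendro <- hierarchical_cluster(
    sample_distance_matrix(cm, metric = "euclidean_clr"), "average")
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(dendro, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, colnames(cm))
})

test_that("metadata colouring is stable and handles missing values", {
  md <- metadata_table(data.frame(
    bv = c("positive", "negative", "positive", NA),
    ph = c(3.8, 4.4, 5.2, 4.9),
    row.names = paste0("S", 1:4)), discrete_threshold = 2)
  ca <- colour_by_metadata(md, "bv")
  expect_equal(ca$colours[["S1"]], ca$colours[["S3"]])
  expect_false(ca$colours[["S1"]] == ca$colours[["S2"]])
  expect_equal(ca$colours[["S4"]], "grey70")
  expect_equal(names(ca$legend), c("positive", "negative"))

  cc <- colour_by_metadata(md, "ph")
  expect_equal(cc$colours[["S1"]], cc$legend$low)
  expect_equal(cc$colours[["S3"]], cc$legend$high)

  md2 <- metadata_table(data.frame(x = c(NA, NA),
                                   row.names = c("S1", "S2")))
  expect_warning(ca2 <- colour_by_metadata(md2, "x"), "missing")
  expect_true(all(ca2$colours == "grey70"))
  expect_error(colour_by_metadata(md, "nope"), "not found")
})

test_that("metadata histograms count levels, bins and missing values", {
  md <- metadata_table(data.frame(
    bv = c("positive", "positive", "positive", "negative", "negative", NA),
    row.names = paste0("S", 1:6)))
  h <- metadata_histogram(md, "bv")
  expect_equal(h$count[h$level == "positive"], 3L)
  expect_equal(h$count[h$level == "negative"], 2L)
  expect_equal(attr(h, "n_missing"), 1L)

  md2 <- metadata_table(data.frame(v = c(seq(0, 0.09, by = 0.01), 10.05),
                                   row.names = paste0("S", 1:11)))
  h2 <- metadata_histogram(md2, "v")
  expect_equal(nrow(h2), 10L)
  expect_equal(h2$count[1], 10L)   # first bin swallows the tight cluster
  expect_equal(sum(h2$count), 11L)
})
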