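# CLR-PCA biplots, metadata colouring, and hierarchical clustering.

#' Principal component analysis of a CLR matrix
#'
#' Centers each feature across samples and takes the singular value
#' decomposition of the centered samples x features matrix.  Scores carry
#' the singular values (form biplot: samples in principal coordinates) by
#' default; `scaling = "covariance"` puts them on the loadings instead.
#' Singular-vector signs are fixed so the largest-magnitude element of each
#' loading vector is positive, making output reproducible across
#' linear-algebra backends.
#'
#' Because every CLR sample sums to zero and centering removes one more
#' degree of freedom, at most `min(n_samples - 1, n_features - 1)` singular
#' values are non-negligible.
#'
#' @param clr_mat a `clr_matrix` (features x samples) from [clr_transform()]
#' @param scaling `"form"` (default) or `"covariance"`
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `singular_values` (descending),
#'   `variance_explained` (fractions summing to 1)
#' @export
pca_clr <- function(clr_mat, scaling = c("form", "covariance")) {
  scaling <- match.arg(scaling)
  X <- t(unclass(clr_mat))                   # samples x features
  if (nrow(X) < 2L) stop_coda("PCA needs at least 2 samples")
  if (ncol(X) < 2L) stop_coda("PCA needs at least 2 features")
  Xc <- sweep(X, 2, colMeans(X), "-")
  sv <- svd(Xc)
  flip <- vapply(seq_len(ncol(sv$v)), function(k) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) -1 else 1
  }, numeric(1))
  V <- sweep(sv$v, 2, flip, "*")
  U <- sweep(sv$u, 2, flip, "*")
  d <- sv$d
  if (scaling == "form") {
    scores <- U %*% diag(d, length(d))
    loadings <- V
  } else {
    scores <- U
    loadings <- V %*% diag(d, length(d))
  }
  comp <- paste0("PC", seq_along(d))
  dimnames(scores) <- list(rownames(X), comp)
  dimnames(loadings) <- list(colnames(X), comp)
  structure(list(scores = scores, loadings = loadings,
                 singular_values = d,
                 variance_explained = d^2 / sum(d^2),
                 scaling = scaling),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", nrow(x$loadings),
      "features\n  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained[1:min(3,
        length(x$variance_explained))]), collapse = ", "), "...\n")
  invisible(x)
}

#' Assign plotting colours from a metadata variable
#'
#' Discrete variables map levels to a categorical palette in order of first
#' appearance; continuous variables map to a monotone gradient over the
#' observed range.  Missing values receive a reserved grey.
#'
#' @param metadata a `metadata_table`
#' @param variable variable name
#' @param sample_ids samples to colour (default: all in the metadata)
#' @return list with `colours` (named per sample), `kind`, and `legend`
#'   (level-to-colour map for discrete variables, range and ramp endpoints
#'   for continuous ones)
#' @export
colour_by_metadata <- function(metadata, variable, sample_ids = NULL) {
  if (!variable %in% names(metadata$data))
    stop_coda("metadata variable '", variable, "' not found")
  ids <- sample_ids %||% rownames(metadata$data)
  vals <- metadata$data[ids, variable]
  missing_col <- "grey70"
  kind <- metadata$kinds[[variable]]
  if (all(is.na(vals))) {
    warning("variable '", variable, "' is missing for every plotted sample")
    return(list(colours = stats::setNames(rep(missing_col, length(ids)), ids),
                kind = kind, legend = NULL))
  }
  if (kind == "discrete") {
    levels <- unique(as.character(vals[!is.na(vals)]))
    pal <- grDevices::hcl.colors(max(length(levels), 2L), "Dark 3")
    pal <- pal[seq_along(levels)]
    names(pal) <- levels
    cols <- pal[as.character(vals)]
    cols[is.na(vals)] <- missing_col
    list(colours = stats::setNames(unname(cols), ids), kind = kind,
         legend = pal)
  } else {
    num <- as.numeric(vals)
    rng <- range(num, na.rm = TRUE)
    ramp <- grDevices::hcl.colors(100, "Viridis")
    span <- if (diff(rng) > 0) diff(rng) else 1
    idx <- pmin(100L, pmax(1L, 1L + floor(99 * (num - rng[1]) / span + 0.5)))
    cols <- ramp[idx]
    cols[is.na(num)] <- missing_col
    list(colours = stats::setNames(cols, ids), kind = kind,
         legend = list(range = rng, low = ramp[1], high = ramp[100]))
  }
}

#' Frequency table of a metadata variable
#'
#' Discrete variables yield level counts; continuous ones counts in
#' equal-width bins over the observed range.  Missing values are counted
#' separately.
#'
#' @param metadata a `metadata_table`
#' @param variable variable name
#' @param bins number of equal-width bins for continuous variables
#' @return data.frame (level or bin label, count) with an `n_missing`
#'   attribute
#' @export
metadata_histogram <- function(metadata, variable, bins = 10L) {
  if (!variable %in% names(metadata$data))
    stop_coda("metadata variable '", variable, "' not found")
  vals <- metadata$data[[variable]]
  n_missing <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (metadata$kinds[[variable]] == "discrete") {
    if (!length(vals)) {
      out <- data.frame(level = character(), count = integer())
    } else {
      tab <- table(factor(as.character(vals),
                          levels = unique(as.character(vals))))
      out <- data.frame(level = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
    }
  } else {
    num <- as.numeric(vals)
    if (!length(num)) {
      out <- data.frame(level = character(), count = integer())
    } else {
      rng <- range(num)
      if (diff(rng) == 0) {
        out <- data.frame(level = sprintf("[%g,%g]", rng[1], rng[2]),
                          count = length(num), stringsAsFactors = FALSE)
      } else {
        breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
        cut_idx <- pmin(bins, pmax(1L,
          1L + findInterval(num, breaks, rightmost.closed = TRUE) - 1L))
        tab <- tabulate(cut_idx, nbins = bins)
        out <- data.frame(
          level = sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1],
                          c(rep(")", bins - 1L), "]")),
          count = tab, stringsAsFactors = FALSE)
      }
    }
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Pairwise distances between samples
#'
#' `"aitchison"` computes CLR vectors from strictly positive (zero-handled)
#' data and takes Euclidean distances between them; `"euclidean_clr"` is
#' the same metric applied to an already-CLR-transformed matrix — the two
#' are identical by construction.  `"jaccard_presence"` uses
#' presence/absence of raw counts.
#'
#' @param x for `"aitchison"`, a [count_table()] with no zeros or a strictly
#'   positive matrix; for `"euclidean_clr"`, a `clr_matrix`; for
#'   `"jaccard_presence"`, a [count_table()]
#' @param metric `"aitchison"`, `"euclidean_clr"` or `"jaccard_presence"`
#' @return a `dist` over samples
#' @export
sample_distance_matrix <- function(x, metric = c("aitchison",
                                                 "euclidean_clr",
                                                 "jaccard_presence")) {
  metric <- match.arg(metric)
  if (metric == "aitchison") {
    mat <- if (inherits(x, "count_table")) x$counts else x
    if (any(mat <= 0))
      stop_coda("aitchison distance needs strictly positive data; ",
                "apply zero handling first")
    stats::dist(t(unclass(clr_transform(mat))))
  } else if (metric == "euclidean_clr") {
    if (!inherits(x, "clr_matrix"))
      stop_coda("euclidean_clr expects a clr_matrix")
    stats::dist(t(unclass(x)))
  } else {
    mat <- if (inherits(x, "count_table")) x$counts else x
    stats::dist(t(mat > 0), method = "binary")
  }
}

#' Agglomerative hierarchical clustering of samples
#'
#' Wraps the standard agglomerative algorithm with the named linkage.
#' `"ward"` uses the squared-distance update (the Ward.D2 convention).
#' Merge heights are non-decreasing for single, complete and average
#' linkage.
#'
#' @param d a `dist` or a symmetric non-negative matrix with zero diagonal
#' @param linkage `"single"`, `"complete"`, `"average"`, or `"ward"`
#' @return object of class `dendrogram_result`: the `hclust` fit plus the
#'   linkage and distance names
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "single",
                                                "average", "ward")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop_coda("distance matrix must be symmetric")
    if (any(d < 0)) stop_coda("distances must be non-negative")
    if (any(abs(diag(d)) > 1e-12))
      stop_coda("distance matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  if (any(d < 0)) stop_coda("distances must be non-negative")
  method <- if (linkage == "ward") "ward.D2" else linkage
  fit <- stats::hclust(d, method = method)
  structure(list(hclust = fit, linkage = linkage,
                 distance = attr(d, "method") %||% "unknown"),
            class = "dendrogram_result")
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths.
#'
#' @param dendro a `dendrogram_result`
#' @param path output path
#' @export
write_dendrogram_newick <- function(dendro, path) {
  phy <- ape::as.phylo(dendro$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export PCA results as TSV tables
#'
#' Writes `<prefix>_scores.tsv`, `<prefix>_loadings.tsv`, and
#' `<prefix>_variance.tsv`.
#'
#' @param pca a `pca_result`
#' @param prefix output path prefix
#' @export
write_pca_result <- function(pca, prefix) {
  write_tsv_det(as.data.frame(pca$scores), paste0(prefix, "_scores.tsv"),
                row_label = "sample")
  write_tsv_det(as.data.frame(pca$loadings),
                paste0(prefix, "_loadings.tsv"), row_label = "feature")
  write_tsv_det(data.frame(component = paste0("PC",
                             seq_along(pca$singular_values)),
                           singular_value = pca$singular_values,
                           variance_explained = pca$variance_explained),
                paste0(prefix, "_variance.tsv"))
  invisible(prefix)
}
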