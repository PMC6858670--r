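# Zero handling and the centered log-ratio transform.
#
# Sequencing counts are compositional: only the ratios between features
# carry information.  All log-ratio work here is in base 2, matching the
# fold-change convention of the differential-abundance ecosystem.

#' Count-zero-multiplicative replacement for one sample
#'
#' Replaces zeros in a count vector with a small proportion tied to the
#' sequencing depth, delta = frac / (n + 1) where n is the sample's total
#' count, and shrinks the non-zero parts multiplicatively so the result is
#' a composition (sums to 1).  The ratios between non-zero parts are
#' preserved exactly.
#'
#' @param counts non-negative count vector for one sample
#' @param frac fraction of the per-read detection limit assigned to each
#'   zero, in `(0, 1]`; default 0.65
#' @return a strictly positive composition summing to 1
#' @export
impute_zeros_czm <- function(counts, frac = 0.65) {
  if (any(counts < 0)) stop_coda("counts must be non-negative")
  if (frac <= 0 || frac > 1) stop_coda("frac must lie in (0, 1]")
  n <- sum(counts)
  if (n <= 0) stop_coda("all-zero sample: nothing to impute")
  zero <- counts == 0
  nz <- sum(zero)
  delta <- frac / (n + 1)
  if (nz * delta >= 1)
    stop_coda("too many zeros for this sequencing depth (", nz, " zeros, ",
              "depth ", n, "); filter low-count features more aggressively")
  out <- (counts / n) * (1 - nz * delta)
  out[zero] <- delta
  out
}

#' Pseudocount zero replacement
#'
#' Adds a constant to every cell; the quick alternative to multiplicative
#' replacement.
#'
#' @param counts non-negative count vector or matrix
#' @param pseudo positive constant, default 0.5
#' @return strictly positive vector or matrix of the same shape
#' @export
impute_zeros_pseudocount <- function(counts, pseudo = 0.5) {
  if (pseudo <= 0) stop_coda("pseudo must be positive")
  if (any(counts < 0)) stop_coda("counts must be non-negative")
  counts + pseudo
}

#' Centered log-ratio transform of one composition
#'
#' `clr(x)_j = log2(x_j) - mean(log2(x))`.  The output sums to zero and is
#' invariant to rescaling the input by a positive scalar, so counts,
#' proportions and percentages all map to the same point.
#'
#' @param parts strictly positive vector, length >= 2
#' @param base logarithm base (default 2; every documented number assumes 2)
#' @return real vector summing to 0
#' @export
clr <- function(parts, base = 2) {
  if (length(parts) < 2L) stop_coda("clr needs at least two parts")
  if (any(parts <= 0))
    stop_coda("clr requires strictly positive parts; handle zeros first ",
              "(impute_zeros_czm or impute_zeros_pseudocount)")
  lg <- log(parts, base = base)
  lg - mean(lg)
}

#' CLR-transform a zero-handled count matrix
#'
#' Applies [clr()] to each sample (column) of a strictly positive
#' features x samples matrix.
#'
#' @param mat strictly positive matrix, features x samples
#' @param base logarithm base
#' @return a `clr_matrix`: features x samples matrix of CLR values, each
#'   column summing to 0
#' @export
clr_transform <- function(mat, base = 2) {
  if (any(mat <= 0))
    stop_coda("clr_transform requires strictly positive values; ",
              "handle zeros first")
  lg <- log(mat, base = base)
  out <- sweep(lg, 2, colMeans(lg), "-")
  structure(out, log_base = base, class = c("clr_matrix", class(out)))
}

#' Zero-handle a count table into strictly positive values
#'
#' Dispatches between the two supported strategies, per sample for the
#' multiplicative method and globally for the pseudocount.
#'
#' @param table a [count_table()]
#' @param method `"czm"` (count-zero multiplicative, the default) or
#'   `"pseudocount"`
#' @param frac [impute_zeros_czm()] fraction
#' @param pseudo [impute_zeros_pseudocount()] constant
#' @return strictly positive matrix, features x samples (compositions per
#'   column for `"czm"`, shifted counts for `"pseudocount"`)
#' @export
zero_handle <- function(table, method = c("czm", "pseudocount"),
                        frac = 0.65, pseudo = 0.5) {
  method <- match.arg(method)
  if (method == "czm") {
    out <- apply(table$counts, 2, impute_zeros_czm, frac = frac)
    dimnames(out) <- dimnames(table$counts)
    out
  } else {
    impute_zeros_pseudocount(table$counts, pseudo = pseudo)
  }
}

#' Aitchison distance between two compositions
#'
#' The Euclidean norm of the difference of the CLR vectors: the natural
#' metric on compositions.  Zero iff the inputs are proportional; invariant
#' to element-wise perturbation by a common positive vector.
#'
#' @param x,y strictly positive vectors of equal length
#' @param base logarithm base
#' @return non-negative real
#' @export
aitchison_distance <- function(x, y, base = 2) {
  if (length(x) != length(y))
    stop_coda("length mismatch: ", length(x), " vs ", length(y))
  sqrt(sum((clr(x, base) - clr(y, base))^2))
}

#' Export a CLR matrix as TSV
#'
#' @param clr_mat a `clr_matrix`
#' @param path output path
#' @export
write_clr_matrix <- function(clr_mat, path) {
  write_tsv_det(as.data.frame(unclass(clr_mat)), path,
                row_label = "feature")
}
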