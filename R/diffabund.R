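# Dirichlet Monte-Carlo differential abundance.
#
# Counts are treated as a multinomial draw from each sample's underlying
# proportions; K posterior instances per sample are drawn from
# Dirichlet(counts + prior) and CLR-transformed.  Effect sizes and expected
# Benjamini-Hochberg values are then computed over the instances, so the
# reported statistics carry the count-based uncertainty with them.

#' Define a two-group comparison
#'
#' @param sample_ids sample identifiers
#' @param condition one of exactly two labels per sample; the first label
#'   to appear becomes group A, the other group B
#' @return object of class `group_design` with `sample_ids`, `condition`,
#'   and `groups` (the two labels, A first)
#' @export
group_design <- function(sample_ids, condition) {
  condition <- as.character(condition)
  if (length(sample_ids) != length(condition))
    stop_coda("sample_ids and condition must have equal length")
  if (anyNA(condition)) stop_coda("every sample must be labelled")
  levels <- unique(condition)
  if (length(levels) != 2L)
    stop_coda("design needs exactly two condition labels, found ",
              length(levels), " (", paste(levels, collapse = ", "), ")")
  structure(list(sample_ids = as.character(sample_ids),
                 condition = condition, groups = levels),
            class = "group_design")
}

#' Draw Dirichlet Monte-Carlo CLR instances
#'
#' For each sample independently, draws `K` vectors of proportions from
#' Dirichlet(counts + prior) and CLR-transforms each (base 2).  The prior
#' 0.5 is the Jeffreys-style default of the ALDEx2 ecosystem.  Regenerating
#' with the same seed reproduces the ensemble bit-identically.
#'
#' @param table a [count_table()] with at least 2 features
#' @param K number of Monte-Carlo instances (default 128)
#' @param prior positive Dirichlet prior added to every count
#' @param seed integer seed; all randomness is confined to this call
#' @return object of class `mc_ensemble`: list with `clr` (3-d array,
#'   features x samples x K), `K`, `prior`, `seed`
#' @export
sample_mc_instances <- function(table, K = 128, prior = 0.5, seed = 1L) {
  if (K < 1) stop_coda("K must be at least 1")
  if (prior <= 0) stop_coda("prior must be positive")
  counts <- table$counts
  if (nrow(counts) < 2L) stop_coda("need at least 2 features")
  D <- nrow(counts); S <- ncol(counts)
  arr <- array(NA_real_, dim = c(D, S, K),
               dimnames = list(rownames(counts), colnames(counts), NULL))
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(S)) {
      g <- matrix(stats::rgamma(D * K, shape = counts[, s] + prior, rate = 1),
                  nrow = D, ncol = K)
      p <- sweep(g, 2, colSums(g), "/")
      lg <- log2(p)
      arr[, s, ] <- sweep(lg, 2, colMeans(lg), "-")
    }
  })
  structure(list(clr = arr, K = as.integer(K), prior = prior,
                 seed = as.integer(seed)),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  d <- dim(x$clr)
  cat("mc_ensemble:", d[1], "features x", d[2], "samples x", d[3],
      "instances (prior", x$prior, ", seed", x$seed, ")\n")
  invisible(x)
}

# Pool one group's CLR values: features x (n_group * K) matrix.
pool_group <- function(ensemble, design, group) {
  idx <- which(design$condition == group)
  sub <- ensemble$clr[, idx, , drop = FALSE]
  dim(sub) <- c(dim(sub)[1], dim(sub)[2] * dim(sub)[3])
  rownames(sub) <- dimnames(ensemble$clr)[[1]]
  sub
}

median_abs_pairwise <- function(v) {
  # median |u - v| over all unordered pairs of distinct positions
  d <- abs(outer(v, v, "-"))
  stats::median(d[upper.tri(d)])
}

overlap_from_diffs <- function(d) {
  # min of the two signed fractions; exact zeros split evenly
  nz <- sum(d == 0)
  f_pos <- (sum(d > 0) + nz / 2) / length(d)
  min(f_pos, 1 - f_pos)
}

#' Compositional effect-size statistics
#'
#' For each feature, pools CLR values across Monte-Carlo instances within
#' each group and computes: `rab.all` (median over all pooled values),
#' per-group medians, `diff.btw` (median over ordered between-group pairs
#' of B minus A), `diff.win` (the larger of the two within-group median
#' absolute pairwise differences), `effect = diff.btw / diff.win`, and
#' `overlap` (the smaller of the fractions of between-group differences
#' above and below zero; exact zeros are split evenly).  A 0/0 effect is
#' defined as 0 and x/0 as signed infinity.
#'
#' `mode = "exact"` enumerates every pair (the test oracle; quadratic in
#' the pooled sizes).  `mode = "subsample"` draws `max_pairs` random pairs
#' with the given seed and converges to the exact values as `max_pairs`
#' grows.
#'
#' @param ensemble an [sample_mc_instances()] ensemble
#' @param design a [group_design()] covering the ensemble's samples
#' @param mode `"subsample"` (default) or `"exact"`
#' @param max_pairs pairs drawn per estimand in subsample mode
#' @param seed seed for pair subsampling
#' @return data.frame of class `effect_table`, one row per feature, in the
#'   ALDEx2 column dialect (`rab.all`, `rab.win.<A>`, `rab.win.<B>`,
#'   `diff.btw`, `diff.win`, `effect`, `overlap`) plus the 2.5% and 97.5%
#'   quantiles of the between-group difference distribution
#'   (`diff.btw.q025`, `diff.btw.q975`); test columns are filled by
#'   [per_instance_tests()] via [aldex_like()]
#' @export
effect_statistics <- function(ensemble, design,
                              mode = c("subsample", "exact"),
                              max_pairs = 10000L, seed = 2L) {
  mode <- match.arg(mode)
  design <- check_design(ensemble, design)
  A <- design$groups[1]; B <- design$groups[2]
  PA <- pool_group(ensemble, design, A)
  PB <- pool_group(ensemble, design, B)
  if (ncol(PA) < 2L || ncol(PB) < 2L)
    stop_coda("each group needs at least 2 pooled values for the ",
              "within-group dispersion")
  D <- nrow(PA)
  rab_all <- apply(cbind(PA, PB), 1, stats::median)
  rab_A <- apply(PA, 1, stats::median)
  rab_B <- apply(PB, 1, stats::median)

  if (mode == "exact") {
    diff_btw <- numeric(D); diff_wA <- numeric(D); diff_wB <- numeric(D)
    overlap <- numeric(D)
    btw_q <- matrix(0, D, 2)
    for (f in seq_len(D)) {
      d <- as.vector(outer(PB[f, ], PA[f, ], "-"))
      diff_btw[f] <- stats::median(d)
      overlap[f] <- overlap_from_diffs(d)
      btw_q[f, ] <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
      diff_wA[f] <- median_abs_pairwise(PA[f, ])
      diff_wB[f] <- median_abs_pairwise(PB[f, ])
    }
  } else {
    mp <- as.integer(max_pairs)
    if (mp < 1L) stop_coda("max_pairs must be positive")
    res <- withr::with_seed(as.integer(seed), {
      ib <- sample.int(ncol(PB), mp, replace = TRUE)
      ia <- sample.int(ncol(PA), mp, replace = TRUE)
      dmat <- PB[, ib, drop = FALSE] - PA[, ia, drop = FALSE]
      u <- sample.int(ncol(PA), mp, replace = TRUE)
      v <- sample.int(ncol(PA), mp, replace = TRUE)
      keep <- u != v
      wa <- abs(PA[, u[keep], drop = FALSE] - PA[, v[keep], drop = FALSE])
      u <- sample.int(ncol(PB), mp, replace = TRUE)
      v <- sample.int(ncol(PB), mp, replace = TRUE)
      keep <- u != v
      wb <- abs(PB[, u[keep], drop = FALSE] - PB[, v[keep], drop = FALSE])
      list(dmat = dmat, wa = wa, wb = wb)
    })
    diff_btw <- apply(res$dmat, 1, stats::median)
    overlap <- apply(res$dmat, 1, overlap_from_diffs)
    btw_q <- t(apply(res$dmat, 1, stats::quantile, probs = c(0.025, 0.975),
                     names = FALSE))
    diff_wA <- apply(res$wa, 1, stats::median)
    diff_wB <- apply(res$wb, 1, stats::median)
  }
  diff_win <- pmax(diff_wA, diff_wB)
  effect <- ifelse(diff_win > 0, diff_btw / diff_win,
                   ifelse(diff_btw == 0, 0, sign(diff_btw) * Inf))
  # the 95% interval of the between-group difference distribution is the
  # per-feature uncertainty an interactive effect plot would show on hover
  out <- data.frame(rab.all = rab_all, rab_A, rab_B,
                    diff.btw = diff_btw, diff.win = diff_win,
                    effect = effect, overlap = overlap,
                    diff.btw.q025 = btw_q[, 1], diff.btw.q975 = btw_q[, 2],
                    row.names = rownames(PA), check.names = FALSE)
  names(out)[2:3] <- paste0("rab.win.", c(A, B))
  attr(out, "groups") <- c(A, B)
  class(out) <- c("effect_table", "data.frame")
  out
}

# Returns the design reordered to the ensemble's sample order.
check_design <- function(ensemble, design) {
  ids <- dimnames(ensemble$clr)[[2]]
  if (!setequal(ids, design$sample_ids) ||
      length(ids) != length(design$sample_ids))
    stop_coda("design does not cover the ensemble's samples")
  ord <- match(ids, design$sample_ids)
  design$condition <- design$condition[ord]
  design$sample_ids <- ids
  design
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a vector of p-values.
#' Missing values propagate and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed)
#' @return adjusted vector, same order and length
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_coda("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Vectorised Welch unequal-variance t-test over the rows of a matrix.
# Zero pooled variance: equal means -> p = 1, unequal -> p = 0 (limit
# behaviour; avoids NaN propagating into the expected-BH mean).
welch_p_rows <- function(M, idxA, idxB) {
  nA <- length(idxA); nB <- length(idxB)
  XA <- M[, idxA, drop = FALSE]; XB <- M[, idxB, drop = FALSE]
  mA <- rowMeans(XA); mB <- rowMeans(XB)
  vA <- rowSums((XA - mA)^2) / (nA - 1)
  vB <- rowSums((XB - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  p <- rep(NA_real_, nrow(M))
  zero <- se2 == 0
  p[zero] <- ifelse(mA[zero] == mB[zero], 1, 0)
  nz <- !zero
  tstat <- (mA[nz] - mB[nz]) / sqrt(se2[nz])
  df <- se2[nz]^2 / ((vA[nz] / nA)^2 / (nA - 1) + (vB[nz] / nB)^2 / (nB - 1))
  p[nz] <- 2 * stats::pt(-abs(tstat), df)
  p
}

# Two-sided Wilcoxon rank-sum p for one feature.  Exact null distribution
# (stats::pwilcox) when the combined n is small and there are no ties;
# tie-corrected normal approximation with continuity correction otherwise
# (the conventions of stats::wilcox.test).
wilcoxon_p <- function(a, b, exact_threshold = 20L) {
  nA <- length(a); nB <- length(b); n <- nA + nB
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (n <= exact_threshold && !ties) {
    mu <- nA * nB / 2
    p <- if (U > mu) 2 * stats::pwilcox(U - 1, nA, nB, lower.tail = FALSE)
         else 2 * stats::pwilcox(U, nA, nB)
    return(min(p, 1))
  }
  nties <- table(r)
  mu <- nA * nB / 2
  sigma2 <- (nA * nB / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Per-instance hypothesis tests with expected BH values
#'
#' For every Monte-Carlo instance and feature, runs a two-sided Welch
#' unequal-variance t-test and a two-sided Wilcoxon rank-sum test on the
#' CLR values across samples; adjusts each instance's p-values across
#' features by Benjamini-Hochberg; and reports the arithmetic mean across
#' instances of each quantity (the "expected" p and BH values).
#'
#' @param ensemble an [sample_mc_instances()] ensemble
#' @param design a [group_design()]; each group needs >= 2 samples
#' @param exact_threshold combined sample size up to which the Wilcoxon
#'   null distribution is evaluated exactly
#' @return data.frame with columns `we.ep`, `we.eBH`, `wi.ep`, `wi.eBH`,
#'   one row per feature
#' @export
per_instance_tests <- function(ensemble, design, exact_threshold = 20L) {
  design <- check_design(ensemble, design)
  idxA <- which(design$condition == design$groups[1])
  idxB <- which(design$condition == design$groups[2])
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop_coda("each group needs at least 2 samples")
  D <- dim(ensemble$clr)[1]; K <- dim(ensemble$clr)[3]
  acc <- matrix(0, nrow = D, ncol = 4)
  for (k in seq_len(K)) {
    M <- ensemble$clr[, , k, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    we <- welch_p_rows(M, idxA, idxB)
    wi <- vapply(seq_len(D), function(f)
      wilcoxon_p(M[f, idxA], M[f, idxB], exact_threshold), numeric(1))
    acc <- acc + cbind(we, benjamini_hochberg(we),
                       wi, benjamini_hochberg(wi))
  }
  out <- as.data.frame(acc / K)
  names(out) <- c("we.ep", "we.eBH", "wi.ep", "wi.eBH")
  rownames(out) <- dimnames(ensemble$clr)[[1]]
  out
}

#' One-call differential abundance in the ALDEx2 style
#'
#' Draws the Monte-Carlo ensemble, computes effect statistics and the
#' per-instance tests, and returns the combined effect table.
#'
#' @inheritParams sample_mc_instances
#' @inheritParams effect_statistics
#' @param condition two-level label per sample, in the table's sample order
#' @return an `effect_table` with all eleven ALDEx2-dialect columns
#' @export
aldex_like <- function(table, condition, K = 128, prior = 0.5, seed = 1L,
                       mode = "subsample", max_pairs = 10000L) {
  design <- group_design(sample_ids(table), condition)
  ens <- sample_mc_instances(table, K = K, prior = prior, seed = seed)
  eff <- effect_statistics(ens, design, mode = mode, max_pairs = max_pairs,
                           seed = as.integer(seed) + 1L)
  tests <- per_instance_tests(ens, design)
  out <- cbind(eff, tests[rownames(eff), , drop = FALSE])
  attr(out, "groups") <- attr(eff, "groups")
  class(out) <- c("effect_table", "data.frame")
  out
}

classify_features <- function(effects, effect_cutoff, ebh_cutoff,
                              test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  col <- if (test == "wilcoxon") "wi.eBH" else "we.eBH"
  eff_hit <- !is.na(effects$effect) & abs(effects$effect) >= effect_cutoff
  if (col %in% names(effects)) {
    ebh <- effects[[col]]
    test_hit <- !is.na(ebh) & ebh <= ebh_cutoff
  } else test_hit <- rep(FALSE, nrow(effects))
  ifelse(eff_hit & test_hit, "both",
         ifelse(eff_hit, "effect_only",
                ifelse(test_hit, "test_significant", "nonsignificant")))
}

#' Effect-plot records
#'
#' One record per feature with x = within-group dispersion (`diff.win`),
#' y = between-group difference (`diff.btw`), and a significance class:
#' `both`, `effect_only` (|effect| at or above the cutoff),
#' `test_significant` (expected BH at or below the cutoff), or
#' `nonsignificant`.  The y = +/-x diagonals of the resulting plot are the
#' |effect| = 1 contours.
#'
#' @param effects an `effect_table`
#' @param effect_cutoff |effect| threshold (default 1.0)
#' @param ebh_cutoff expected-BH threshold (default 0.05)
#' @param test which expected BH classifies features: `"wilcoxon"`
#'   (default) or `"welch"`
#' @return data.frame (feature, x, y, effect, class)
#' @export
effect_plot_data <- function(effects, effect_cutoff = 1.0,
                             ebh_cutoff = 0.05, test = "wilcoxon") {
  out <- data.frame(feature = rownames(effects),
                    x = effects$diff.win, y = effects$diff.btw,
                    effect = effects$effect,
                    class = classify_features(effects, effect_cutoff,
                                              ebh_cutoff, test),
                    stringsAsFactors = FALSE)
  # hover-style uncertainty, when the table carries it (computed tables
  # do; minimal re-imported ones may not)
  if (all(c("diff.btw.q025", "diff.btw.q975") %in% names(effects))) {
    out$y_q025 <- effects$diff.btw.q025
    out$y_q975 <- effects$diff.btw.q975
  }
  out
}

#' MA-plot records
#'
#' Difference (`diff.btw`) against relative abundance (`rab.all`), with the
#' same significance classing as [effect_plot_data()].
#'
#' @inheritParams effect_plot_data
#' @return data.frame (feature, x, y, effect, class)
#' @export
ma_plot_data <- function(effects, effect_cutoff = 1.0, ebh_cutoff = 0.05,
                         test = "wilcoxon") {
  data.frame(feature = rownames(effects),
             x = effects$rab.all, y = effects$diff.btw,
             effect = effects$effect,
             class = classify_features(effects, effect_cutoff, ebh_cutoff,
                                       test),
             stringsAsFactors = FALSE)
}
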