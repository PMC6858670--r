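# Synthetic count tables with known compositional structure and spiked
# differential features, so every downstream stage is testable without any
# external download.

#' Specify a synthetic two-group count table
#'
#' A base composition is drawn once from a log2-normal and closed; the
#' group-B target perturbs the spiked features by `fold_change` in
#' proportion space and re-closes.  Spiking before closure deliberately
#' reproduces the compositional artifact that an absolute change in some
#' features induces apparent (renormalisation) changes in all others, while
#' preserving the pairwise ratios among non-spiked features.
#'
#' Each sample then draws proportions from Dirichlet(dispersion x target)
#' — `dispersion` is the total concentration, so larger values mean less
#' between-sample biological variability — and counts from a multinomial at
#' a depth uniform on `depth_range`.
#'
#' @param n_features number of features (default 200)
#' @param samples_per_group c(n_A, n_B) (default 10 + 10)
#' @param base_log2_mean,base_log2_sd parameters of the log2-normal base
#'   composition (defaults 0 and 1)
#' @param spike_ids indices or ids of features spiked in group B (default
#'   none)
#' @param fold_change positive fold applied to spikes in group B (default 1
#'   = null data)
#' @param depth_range c(min, max) sequencing depths (default 5000-20000)
#' @param dispersion Dirichlet total concentration (default 1000)
#' @param seed integer seed
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(n_features = 200L, samples_per_group = c(10L, 10L),
                       base_log2_mean = 0, base_log2_sd = 1,
                       spike_ids = integer(), fold_change = 1,
                       depth_range = c(5000L, 20000L), dispersion = 1000,
                       seed = 1L) {
  stopifnot(n_features >= 2, length(samples_per_group) == 2,
            all(samples_per_group >= 1), fold_change > 0,
            length(depth_range) == 2, all(depth_range > 0),
            depth_range[1] <= depth_range[2], dispersion > 0,
            base_log2_sd >= 0)
  if (is.numeric(spike_ids)) {
    if (any(spike_ids < 1 | spike_ids > n_features))
      stop_coda("spike_ids out of range")
    spike_ids <- as.integer(spike_ids)
  }
  structure(list(n_features = as.integer(n_features),
                 samples_per_group = as.integer(samples_per_group),
                 base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd,
                 spike_ids = spike_ids, fold_change = fold_change,
                 depth_range = as.integer(depth_range),
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "synth_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic count table with known truth
#'
#' Fully reproducible from the spec's seed.
#'
#' @param spec a [synth_spec()]
#' @return list with `table` (a [count_table()]), `metadata` (a
#'   `metadata_table` with the two-level `group` variable), and `truth`
#'   (data.frame of per-feature true log2 fold changes, plus `group_labels`
#'   and `depths` attributes)
#' @export
generate_counts <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop_coda("spec must be a synth_spec")
  D <- spec$n_features
  nA <- spec$samples_per_group[1]; nB <- spec$samples_per_group[2]
  fids <- sprintf("F%04d", seq_len(D))
  sids <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
  group <- rep(c("A", "B"), c(nA, nB))
  spikes <- if (is.character(spec$spike_ids)) match(spec$spike_ids, fids)
            else spec$spike_ids
  res <- withr::with_seed(spec$seed, {
    z <- stats::rnorm(D, spec$base_log2_mean, spec$base_log2_sd)
    base <- 2^z; base <- base / sum(base)
    target_B <- base
    target_B[spikes] <- target_B[spikes] * spec$fold_change
    target_B <- target_B / sum(target_B)
    depths <- floor(stats::runif(nA + nB, spec$depth_range[1],
                                 spec$depth_range[2] + 1))
    counts <- matrix(0, nrow = D, ncol = nA + nB,
                     dimnames = list(fids, sids))
    for (s in seq_len(nA + nB)) {
      target <- if (group[s] == "A") base else target_B
      p <- rdirichlet1(spec$dispersion * target)
      counts[, s] <- stats::rmultinom(1, size = depths[s], prob = p)
    }
    list(counts = counts, depths = depths)
  })
  # multinomial draws can zero out a whole sample only at absurd depths;
  # guard anyway so validation errors are intelligible
  tab <- count_table(res$counts)
  md <- metadata_table(data.frame(group = group,
                                  row.names = sids,
                                  stringsAsFactors = FALSE))
  truth <- data.frame(feature = fids,
                      true_log2_fc = ifelse(seq_len(D) %in% spikes,
                                            log2(spec$fold_change), 0),
                      stringsAsFactors = FALSE)
  attr(truth, "group_labels") <- group
  attr(truth, "depths") <- res$depths
  list(table = tab, metadata = md, truth = truth)
}

#' Score differential-abundance recovery against known truth
#'
#' @param effects an `effect_table` over the same features
#' @param truth the `truth` component of [generate_counts()]
#' @param effect_cutoff |effect| threshold for calling a feature
#' @return list: `sensitivity` (spiked features at or above the cutoff),
#'   `false_positive_rate` (non-spiked at or above it; `NA` when every
#'   feature is spiked), `rank_agreement` (fraction of spiked features in
#'   the top-n_spiked by |effect|)
#' @export
evaluate_recovery <- function(effects, truth, effect_cutoff = 1) {
  if (!setequal(rownames(effects), truth$feature))
    stop_coda("effects and truth cover different feature sets")
  eff <- abs(effects[truth$feature, "effect"])
  spiked <- truth$true_log2_fc != 0
  n_spiked <- sum(spiked)
  sensitivity <- if (n_spiked) mean(eff[spiked] >= effect_cutoff) else NA_real_
  fpr <- if (n_spiked < length(eff))
    mean(eff[!spiked] >= effect_cutoff) else NA_real_
  rank_agreement <- if (n_spiked) {
    top <- order(eff, decreasing = TRUE)[seq_len(n_spiked)]
    mean(which(spiked) %in% top)
  } else NA_real_
  list(sensitivity = sensitivity, false_positive_rate = fpr,
       rank_agreement = rank_agreement)
}

#' Write a synthetic dataset to disk as TSV fixtures
#'
#' Emits the standard count-table and metadata files (so they exercise the
#' real readers) plus the truth table.
#'
#' @param synth result of [generate_counts()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_synth_fixture <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(synth$table, file.path(dir, "counts.tsv"))
  write_tsv_det(synth$metadata$data, file.path(dir, "metadata.tsv"),
                row_label = "sample")
  write_tsv_det(synth$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
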