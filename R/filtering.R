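# Low-count filtering of samples and features, with a full removal report.

#' Specify count-table filtering thresholds
#'
#' Thresholds are "keep if >=": a sample or feature is removed only when its
#' statistic is strictly below the threshold.  All defaults are 0, i.e. no
#' silent filtering.
#'
#' @param min_sample_total minimum column (sample) total to keep a sample
#' @param min_feature_total minimum row total, over retained samples, to
#'   keep a feature
#' @param min_feature_max_prop minimum of a feature's maximum per-sample
#'   relative abundance, in `[0, 1]`
#' @param metadata_selector optional list `list(variable =, values =)` for a
#'   discrete variable or `list(variable =, range = c(lo, hi))` for a
#'   continuous one; applied before the count thresholds
#' @return an object of class `filter_spec`
#' @export
filter_spec <- function(min_sample_total = 0, min_feature_total = 0,
                        min_feature_max_prop = 0, metadata_selector = NULL) {
  stopifnot(is.finite(min_sample_total), min_sample_total >= 0,
            is.finite(min_feature_total), min_feature_total >= 0,
            is.finite(min_feature_max_prop),
            min_feature_max_prop >= 0, min_feature_max_prop <= 1)
  if (!is.null(metadata_selector)) {
    if (is.null(metadata_selector$variable))
      stop_coda("metadata_selector needs a 'variable' entry")
    if (is.null(metadata_selector$values) && is.null(metadata_selector$range))
      stop_coda("metadata_selector needs 'values' or 'range'")
  }
  structure(list(min_sample_total = min_sample_total,
                 min_feature_total = min_feature_total,
                 min_feature_max_prop = min_feature_max_prop,
                 metadata_selector = metadata_selector),
            class = "filter_spec")
}

#' Filter a count table and report every removal
#'
#' Rules are applied in a fixed, documented order: (1) the metadata
#' selector, (2) samples whose total is below `min_sample_total`, (3)
#' features whose total over the retained samples is below
#' `min_feature_total`, (4) features whose maximum per-sample relative
#' abundance over retained samples is below `min_feature_max_prop`.
#' Removing failed samples first prevents them from dragging features below
#' threshold.
#'
#' @param table a [count_table()]
#' @param spec a [filter_spec()]
#' @param metadata `metadata_table`, required when the spec carries a
#'   metadata selector
#' @return list with the filtered `table` and a `report` of class
#'   `filter_report`: removals (id, dimension, reason) plus before/after
#'   shapes
#' @export
filter_counts <- function(table, spec = filter_spec(), metadata = NULL) {
  before <- dim(table$counts)
  removed <- data.frame(id = character(), dimension = character(),
                        reason = character(), stringsAsFactors = FALSE)
  tab <- table

  sel <- spec$metadata_selector
  if (!is.null(sel)) {
    if (is.null(metadata))
      stop_coda("spec has a metadata selector but no metadata was given")
    kept <- metadata_selection_ids(tab, metadata, sel$variable,
                                   values = sel$values, range = sel$range)
    gone <- setdiff(sample_ids(tab), kept)
    if (length(gone))
      removed <- rbind(removed, data.frame(
        id = gone, dimension = "sample",
        reason = paste0("metadata_selector:", sel$variable),
        stringsAsFactors = FALSE))
    if (!length(kept))
      stop_filter_empty(removed, before, "all samples removed by metadata selector")
    tab <- subset_samples(tab, kept)
  }

  totals <- colSums(tab$counts)
  gone <- names(totals)[totals < spec$min_sample_total]
  if (length(gone))
    removed <- rbind(removed, data.frame(
      id = gone, dimension = "sample", reason = "min_sample_total",
      stringsAsFactors = FALSE))
  kept <- setdiff(sample_ids(tab), gone)
  if (!length(kept))
    stop_filter_empty(removed, before, "all samples below min_sample_total")
  tab <- subset_samples(tab, kept)

  ftot <- rowSums(tab$counts)
  gone <- names(ftot)[ftot < spec$min_feature_total]
  if (length(gone))
    removed <- rbind(removed, data.frame(
      id = gone, dimension = "feature", reason = "min_feature_total",
      stringsAsFactors = FALSE))
  keptf <- setdiff(feature_ids(tab), gone)
  if (!length(keptf))
    stop_filter_empty(removed, before, "all features below min_feature_total")
  tab <- subset_features(tab, keptf)

  if (spec$min_feature_max_prop > 0) {
    props <- sweep(tab$counts, 2, colSums(tab$counts), "/")
    fmax <- apply(props, 1, max)
    gone <- names(fmax)[fmax < spec$min_feature_max_prop]
    if (length(gone))
      removed <- rbind(removed, data.frame(
        id = gone, dimension = "feature", reason = "min_feature_max_prop",
        stringsAsFactors = FALSE))
    keptf <- setdiff(feature_ids(tab), gone)
    if (!length(keptf))
      stop_filter_empty(removed, before,
                        "all features below min_feature_max_prop")
    tab <- subset_features(tab, keptf)
  }

  report <- structure(list(removed = removed, before = before,
                           after = dim(tab$counts)),
                      class = "filter_report")
  list(table = tab, report = report)
}

stop_filter_empty <- function(removed, before, msg) {
  cond <- structure(
    class = c("codaexplore_filter_empty", "codaexplore_error", "error",
              "condition"),
    list(message = msg, call = sys.call(-1),
         report = structure(list(removed = removed, before = before,
                                 after = c(0L, 0L)),
                            class = "filter_report")))
  stop(cond)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$before[1], "x", x$before[2], "->",
      x$after[1], "x", x$after[2], "\n")
  if (nrow(x$removed)) {
    tab <- table(x$removed$dimension, x$removed$reason)
    print(tab)
  } else cat("  nothing removed\n")
  invisible(x)
}

#' Export a filter report
#'
#' @param report a `filter_report`
#' @param path output path
#' @param format `"tsv"` (id, dimension, reason) or `"json"`
#' @export
write_filter_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv_det(report$removed, path)
  } else {
    jsonlite::write_json(
      list(removed = report$removed,
           before = list(n_features = report$before[1],
                         n_samples = report$before[2]),
           after = list(n_features = report$after[1],
                        n_samples = report$after[2])),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

metadata_selection_ids <- function(table, metadata, variable,
                                   values = NULL, range = NULL) {
  if (!variable %in% names(metadata$data))
    stop_coda("metadata variable '", variable, "' not found")
  ids <- sample_ids(table)
  if (!all(ids %in% rownames(metadata$data)))
    stop_coda("metadata is missing sample(s): ",
              paste(setdiff(ids, rownames(metadata$data)), collapse = ", "))
  col <- metadata$data[ids, variable]
  if (!is.null(values)) {
    keep <- !is.na(col) & as.character(col) %in% as.character(values)
  } else if (!is.null(range)) {
    if (metadata$kinds[[variable]] != "continuous")
      stop_coda("numeric range selection requires a continuous variable")
    num <- as.numeric(col)
    keep <- !is.na(num) & num >= range[1] & num <= range[2]
  } else stop_coda("give either 'values' or 'range'")
  ids[keep]
}

#' Filter samples by a metadata variable
#'
#' Retains samples whose metadata value lies in a value set (discrete
#' variables) or a closed numeric interval (continuous variables).  Missing
#' values never match.
#'
#' @param table a [count_table()]
#' @param metadata a `metadata_table` covering the table's samples
#' @param variable metadata variable name
#' @param values value set for a discrete variable
#' @param range length-2 numeric interval for a continuous variable
#' @return the restricted [count_table()]
#' @export
filter_by_metadata <- function(table, metadata, variable,
                               values = NULL, range = NULL) {
  keep <- metadata_selection_ids(table, metadata, variable,
                                 values = values, range = range)
  if (!length(keep))
    stop_coda("metadata selection on '", variable, "' matches no samples")
  subset_samples(table, keep)
}
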