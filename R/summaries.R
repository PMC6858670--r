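# Relative-abundance summaries by taxonomy and GO-slim category.

#' Relative abundance aggregated by taxonomic level
#'
#' Taxonomy strings are split on `level_delimiter`; features are grouped by
#' their first `level` lineage fields (features whose annotation cannot be
#' parsed to that depth keep their available prefix; empty annotations fall
#' in `"unclassified"`).  Counts are summed per group and each sample is
#' closed to proportions.
#'
#' @param table a [count_table()] with taxonomy
#' @param level_delimiter lineage separator (default `";"`,
#'   Greengenes/SILVA style)
#' @param level number of lineage fields to aggregate on (>= 1)
#' @param min_mean_prop optional threshold: groups whose mean proportion is
#'   below it are collapsed into `"Other"` (default 0 = off)
#' @return object of class `abundance_summary`: `proportions` (groups x
#'   samples, columns sum to 1), plus group and sample ids
#' @export
relative_abundance_by_taxon <- function(table, level_delimiter = ";",
                                        level = 1L, min_mean_prop = 0) {
  if (is.null(table$taxonomy))
    stop_coda("table carries no taxonomy column")
  if (level < 1L) stop_coda("level must be >= 1")
  groups <- vapply(strsplit(table$taxonomy, level_delimiter, fixed = TRUE),
                   function(f) {
                     f <- trimws(f[nzchar(trimws(f))])
                     if (!length(f)) "unclassified"
                     else paste(f[seq_len(min(level, length(f)))],
                                collapse = level_delimiter)
                   }, character(1))
  agg <- rowsum(table$counts, group = groups)
  props <- sweep(agg, 2, colSums(agg), "/")
  if (min_mean_prop > 0) {
    rare <- rowMeans(props) < min_mean_prop
    if (any(rare) && sum(!rare) >= 1L) {
      other <- colSums(props[rare, , drop = FALSE])
      props <- rbind(props[!rare, , drop = FALSE], Other = other)
    }
  }
  props <- props[order(rowMeans(props), decreasing = TRUE), , drop = FALSE]
  structure(list(proportions = props, group_ids = rownames(props),
                 sample_ids = colnames(props)),
            class = "abundance_summary")
}

#' @export
print.abundance_summary <- function(x, ...) {
  cat("abundance_summary:", length(x$group_ids), "groups x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Export an abundance summary as TSV
#'
#' @param summary an `abundance_summary`
#' @param path output path
#' @export
write_abundance_summary <- function(summary, path) {
  write_tsv_det(as.data.frame(summary$proportions), path,
                row_label = "group")
}

#' Per-feature GO-slim stripchart records
#'
#' One record per (category, GO id, sample): the feature's within-sample
#' relative abundance, grouped by GO category (e.g. biological_process).
#' When metadata is attached, each record carries the sample's value of the
#' colour variable.
#'
#' @param table a [count_table()] with GO-slim annotation
#' @param metadata optional `metadata_table`
#' @param colour_variable optional metadata variable attached per record
#' @return data.frame (category, go_id, description, sample, proportion,
#'   and optionally colour_value)
#' @export
goslim_stripchart_data <- function(table, metadata = NULL,
                                   colour_variable = NULL) {
  if (is.null(table$go_annotation))
    stop_coda("table carries no GO-slim annotation")
  props <- sweep(table$counts, 2, colSums(table$counts), "/")
  go <- table$go_annotation
  D <- nrow(props); S <- ncol(props)
  out <- data.frame(
    category = rep(go$category, times = S),
    go_id = rep(go$go_id, times = S),
    description = rep(go$description, times = S),
    sample = rep(colnames(props), each = D),
    proportion = as.vector(props),
    stringsAsFactors = FALSE)
  if (!is.null(colour_variable)) {
    if (is.null(metadata))
      stop_coda("colour_variable given without metadata")
    if (!colour_variable %in% names(metadata$data))
      stop_coda("metadata variable '", colour_variable, "' not found")
    out$colour_value <- metadata$data[out$sample, colour_variable]
  }
  out
}
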