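# Reading, validating and writing count tables, metadata and
# pre-computed effect tables.

#' Construct a validated count table
#'
#' A count table holds non-negative integer counts with features as rows and
#' samples as columns, plus optional per-feature taxonomy strings or GO-slim
#' annotations (GO id, description, category).
#'
#' @param counts numeric matrix, features x samples, with unique row and
#'   column names
#' @param taxonomy optional character vector, one lineage string per feature
#' @param go_annotation optional data.frame with columns `go_id`,
#'   `description`, `category`, one row per feature
#' @param strict if `FALSE`, non-integer numeric cells are rounded with a
#'   warning instead of rejected (some upstream exports store floats)
#' @return an object of class `count_table`
#' @export
count_table <- function(counts, taxonomy = NULL, go_annotation = NULL,
                        strict = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop_coda("empty table: no features or no samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_coda("counts must carry feature (row) and sample (column) names")
  dup_f <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_f))
    stop_coda("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop_coda("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(as.numeric(counts))) &
                   !is.na(counts), arr.ind = TRUE)
    loc <- if (nrow(bad)) paste0(" (first at row ", bad[1, 1],
                                 ", column ", bad[1, 2], ")") else ""
    stop_coda("non-numeric count cell", loc)
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)
    stop_coda("missing count cell at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)
    stop_coda("negative count at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  if (!all(is_wholenumber(counts))) {
    if (strict) {
      bad <- which(!is_wholenumber(counts), arr.ind = TRUE)
      stop_coda("non-integer count at row ", bad[1, 1], ", column ",
                bad[1, 2], "; use strict = FALSE to round")
    }
    warning("non-integer counts rounded to nearest integer")
    counts <- round(counts)
  }
  storage.mode(counts) <- "double"
  if (any(colSums(counts) <= 0))
    stop_coda("sample(s) with zero total counts: ",
              paste(colnames(counts)[colSums(counts) <= 0], collapse = ", "))
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(counts))
      stop_coda("taxonomy length must match the number of features")
    names(taxonomy) <- rownames(counts)
  }
  if (!is.null(go_annotation)) {
    need <- c("go_id", "description", "category")
    if (!all(need %in% names(go_annotation)))
      stop_coda("go_annotation needs columns go_id, description, category")
    if (nrow(go_annotation) != nrow(counts))
      stop_coda("go_annotation rows must match the number of features")
    go_annotation <- go_annotation[, need, drop = FALSE]
    rownames(go_annotation) <- rownames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 go_annotation = go_annotation),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  if (!is.null(x$taxonomy)) cat("  with per-feature taxonomy\n")
  if (!is.null(x$go_annotation)) cat("  with GO-slim annotation\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

feature_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

#' Read a count table from a delimited file
#'
#' The file must have a header row of sample ids and feature ids in the
#' first column, samples as columns and features as rows.  Three dialects
#' are understood: `plain`; `taxonomy_last_column`, whose final column is a
#' lineage string per feature; and `go_slim` (MGnify export convention),
#' whose first three columns are GO id (the feature id), description and
#' category, followed by the sample columns.
#'
#' @param path path to a TSV/CSV file
#' @param dialect one of `"plain"`, `"taxonomy_last_column"`, `"go_slim"`
#' @param delimiter `"tab"`, `"comma"`, or `"auto"` (sniffed from the first
#'   line; tab wins over comma)
#' @param strict reject non-integer counts (see [count_table()])
#' @return a [count_table()]
#' @export
read_count_table <- function(path,
                             dialect = c("plain", "taxonomy_last_column",
                                         "go_slim"),
                             delimiter = "auto", strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_coda("file not found: ", path)
  sep <- resolve_delimiter(delimiter, path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_coda("empty table: ", path)
  taxonomy <- NULL
  go <- NULL
  if (dialect == "go_slim") {
    if (ncol(raw) < 4L)
      stop_coda("go_slim dialect needs go_id, description, category plus ",
                "at least one sample column")
    go <- data.frame(go_id = as.character(raw[[1]]),
                     description = as.character(raw[[2]]),
                     category = as.character(raw[[3]]),
                     stringsAsFactors = FALSE)
    ids <- as.character(raw[[1]])
    body <- raw[, -(1:3), drop = FALSE]
  } else {
    ids <- as.character(raw[[1]])
    body <- raw[, -1, drop = FALSE]
    if (dialect == "taxonomy_last_column") {
      if (ncol(body) < 2L)
        stop_coda("taxonomy_last_column dialect needs at least one sample ",
                  "column before the taxonomy column")
      taxonomy <- as.character(body[[ncol(body)]])
      body <- body[, -ncol(body), drop = FALSE]
    }
  }
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))
      stop_coda("non-numeric count at row ", if (length(bad)) bad[1] else "?",
                ", column '", names(body)[j], "'")
    }
  }
  counts <- as.matrix(body)
  rownames(counts) <- ids
  count_table(counts, taxonomy = taxonomy, go_annotation = go,
              strict = strict)
}

#' Write a count table to a delimited file
#'
#' Inverse of [read_count_table()]: the same dialect round-trips
#' cell-identically.
#'
#' @param table a [count_table()]
#' @param path output path
#' @param dialect dialect to emit (annotation must be present for the
#'   annotated dialects)
#' @param delimiter `"tab"` or `"comma"`
#' @param feature_column header label for the feature-id column
#' @export
write_count_table <- function(table, path,
                              dialect = c("plain", "taxonomy_last_column",
                                          "go_slim"),
                              delimiter = "tab", feature_column = "feature") {
  dialect <- match.arg(dialect)
  sep <- if (delimiter == "comma") "," else "\t"
  cnt <- as.data.frame(table$counts, check.names = FALSE)
  if (dialect == "plain") {
    out <- cbind(stats::setNames(data.frame(rownames(cnt),
                                            stringsAsFactors = FALSE),
                                 feature_column), cnt)
  } else if (dialect == "taxonomy_last_column") {
    if (is.null(table$taxonomy)) stop_coda("table carries no taxonomy")
    out <- cbind(stats::setNames(data.frame(rownames(cnt),
                                            stringsAsFactors = FALSE),
                                 feature_column), cnt,
                 data.frame(taxonomy = unname(table$taxonomy),
                            stringsAsFactors = FALSE))
  } else {
    if (is.null(table$go_annotation))
      stop_coda("table carries no GO-slim annotation")
    out <- cbind(table$go_annotation, cnt)
  }
  rownames(out) <- NULL
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' The first column holds sample ids; remaining columns are metadata
#' variables.  Each variable is typed `discrete` when it contains any
#' non-numeric value or at most `discrete_threshold` distinct numeric
#' values, and `continuous` otherwise.  Empty cells and `"NA"` are recorded
#' as missing.
#'
#' @param path path to a TSV/CSV file
#' @param delimiter `"tab"`, `"comma"`, or `"auto"`
#' @param discrete_threshold distinct-numeric-value cut-off below which a
#'   numeric variable is treated as discrete
#' @return an object of class `metadata_table`: a list with `data` (a
#'   data.frame keyed by sample id) and `kinds` (named character vector,
#'   `"discrete"` or `"continuous"` per variable)
#' @export
read_metadata <- function(path, delimiter = "auto", discrete_threshold = 10) {
  if (!file.exists(path)) stop_coda("file not found: ", path)
  sep <- resolve_delimiter(delimiter, path)
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "", na.strings = c("NA", "")),
    error = function(e) stop_coda("cannot parse metadata file: ",
                                  conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 1L)
    stop_coda("empty metadata table: ", path)
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_coda("duplicate sample ids in metadata: ", paste(dup, collapse = ", "))
  data <- raw[, -1, drop = FALSE]
  rownames(data) <- ids
  metadata_table(data, discrete_threshold = discrete_threshold)
}

#' Construct a metadata table from a data.frame
#'
#' @param data data.frame with sample ids as row names
#' @param discrete_threshold see [read_metadata()]
#' @return a `metadata_table`
#' @export
metadata_table <- function(data, discrete_threshold = 10) {
  if (is.null(rownames(data))) stop_coda("metadata needs sample-id row names")
  kinds <- vapply(data, function(col) {
    vals <- col[!is.na(col)]
    if (!length(vals)) return("discrete")
    num <- suppressWarnings(as.numeric(as.character(vals)))
    if (anyNA(num)) "discrete"
    else if (length(unique(num)) <= discrete_threshold) "discrete"
    else "continuous"
  }, character(1))
  for (v in names(kinds)[kinds == "continuous"])
    data[[v]] <- as.numeric(as.character(data[[v]]))
  structure(list(data = data, kinds = kinds), class = "metadata_table")
}

#' @export
print.metadata_table <- function(x, ...) {
  cat("metadata_table:", nrow(x$data), "samples,", ncol(x$data),
      "variables\n")
  for (v in names(x$kinds)) cat("  ", v, " (", x$kinds[v], ")\n", sep = "")
  invisible(x)
}

#' Restrict a count table and metadata to their shared samples
#'
#' Both outputs are restricted to the intersection of sample ids, in the
#' count table's column order.  Samples dropped from either side are listed
#' in the `dropped` attribute and reported as a warning.
#'
#' @param table a [count_table()]
#' @param metadata a `metadata_table`
#' @return list with elements `table`, `metadata`, and `dropped` (list with
#'   `from_table` and `from_metadata` id vectors)
#' @export
align_samples <- function(table, metadata) {
  ids_t <- sample_ids(table)
  ids_m <- rownames(metadata$data)
  common <- ids_t[ids_t %in% ids_m]
  if (!length(common))
    stop_coda("no samples shared between count table and metadata")
  dropped <- list(from_table = setdiff(ids_t, common),
                  from_metadata = setdiff(ids_m, common))
  if (length(dropped$from_table) || length(dropped$from_metadata))
    warning("align_samples dropped ",
            length(dropped$from_table), " count-table and ",
            length(dropped$from_metadata), " metadata sample(s)")
  tab <- subset_samples(table, common)
  md <- metadata
  md$data <- md$data[common, , drop = FALSE]
  list(table = tab, metadata = md, dropped = dropped)
}

subset_samples <- function(table, ids) {
  count_table(table$counts[, ids, drop = FALSE],
              taxonomy = table$taxonomy,
              go_annotation = table$go_annotation)
}

subset_features <- function(table, ids) {
  keep <- rownames(table$counts) %in% ids
  count_table(table$counts[keep, , drop = FALSE],
              taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[keep],
              go_annotation = if (!is.null(table$go_annotation))
                table$go_annotation[keep, , drop = FALSE])
}

effect_table_columns <- c("rab.all", "diff.btw", "diff.win", "effect",
                          "overlap", "we.ep", "we.eBH", "wi.ep", "wi.eBH")

#' Read a pre-computed effect table
#'
#' Accepts the column dialect produced by ALDEx2-style differential
#' abundance: `rab.all`, two `rab.win.<group>` columns (located by prefix),
#' `diff.btw`, `diff.win`, `effect`, `overlap`, `we.ep`, `we.eBH`, `wi.ep`,
#' `wi.eBH`.  The first column keys rows by feature id.  `"NA"` cells become
#' missing values.
#'
#' @param path path to a delimited file with a header row
#' @param delimiter `"tab"`, `"comma"`, or `"auto"`
#' @return a data.frame of class `effect_table`, feature ids as row names
#' @export
read_effect_table <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stop_coda("file not found: ", path)
  sep <- resolve_delimiter(delimiter, path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  ids <- as.character(raw[[1]])
  df <- raw[, -1, drop = FALSE]
  rab_win <- grep("^rab\\.win\\.", names(df), value = TRUE)
  if (length(rab_win) != 2L)
    stop_coda("expected exactly two rab.win.<group> columns, found ",
              length(rab_win))
  missing <- setdiff(effect_table_columns, names(df))
  if (length(missing))
    stop_coda("missing required column(s): ", paste(missing, collapse = ", "))
  keep <- c("rab.all", rab_win, setdiff(effect_table_columns, "rab.all"))
  df <- df[, keep, drop = FALSE]
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (any(!is.na(df[[j]]) & is.na(num)))
      stop_coda("non-numeric cell in column '", names(df)[j], "'")
    df[[j]] <- num
  }
  rownames(df) <- ids
  attr(df, "groups") <- sub("^rab\\.win\\.", "", rab_win)
  class(df) <- c("effect_table", "data.frame")
  df
}

#' Write an effect table in the ALDEx2 column dialect
#'
#' The emitted file re-imports through [read_effect_table()].
#'
#' @param effects an `effect_table` (see [effect_statistics()])
#' @param path output path
#' @export
write_effect_table <- function(effects, path) {
  write_tsv_det(as.data.frame(effects), path, row_label = "feature")
}
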