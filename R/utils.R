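# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_coda <- function(..., class = "codaexplore_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Sniff the delimiter of a delimited text file
#'
#' Inspects the first line; a tab wins over a comma when both are present
#' (MGnify-style exports are tab-delimited).
#'
#' @param path path to a delimited file
#' @return `"\t"` or `","`
#' @keywords internal
sniff_delimiter <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop_coda("empty file: ", path)
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

resolve_delimiter <- function(delimiter, path) {
  switch(delimiter,
    tab = "\t",
    comma = ",",
    auto = sniff_delimiter(path),
    stop_coda("unknown delimiter '", delimiter, "'; use tab, comma or auto"))
}

# Deterministic TSV writer used for every data artifact, so byte-identical
# reruns are a matter of identical numbers, not of formatting drift.
write_tsv_det <- function(df, path, row_label = NULL) {
  if (!is.null(row_label)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                row_label),
                as.data.frame(df, stringsAsFactors = FALSE))
    rownames(df) <- NULL
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  is.finite(x) & abs(x - round(x)) < tol
}
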