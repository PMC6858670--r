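# Static, headless rendering of the exploratory plots.  Every plot is
# written as SVG and PNG; the numbers behind it live in the TSV sidecar.

#' Render a plot record set to SVG and PNG
#'
#' Rendering is headless (cairo devices; no display required).  The PCA
#' biplot overlays sample scores and feature loadings with per-axis
#' proportion-of-variance labels; the effect plot draws the |effect| = 1
#' diagonals; the dendrogram panel adds a stacked relative-abundance bar
#' per sample when taxonomy is available.
#'
#' @param records output of [compute_plot_records()]
#' @param kind one of `pca_biplot`, `effect`, `ma`, `dendro_abundance`,
#'   `stripchart`, `histogram`
#' @param path_base output path without extension; `.svg` and `.png` are
#'   appended
#' @param state the [pipeline_state()] (required for `dendro_abundance`)
#' @param width,height device size in inches
#' @return character vector of the two files written, invisibly
#' @export
render_plot <- function(records, kind, path_base, state = NULL,
                        width = 7, height = 6) {
  if (is.null(records) || nrow(records) == 0L)
    stop_coda("empty record set for plot '", kind, "'")
  files <- paste0(path_base, c(".svg", ".png"))
  for (f in files) {
    if (grepl("\\.svg$", f)) grDevices::svg(f, width = width, height = height)
    else grDevices::png(f, width = width * 100, height = height * 100,
                        res = 100)
    tryCatch(draw_plot(records, kind, state),
             finally = grDevices::dev.off())
  }
  invisible(files)
}

class_palette <- c(nonsignificant = "grey60", effect_only = "#D55E00",
                   test_significant = "#0072B2", both = "#CC79A7")

draw_plot <- function(records, kind, state = NULL) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  switch(kind,
    pca_biplot = {
      ve <- attr(records, "variance_explained")
      sc <- records[records$type == "score", ]
      ld <- records[records$type == "loading", ]
      # loadings rescaled into the score range so both layers are visible
      rescale <- if (nrow(ld) && max(abs(c(ld$x, ld$y))) > 0)
        0.8 * max(abs(c(sc$x, sc$y))) / max(abs(c(ld$x, ld$y))) else 1
      lim <- range(c(sc$x, sc$y, ld$x * rescale, ld$y * rescale))
      graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
        xlab = sprintf("PC1 (%.1f%% of variance)", 100 * ve[1]),
        ylab = sprintf("PC2 (%.1f%% of variance)", 100 * ve[2]),
        main = "CLR-PCA biplot")
      graphics::abline(h = 0, v = 0, col = "grey85")
      graphics::points(ld$x * rescale, ld$y * rescale, pch = 4,
                       col = "grey50", cex = 0.6)
      cols <- if ("colour" %in% names(records)) sc$colour else "black"
      graphics::points(sc$x, sc$y, pch = 19, col = cols)
      graphics::text(sc$x, sc$y, sc$id, pos = 3, cex = 0.6)
      if ("colour" %in% names(records)) {
        uc <- unique(stats::na.omit(sc$colour))
        graphics::legend("topright", legend = seq_along(uc), col = uc,
                         pch = 19, cex = 0.7, title = "group colour")
      }
    },
    effect = {
      cols <- class_palette[records$class]
      lim <- max(abs(records$y), records$x, 1)
      graphics::plot(records$x, records$y, pch = 19, cex = 0.6, col = cols,
        xlim = c(0, lim), ylim = c(-lim, lim),
        xlab = "median within-group difference (diff.win)",
        ylab = "median between-group difference (diff.btw)",
        main = "Effect plot")
      graphics::abline(0, 1, lty = 2); graphics::abline(0, -1, lty = 2)
      graphics::legend("topleft", legend = names(class_palette),
                       col = class_palette, pch = 19, cex = 0.7)
    },
    ma = {
      cols <- class_palette[records$class]
      graphics::plot(records$x, records$y, pch = 19, cex = 0.6, col = cols,
        xlab = "median CLR abundance (rab.all)",
        ylab = "median between-group difference (diff.btw)",
        main = "MA plot")
      graphics::abline(h = 0, col = "grey70")
      graphics::legend("topleft", legend = names(class_palette),
                       col = class_palette, pch = 19, cex = 0.7)
    },
    dendro_abundance = {
      dendro <- attr(records, "dendro")
      if (is.null(dendro) && !is.null(state))
        dendro <- attr(compute_plot_records(state, "dendro_abundance"),
                       "dendro")
      if (is.null(dendro))
        stop_coda("dendrogram rendering needs the pipeline state")
      has_tax <- !is.null(state) && !is.null(state$table$taxonomy)
      if (has_tax) graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
      graphics::plot(dendro$hclust,
                     main = sprintf("Hierarchical clustering (%s linkage, %s)",
                                    dendro$linkage, dendro$distance),
                     xlab = "", sub = "")
      if (has_tax) {
        ab <- relative_abundance_by_taxon(
          state$table, level_delimiter = state$config$level_delimiter,
          level = state$config$taxonomy_level)
        ord <- dendro$hclust$labels[dendro$hclust$order]
        graphics::par(mar = c(4, 4, 1, 1))
        graphics::barplot(ab$proportions[, ord, drop = FALSE],
                          col = grDevices::hcl.colors(nrow(ab$proportions),
                                                      "Spectral"),
                          las = 2, cex.names = 0.6,
                          ylab = "relative abundance")
      }
    },
    stripchart = {
      cats <- unique(records$category)
      graphics::par(mfrow = c(length(cats), 1), mar = c(3, 10, 2, 1))
      for (ct in cats) {
        sub <- records[records$category == ct, ]
        ids <- unique(sub$go_id)
        graphics::plot(NA, xlim = range(sub$proportion),
                       ylim = c(0.5, length(ids) + 0.5),
                       yaxt = "n", xlab = "relative abundance", ylab = "",
                       main = ct)
        graphics::axis(2, at = seq_along(ids), labels = ids, las = 2,
                       cex.axis = 0.6)
        graphics::points(sub$proportion, match(sub$go_id, ids),
                         pch = 1, col = "#0072B2", cex = 0.7)
      }
    },
    histogram = {
      graphics::barplot(records$count, names.arg = records$level, las = 2,
                        ylab = "count", main = "Metadata frequencies",
                        cex.names = 0.7)
      nm <- attr(records, "n_missing")
      if (!is.null(nm) && nm > 0)
        graphics::mtext(sprintf("missing: %d", nm), side = 3, adj = 1,
                        cex = 0.7)
    },
    stop_coda("unknown plot kind '", kind, "'"))
}
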