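# Headless pipeline: configuration, orchestration, and reproducible-script
# export.  Every numeric artifact is a pure function of (inputs, config);
# reruns are byte-identical.

config_defaults <- function() list(
  counts = "",                 # path to the count table
  counts_dialect = "plain",    # plain | taxonomy_last_column | go_slim
  delimiter = "auto",          # tab | comma | auto
  metadata = "",               # optional path to the metadata table
  min_sample_total = 0,
  min_feature_total = 0,
  min_feature_max_prop = 0,
  selector_variable = "",      # optional metadata pre-filter
  selector_values = "",        # comma-separated allowed values
  selector_min = NA_real_,     # or a numeric range for continuous variables
  selector_max = NA_real_,
  zero_method = "czm",         # czm | pseudocount
  czm_frac = 0.65,
  pseudocount = 0.5,
  mc_instances = 128,
  prior = 0.5,
  mc_seed = 1,
  pair_seed = 2,
  effect_mode = "subsample",   # subsample | exact
  max_pairs = 10000,
  design_variable = "",        # two-level metadata variable for effects
  effect_test = "wilcoxon",    # wilcoxon | welch (for plot classing)
  effect_cutoff = 1.0,
  ebh_cutoff = 0.05,
  colour_variable = "",
  linkage = "complete",
  distance = "aitchison",
  biplot = "form",             # form | covariance
  taxonomy_level = 1,
  level_delimiter = ";",
  stages = "pca,cluster,effects,summaries",
  out_dir = "codaexplore_out"
)

#' Build a pipeline configuration
#'
#' A run configuration is a flat key-value list; every random seed is
#' explicit, and serialisation to/from the YAML config file is lossless.
#' Unknown keys are errors, not warnings, to protect reproducibility.
#'
#' @param ... configuration keys overriding the defaults (see
#'   `codaexplore:::config_defaults()` for the full list)
#' @return object of class `run_config`
#' @export
run_config <- function(...) {
  given <- list(...)
  defs <- config_defaults()
  unknown <- setdiff(names(given), names(defs))
  if (length(unknown))
    stop_coda("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, given)
  for (k in c("min_sample_total", "min_feature_total", "min_feature_max_prop",
              "czm_frac", "pseudocount", "mc_instances", "prior", "mc_seed",
              "pair_seed", "max_pairs", "effect_cutoff", "ebh_cutoff",
              "taxonomy_level"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path path to a flat key-value YAML file
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a pipeline configuration as flat YAML
#'
#' Round-trips losslessly through [read_run_config()].
#'
#' @param config a [run_config()]
#' @param path output path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_stages <- function(config)
  trimws(strsplit(config$stages, ",", fixed = TRUE)[[1]])

#' Execute the shared front of the pipeline
#'
#' Reads the inputs, aligns samples with the metadata, checks that every
#' metadata variable named in the config exists (before any computation),
#' filters, zero-handles, CLR-transforms, and — when a design variable is
#' configured — runs the Dirichlet Monte-Carlo differential-abundance
#' analysis.  The returned state feeds [run_pipeline()] and the exported
#' reproduction scripts, so both produce identical numbers.
#'
#' @param config a [run_config()]
#' @return a list with the validated inputs and every intermediate result
#' @export
pipeline_state <- function(config) {
  if (!nzchar(config$counts)) stop_coda("config key 'counts' is required")
  table <- read_count_table(config$counts, dialect = config$counts_dialect,
                            delimiter = config$delimiter)
  metadata <- NULL
  if (nzchar(config$metadata)) {
    metadata <- read_metadata(config$metadata, delimiter = config$delimiter)
    al <- align_samples(table, metadata)
    table <- al$table; metadata <- al$metadata
    for (key in c("selector_variable", "design_variable", "colour_variable")) {
      v <- config[[key]]
      if (nzchar(v) && !v %in% names(metadata$data))
        stop_coda("config key '", key, "' names metadata variable '", v,
                  "', which does not exist")
    }
  } else {
    for (key in c("selector_variable", "design_variable", "colour_variable"))
      if (nzchar(config[[key]]))
        stop_coda("config key '", key, "' needs a metadata table")
  }
  selector <- NULL
  if (nzchar(config$selector_variable)) {
    selector <- list(variable = config$selector_variable)
    if (nzchar(config$selector_values))
      selector$values <- trimws(strsplit(config$selector_values, ",")[[1]])
    else if (!is.na(config$selector_min) && !is.na(config$selector_max))
      selector$range <- c(config$selector_min, config$selector_max)
    else stop_coda("selector_variable given without selector_values or a ",
                   "selector_min/selector_max range")
  }
  spec <- filter_spec(config$min_sample_total, config$min_feature_total,
                      config$min_feature_max_prop, metadata_selector = selector)
  fl <- filter_counts(table, spec, metadata = metadata)
  table_f <- fl$table
  if (!is.null(metadata))
    metadata$data <- metadata$data[sample_ids(table_f), , drop = FALSE]
  pos <- zero_handle(table_f, method = config$zero_method,
                     frac = config$czm_frac, pseudo = config$pseudocount)
  clr_mat <- clr_transform(pos)
  effects <- NULL
  if (nzchar(config$design_variable)) {
    cond <- metadata$data[sample_ids(table_f), config$design_variable]
    effects <- aldex_like(table_f, cond, K = config$mc_instances,
                          prior = config$prior, seed = config$mc_seed,
                          mode = config$effect_mode,
                          max_pairs = config$max_pairs)
  }
  list(config = config, table_raw = table, table = table_f,
       report = fl$report, metadata = metadata, positive = pos,
       clr = clr_mat, effects = effects)
}

plot_kinds <- c("pca_biplot", "effect", "ma", "dendro_abundance",
                "stripchart", "histogram")

#' Compute the machine-readable record set behind a plot
#'
#' The sidecar data written next to each rendered plot; the reproduction
#' scripts regenerate exactly these records.
#'
#' @param state a [pipeline_state()]
#' @param kind one of `pca_biplot`, `effect`, `ma`, `dendro_abundance`,
#'   `stripchart`, `histogram`
#' @return a data.frame of plot records (plot-specific columns)
#' @export
compute_plot_records <- function(state, kind) {
  cfg <- state$config
  switch(kind,
    pca_biplot = {
      pca <- pca_clr(state$clr, scaling = cfg$biplot)
      rec <- rbind(
        data.frame(type = "score", id = rownames(pca$scores),
                   x = pca$scores[, 1], y = pca$scores[, 2],
                   stringsAsFactors = FALSE),
        data.frame(type = "loading", id = rownames(pca$loadings),
                   x = pca$loadings[, 1], y = pca$loadings[, 2],
                   stringsAsFactors = FALSE))
      rownames(rec) <- NULL
      if (nzchar(cfg$colour_variable)) {
        ca <- colour_by_metadata(state$metadata, cfg$colour_variable,
                                 sample_ids(state$table))
        rec$colour <- ifelse(rec$type == "score",
                             unname(ca$colours[rec$id]), NA)
      }
      attr(rec, "variance_explained") <- pca$variance_explained
      rec
    },
    effect = {
      if (is.null(state$effects))
        stop_coda("effect plot needs a design_variable in the config")
      effect_plot_data(state$effects, cfg$effect_cutoff, cfg$ebh_cutoff,
                       test = cfg$effect_test)
    },
    ma = {
      if (is.null(state$effects))
        stop_coda("MA plot needs a design_variable in the config")
      ma_plot_data(state$effects, cfg$effect_cutoff, cfg$ebh_cutoff,
                   test = cfg$effect_test)
    },
    dendro_abundance = {
      d <- sample_distance_matrix(
        if (cfg$distance == "jaccard_presence") state$table
        else if (cfg$distance == "euclidean_clr") state$clr
        else state$positive,
        metric = cfg$distance)
      dendro <- hierarchical_cluster(d, linkage = cfg$linkage)
      h <- dendro$hclust
      rec <- data.frame(step = seq_len(nrow(h$merge)),
                        left = h$merge[, 1], right = h$merge[, 2],
                        height = h$height, stringsAsFactors = FALSE)
      attr(rec, "dendro") <- dendro
      attr(rec, "order_ids") <- h$labels[h$order]
      rec
    },
    stripchart = {
      goslim_stripchart_data(
        state$table, metadata = state$metadata,
        colour_variable = if (nzchar(cfg$colour_variable))
          cfg$colour_variable)
    },
    histogram = {
      if (!nzchar(cfg$colour_variable))
        stop_coda("histogram needs a colour_variable in the config")
      metadata_histogram(state$metadata, cfg$colour_variable)
    },
    stop_coda("unknown plot kind '", kind, "'"))
}

#' Write plot records as a TSV or JSON sidecar
#'
#' @param records output of [compute_plot_records()]
#' @param path output path
#' @param format `"tsv"` (default) or `"json"`
#' @export
write_plot_records <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") write_tsv_det(records, path)
  else jsonlite::write_json(as.data.frame(records), path,
                            auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full pipeline and write all artifacts
#'
#' Executes read -> align -> filter -> zero-handle -> CLR and then the
#' requested stages (`pca`, `cluster`, `effects`, `summaries`), writing each
#' result table as TSV, each plot as SVG and PNG with a TSV sidecar of the
#' plotted records, the filter report (TSV and JSON), and a parameter
#' manifest.  Identical config and inputs yield byte-identical data
#' artifacts.
#'
#' @param config a [run_config()]
#' @return the output directory, invisibly; the pipeline state as attribute
#'   `"state"`
#' @export
run_pipeline <- function(config) {
  state <- pipeline_state(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- config_stages(config)

  write_count_table(state$table, file.path(out, "counts_filtered.tsv"))
  write_filter_report(state$report, file.path(out, "filter_report.tsv"))
  write_filter_report(state$report, file.path(out, "filter_report.json"),
                      format = "json")
  write_clr_matrix(state$clr, file.path(out, "clr.tsv"))

  produced <- character()
  emit <- function(kind) {
    rec <- compute_plot_records(state, kind)
    write_plot_records(rec, file.path(out, paste0(kind, "_data.tsv")))
    render_plot(rec, kind, file.path(out, kind))
    produced <<- c(produced, kind)
  }

  if ("pca" %in% stages) {
    pca <- pca_clr(state$clr, scaling = config$biplot)
    write_pca_result(pca, file.path(out, "pca"))
    emit("pca_biplot")
  }
  if ("cluster" %in% stages) {
    rec <- compute_plot_records(state, "dendro_abundance")
    write_plot_records(rec, file.path(out, "dendro_abundance_data.tsv"))
    dendro <- attr(rec, "dendro")
    write_dendrogram_newick(dendro, file.path(out, "dendrogram.nwk"))
    d <- sample_distance_matrix(
      if (config$distance == "jaccard_presence") state$table
      else if (config$distance == "euclidean_clr") state$clr
      else state$positive, metric = config$distance)
    write_tsv_det(as.data.frame(as.matrix(d)),
                  file.path(out, "distance.tsv"), row_label = "sample")
    render_plot(rec, "dendro_abundance", file.path(out, "dendro_abundance"),
                state = state)
    produced <- c(produced, "dendro_abundance")
  }
  if ("effects" %in% stages && !is.null(state$effects)) {
    write_effect_table(state$effects, file.path(out, "effect_table.tsv"))
    emit("effect")
    emit("ma")
  }
  if ("summaries" %in% stages) {
    if (!is.null(state$table$taxonomy)) {
      ab <- relative_abundance_by_taxon(state$table,
                                        level_delimiter = config$level_delimiter,
                                        level = config$taxonomy_level)
      write_abundance_summary(ab, file.path(out, "relative_abundance.tsv"))
    }
    if (!is.null(state$table$go_annotation)) emit("stripchart")
    if (nzchar(config$colour_variable)) emit("histogram")
  }

  manifest <- c(list(package = "codaexplore",
                     version = as.character(utils::packageVersion("codaexplore")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     plots = paste(sort(produced), collapse = ",")),
                unclass(config))
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  invisible(structure(out, state = state, produced = produced))
}

#' Export a commented script that reproduces one plot's data
#'
#' Emits a standalone, commented R script that — run from scratch against
#' the same inputs — regenerates the target plot's sidecar TSV
#' byte-identically and re-renders the plot.  Every user-chosen parameter
#' appears as a named, commented entry at the top.
#'
#' @param config the [run_config()] the plot was produced with
#' @param target plot name: one of `pca_biplot`, `effect`, `ma`,
#'   `dendro_abundance`, `stripchart`, `histogram`
#' @param path optional path to write the script to
#' @return the script text, invisibly when `path` is given
#' @export
export_reproduction_script <- function(config, target, path = NULL) {
  if (!target %in% plot_kinds)
    stop_coda("unknown plot target '", target, "'; expected one of ",
              paste(plot_kinds, collapse = ", "))
  cfg <- unclass(config)
  comments <- c(
    counts = "count table (features x samples)",
    counts_dialect = "plain | taxonomy_last_column | go_slim",
    delimiter = "tab | comma | auto",
    metadata = "per-sample metadata table (may be empty)",
    min_sample_total = "filtering: minimum sample total",
    min_feature_total = "filtering: minimum feature total",
    min_feature_max_prop = "filtering: minimum max per-sample proportion",
    zero_method = "zero handling: czm | pseudocount",
    czm_frac = "CZM fraction of the detection limit",
    pseudocount = "pseudocount added when zero_method = pseudocount",
    mc_instances = "Dirichlet Monte-Carlo instances (K)",
    prior = "Dirichlet prior added to every count",
    mc_seed = "seed for the Monte-Carlo draws",
    pair_seed = "seed for effect-size pair subsampling",
    effect_mode = "pair enumeration: subsample | exact",
    max_pairs = "pairs drawn per estimand in subsample mode",
    design_variable = "two-level metadata variable compared",
    effect_test = "expected-BH column used for classing",
    effect_cutoff = "|effect| cutoff for the plot classes",
    ebh_cutoff = "expected-BH cutoff for the plot classes",
    colour_variable = "metadata variable used for colouring",
    linkage = "hierarchical clustering linkage",
    distance = "distance: aitchison | euclidean_clr | jaccard_presence",
    biplot = "PCA biplot scaling: form | covariance",
    taxonomy_level = "lineage depth for relative-abundance grouping",
    level_delimiter = "lineage field separator",
    stages = "pipeline stages to run",
    out_dir = "output directory")
  fmt <- function(v) {
    if (is.character(v)) deparse(v)
    else if (is.na(v)) "NA_real_" else deparse(v)
  }
  param_lines <- vapply(names(cfg), function(k) {
    cm <- if (k %in% names(comments)) paste0("  # ", comments[[k]]) else ""
    sprintf("  %s = %s,%s", k, fmt(cfg[[k]]), cm)
  }, character(1))
  param_lines[length(param_lines)] <-
    sub(",(  #)", "\\1", param_lines[length(param_lines)])
  script <- c(
    sprintf("# Reproduces the data behind the '%s' plot.", target),
    "# Run from the directory the analysis was launched from:",
    sprintf("#   Rscript reproduce_%s.R", target),
    "# Adjust any parameter below and re-run to regenerate the plot.",
    "",
    "library(codaexplore)",
    "",
    "params <- list(",
    param_lines,
    ")",
    "",
    "config <- do.call(run_config, params)",
    "state <- pipeline_state(config)",
    sprintf("records <- compute_plot_records(state, \"%s\")", target),
    "",
    "# The sidecar TSV regenerated here is byte-identical to the one the",
    "# original run wrote next to the plot.",
    sprintf("write_plot_records(records, file.path(params$out_dir, \"%s_data.tsv\"))",
            target),
    if (target == "dendro_abundance")
      sprintf("render_plot(records, \"%s\", file.path(params$out_dir, \"%s\"), state = state)",
              target, target)
    else
      sprintf("render_plot(records, \"%s\", file.path(params$out_dir, \"%s\"))",
              target, target),
    "")
  text <- paste(script, collapse = "\n")
  parse(text = text)  # refuse to emit a syntactically invalid script
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
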