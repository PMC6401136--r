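# End-to-end orchestration: simulate -> reconstruct -> segment -> features ->
# classify, with per-stress-level whisker-box summaries (median, quartiles,
# 1.5*IQR whiskers, outliers beyond them).

#' Extract all eleven features from one hologram
#'
#' Runs reconstruction, head segmentation, OT conversion, and the
#' morphological + texture feature extractors for one cell.
#'
#' @param holo A [hologram()] (or path to one on disk).
#' @param recon Named list of reconstruction settings passed to
#'   [reconstruct_phase()] (`radius_frac`, `window`, `poly_order`).
#' @param texture Named list of texture settings (`entropy_bins`,
#'   `glcm_levels`, `glcm_offset`).
#' @param mask Optional `head_mask` (e.g. ground truth); default segments
#'   automatically.
#' @return One-row tibble with the eleven predictors.
#' @export
extract_cell_features <- function(holo, recon = list(), texture = list(),
                                  mask = NULL) {
  if (is.character(holo)) holo <- read_hologram(holo)
  pm <- do.call(reconstruct_phase, c(list(holo), recon))
  if (is.null(mask)) mask <- segment_head(pm)
  ot <- phase_to_ot(pm)
  dplyr::bind_cols(
    extract_morph_features(pm, ot, mask),
    do.call(extract_texture_features, c(list(pm, mask), texture))
  )
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters with a base seed and an output
#' directory. The configuration hash is invariant to key order and drives
#' the run manifest.
#'
#' @param out_dir Experiment output directory.
#' @param n_per_class Cells per class.
#' @param class_defs Class definitions as in [generate_dataset()].
#' @param base_seed Base seed for all randomness.
#' @param phantom A [phantom_config()].
#' @param carrier A [carrier_spec()].
#' @param jitter_cv Geometry jitter CV.
#' @param recon,texture,classify Stage parameter lists (see
#'   [extract_cell_features()] and [run_classification()]).
#' @param verbose Emit per-stage log lines.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("spermqpm_run_"),
                            n_per_class = 20L,
                            class_defs = list(
                              list(label = 0, s = 0),
                              list(label = 1, s = 1)),
                            base_seed = 1L, phantom = phantom_config(),
                            carrier = carrier_spec(), jitter_cv = 0.05,
                            recon = list(), texture = list(),
                            classify = list(train_fraction = 0.6,
                                            kernel = "linear", cost = 1),
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# order-invariant hash of a (possibly nested) named list
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, canon)
    } else v
  }
  rlang::hash(canon(unclass(x)))
}

#' Run the full experiment
#'
#' Generates the hologram dataset, reconstructs every cell, extracts
#' features, writes `features.csv`, a per-class whisker-box `summary.csv`, a
#' classification `report.json` + `roc.csv` (when the class labels are
#' exactly {0, 1}), and a `run_manifest.json` with the config hash. Two runs
#' from the same config are byte-identical in all CSV/JSON outputs
#' (wall-clock timestamps go to `run.log` only).
#'
#' @param config A [pipeline_config()].
#' @return A list with `features`, `summary`, `report` (or `NULL`), and
#'   `out_dir`.
#' @export
run_all <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config()")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  log_line <- function(stage, msg) {
    line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
    cat(line, "\n", file = logf, append = TRUE)
    if (isTRUE(config$verbose)) message(line)
  }

  log_line("simulate", sprintf("generating %d cells x %d classes",
                               config$n_per_class, length(config$class_defs)))
  manifest <- generate_dataset(
    file.path(out, "holograms"), config$n_per_class, config$class_defs,
    base_seed = config$base_seed, config = config$phantom,
    carrier = config$carrier, jitter_cv = config$jitter_cv, overwrite = TRUE
  )

  feats <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    t0 <- proc.time()[3]
    f <- tryCatch(
      extract_cell_features(file.path(out, "holograms", row$file),
                            recon = config$recon, texture = config$texture),
      error = function(e) {
        stopf("stage 'features' failed for %s: %s", row$cell_id, conditionMessage(e))
      }
    )
    log_line("features", sprintf("%s done in %.2fs", row$cell_id, proc.time()[3] - t0))
    feats[[k]] <- dplyr::bind_cols(row[c("cell_id", "label", "stress")], f)
  }
  features <- dplyr::bind_rows(feats)
  readr::write_csv(features, file.path(out, "features.csv"))

  summary <- summarize_features(features)
  readr::write_csv(summary, file.path(out, "summary.csv"))

  report <- NULL
  labels <- unique(features$label)
  if (setequal(labels, c(0, 1))) {
    log_line("classify", "training SVM")
    report <- do.call(run_classification,
                      c(list(features, seed = config$base_seed,
                             report_json = file.path(out, "report.json"),
                             roc_csv = file.path(out, "roc.csv")),
                        config$classify))
  } else {
    log_line("classify", "skipped (labels are not exactly {0, 1})")
  }

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("spermQPM")),
         config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
         n_cells = nrow(manifest),
         files = c("holograms/manifest.csv", "features.csv", "summary.csv",
                   if (!is.null(report)) c("report.json", "roc.csv"))),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  log_line("done", out)
  list(features = features, summary = summary, report = report, out_dir = out)
}

#' Whisker-box summary of features per class
#'
#' Median, quartiles, 1.5*IQR whisker bounds and outlier counts for every
#' feature, grouped by (label, stress) — the convention of the whisker-box
#' plots used to report these parameters.
#'
#' @param features Feature tibble from [run_all()] (needs `label`, `stress`
#'   plus the feature columns).
#' @return A tibble with one row per (label, stress, feature).
#' @export
summarize_features <- function(features) {
  cols <- intersect(c("max_phase", feature_columns()), names(features))
  features |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "feature") |>
    dplyr::group_by(.data$label, .data$stress, .data$feature) |>
    dplyr::summarise(
      median = median(.data$value),
      q25 = quantile(.data$value, 0.25, names = FALSE),
      q75 = quantile(.data$value, 0.75, names = FALSE),
      whisker_lo = min(.data$value[.data$value >= quantile(.data$value, 0.25) - 1.5 * stats::IQR(.data$value)]),
      whisker_hi = max(.data$value[.data$value <= quantile(.data$value, 0.75) + 1.5 * stats::IQR(.data$value)]),
      n_outliers = sum(.data$value < quantile(.data$value, 0.25) - 1.5 * stats::IQR(.data$value) |
                         .data$value > quantile(.data$value, 0.75) + 1.5 * stats::IQR(.data$value)),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Whisker-box plot of a feature across stress levels
#'
#' @param features Feature tibble (columns `stress` and the feature).
#' @param feature Feature name to plot.
#' @return A ggplot object (median/quartile boxes, 1.5*IQR whiskers, outlier
#'   points).
#' @export
plot_feature_boxes <- function(features, feature = "max_phase") {
  ggplot2::ggplot(features,
                  ggplot2::aes(factor(.data$stress), .data[[feature]])) +
    ggplot2::geom_boxplot(outlier.shape = 3, outlier.colour = "red",
                          coef = 1.5, fill = "lightsteelblue") +
    ggplot2::labs(x = "stress level s", y = feature)
}
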