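# Synthetic study generation: populations of jittered phantoms per class,
# rendered to holograms with a manifest linking each file to its label,
# stress level, seed and ground-truth features. All randomness flows from one
# base seed through a counter-based per-cell derivation, so a dataset is
# bit-reproducible.

#' Jitter a phantom configuration
#'
#' Per-cell biological variability: head semi-axes, peak phase and tail
#' length receive independent multiplicative factors `1 + cv * z` (z standard
#' normal, clamped to +/- 2.5 sd); orientation is drawn around a random grid
#' diagonal (+/- 0.35 rad), where a full-length cell always fits the square
#' field of view.
#'
#' @param config Base [phantom_config()].
#' @param cv Coefficient of variation (0 disables size/phase jitter;
#'   orientation is always randomized).
#' @param seed Integer seed.
#' @return A jittered `phantom_config`.
#' @export
jitter_config <- function(config, cv = 0.05, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  f <- function() 1 + cv * max(-2.5, min(2.5, rnorm(1)))
  cfg <- config
  cfg$head_a <- config$head_a * f()
  cfg$head_b <- config$head_b * f()
  cfg$phi_peak <- config$phi_peak * f()
  cfg$tail_length <- config$tail_length * f()
  # orientation: around a random grid diagonal, so a full-length cell always
  # fits the square field of view
  cfg$orientation <- pi / 4 + sample(0:3, 1) * pi / 2 + runif(1, -0.35, 0.35)
  cfg$seed <- seed
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  cfg
}

#' Generate a hologram dataset
#'
#' For each class definition (label, stress level, illumination mode) renders
#' `n_per_class` jittered phantoms to holograms on disk and writes
#' `manifest.csv` linking each file to its label, stress, seed and
#' ground-truth features. Deterministic given `base_seed`.
#'
#' @param out_dir Output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param n_per_class Cells per class (>= 1).
#' @param class_defs List of `list(label =, s =, illum =)` entries; `illum`
#'   is an [illumination_model()] (default pseudo-thermal preset).
#' @param base_seed Base seed from which all per-cell seeds derive.
#' @param config Base [phantom_config()].
#' @param carrier A [carrier_spec()].
#' @param jitter_cv Geometry jitter CV (see [jitter_config()]).
#' @param overwrite Allow writing into a directory holding a manifest.
#' @return The manifest tibble (columns `cell_id`, `label`, `stress`, `seed`,
#'   `true_max_phase`, `true_volume`, `true_area`, `file`), invisibly.
#' @export
generate_dataset <- function(out_dir, n_per_class,
                             class_defs = list(
                               list(label = 0, s = 0),
                               list(label = 1, s = 1)),
                             base_seed = 1L, config = phantom_config(),
                             carrier = carrier_spec(), jitter_cv = 0.05,
                             overwrite = FALSE) {
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stopf("output directory already holds a dataset manifest (%s); use overwrite = TRUE",
          manifest_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  counter <- 0L
  for (cd in class_defs) {
    illum <- cd$illum %||% illumination_model("pseudo_thermal")
    for (i in seq_len(n_per_class)) {
      counter <- counter + 1L
      cell_seed <- derive_seed(base_seed, counter)
      cfg <- jitter_config(config, cv = jitter_cv, seed = cell_seed)
      ph <- make_phantom(cfg)
      if (cd$s > 0) ph <- stress_transform(ph, cd$s)
      holo <- synthesize_hologram(ph, carrier = carrier, illum = illum,
                                  seed = derive_seed(base_seed, counter + 500000L))
      cell_id <- sprintf("cell_%04d", counter)
      fn <- file.path(out_dir, paste0(cell_id, ".tif"))
      write_hologram(holo, fn)
      rows[[counter]] <- tibble::tibble(
        cell_id = cell_id, label = cd$label, stress = cd$s, seed = cell_seed,
        true_max_phase = ph$truth$max_phase,
        true_volume = ph$truth$head_phase_volume,
        true_area = ph$truth$head_area,
        file = basename(fn)
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, manifest_path)
  invisible(manifest)
}
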