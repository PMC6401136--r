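# S3 containers for the 2D fields moving through the pipeline. All carry the
# calibration needed downstream (wavelength, pixel pitch, interferometer
# geometry); the pixel grid is a plain numeric matrix in `$data` with rows = y
# and columns = x.

#' Construct a hologram object
#'
#' An off-axis interferogram: a nonnegative 2D intensity grid (arbitrary
#' camera counts) plus the acquisition metadata needed for phase
#' reconstruction.
#'
#' @param data Numeric matrix of intensities (counts), all `>= 0`.
#' @param wavelength_nm Illumination wavelength in nm (default 632.8, HeNe).
#' @param dx,dy Pixel pitch in micrometres per pixel.
#' @param geometry `"reflection"` or `"transmission"`; decides the
#'   phase-to-optical-thickness factor (the beam traverses the specimen twice
#'   in reflection).
#' @param meta Optional named list of provenance (seed, phantom id,
#'   illumination mode).
#' @return An object of class `hologram`.
#' @export
hologram <- function(data, wavelength_nm = 632.8, dx = 0.1, dy = 0.1,
                     geometry = c("reflection", "transmission"), meta = list()) {
  geometry <- match.arg(geometry)
  if (!is.matrix(data) || !is.numeric(data)) stopf("hologram data must be a numeric matrix")
  if (anyNA(data) || any(!is.finite(data))) stopf("hologram contains non-finite intensities")
  if (any(data < 0)) stopf("hologram intensities must be nonnegative")
  structure(
    list(data = data, wavelength_nm = wavelength_nm, dx = dx, dy = dy,
         geometry = geometry, meta = meta),
    class = "hologram"
  )
}

new_spectrum <- function(data, dfx, dfy) {
  structure(list(data = data, dfx = dfx, dfy = dfy), class = "spectrum")
}

#' Construct a phase map
#'
#' @param data Numeric matrix of phase values in radians.
#' @param wavelength_nm,dx,dy,geometry Calibration, as in [hologram()].
#' @param wrapped Logical; `TRUE` if values are principal values in
#'   `(-pi, pi]`.
#' @param background_corrected Logical; `TRUE` once a background surface has
#'   been removed.
#' @param n_zero_mag Count of pixels whose complex magnitude was zero when the
#'   phase was taken (their phase is set to 0).
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(data, wavelength_nm = 632.8, dx = 0.1, dy = 0.1,
                      geometry = c("reflection", "transmission"),
                      wrapped = FALSE, background_corrected = FALSE,
                      n_zero_mag = 0L) {
  geometry <- match.arg(geometry)
  if (!is.matrix(data) || !is.numeric(data)) stopf("phase data must be a numeric matrix")
  if (wrapped && (any(data > pi) || any(data <= -pi))) {
    stopf("wrapped phase values must lie in (-pi, pi]")
  }
  structure(
    list(data = data, wavelength_nm = wavelength_nm, dx = dx, dy = dy,
         geometry = geometry, wrapped = wrapped,
         background_corrected = background_corrected,
         n_zero_mag = as.integer(n_zero_mag)),
    class = "phase_map"
  )
}

#' Construct an optical-thickness map
#'
#' Optical thickness (OT) in nanometres: `OT = phi * lambda / (4*pi)` in
#' reflection geometry (factor 2 for the double pass), `phi * lambda / (2*pi)`
#' in transmission.
#'
#' @param data Numeric matrix of OT values in nm.
#' @param dx,dy Pixel pitch in micrometres per pixel.
#' @param units OT unit label (always `"nm"` as produced here).
#' @return An object of class `ot_map`.
#' @export
ot_map <- function(data, dx = 0.1, dy = 0.1, units = "nm") {
  structure(list(data = data, dx = dx, dy = dy, units = units), class = "ot_map")
}

new_head_mask <- function(mask, dx, dy, provenance = c("auto", "ground_truth")) {
  provenance <- match.arg(provenance)
  px <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- if (px > 0) colMeans(idx)[c(2, 1)] else c(NA_real_, NA_real_)
  structure(
    list(mask = mask, dx = dx, dy = dy, n_pixels = as.integer(px),
         centroid_px = unname(centroid), provenance = provenance),
    class = "head_mask"
  )
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, lambda = %.1f nm, pitch = %.3g x %.3g um, %s geometry\n",
              nrow(x$data), ncol(x$data), x$wavelength_nm, x$dx, x$dy, x$geometry))
  cat(sprintf("  intensity range [%.3g, %.3g] counts\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, %s%s, range [%.3f, %.3f] rad\n",
              nrow(x$data), ncol(x$data),
              if (x$wrapped) "wrapped" else "unwrapped",
              if (x$background_corrected) ", background-corrected" else "",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ot_map <- function(x, ...) {
  cat(sprintf("<ot_map> %d x %d px, range [%.2f, %.2f] %s\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data), x$units))
  invisible(x)
}

#' @export
print.head_mask <- function(x, ...) {
  cat(sprintf("<head_mask> %d px (%s), centroid (%.1f, %.1f) px\n",
              x$n_pixels, x$provenance, x$centroid_px[1], x$centroid_px[2]))
  invisible(x)
}

field_to_tibble <- function(m, dx, dy, value_name = "value") {
  tibble::tibble(
    x = rep((seq_len(ncol(m)) - 1) * dx, each = nrow(m)),
    y = rep((seq_len(nrow(m)) - 1) * dy, times = ncol(m)),
    !!value_name := as.vector(m)
  )
}

#' Plot a field object with ggplot2
#'
#' Raster display of a hologram, phase map or optical-thickness map in
#' physical (micrometre) coordinates.
#'
#' @param object A `hologram`, `phase_map` or `ot_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_map <- function(object, ...) {
  df <- field_to_tibble(object$data, object$dx, object$dy, "phase")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @rdname autoplot.phase_map
#' @export
autoplot.hologram <- function(object, ...) {
  df <- field_to_tibble(object$data, object$dx, object$dy, "intensity")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "counts") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @rdname autoplot.phase_map
#' @export
autoplot.ot_map <- function(object, ...) {
  df <- field_to_tibble(object$data, object$dx, object$dy, "ot")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$ot)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("OT (%s)", object$units)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
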