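# Illumination models for off-axis interferogram synthesis. The interferogram
# is h = a(x,y) + b(x,y) * cos(2*pi*(fx*x + fy*y) + dphi(x,y)). The two modes
# emulate the two light sources compared experimentally:
#   * coherent: direct laser illumination; the fringe term is multiplied by a
#     correlated speckle field (exponentiated correlated Gaussian, contrast C,
#     correlation length ell) and a low-frequency parasitic fringe rides on
#     the background.
#   * pseudo_thermal: laser through a rotating diffuser / fibre bundle;
#     speckle-free, modelled as i.i.d. Gaussian intensity noise of std
#     sigma_I counts.
# Default noise amplitudes are calibration presets: they are chosen so the
# reconstructed flat-region phase std lands near the reported instrument
# sensitivities (~300 mrad coherent, ~20 mrad pseudo-thermal).

#' Illumination model
#'
#' @param mode `"pseudo_thermal"` (speckle-free, additive intensity noise) or
#'   `"coherent"` (speckled laser illumination).
#' @param a0 Background (DC) level in counts.
#' @param b0 Fringe modulation amplitude in counts; `a0 >= b0 >= 0` keeps the
#'   noiseless intensity nonnegative.
#' @param speckle_contrast Speckle contrast C in `[0, 1]` (coherent mode).
#' @param speckle_corr_px Speckle correlation length in pixels (`>= 1`).
#' @param parasitic_amp Amplitude (counts) of the parasitic low-frequency
#'   fringe (coherent mode).
#' @param parasitic_freq Parasitic fringe frequency in cycles/pixel.
#' @param sigma_I Additive intensity noise std in counts (pseudo-thermal
#'   mode).
#' @return A list of class `illumination_model`.
#' @export
illumination_model <- function(mode = c("pseudo_thermal", "coherent"),
                               a0 = 600, b0 = 300,
                               speckle_contrast = 0.43, speckle_corr_px = 3,
                               parasitic_amp = 60, parasitic_freq = 0.012,
                               sigma_I = 11.5) {
  mode <- match.arg(mode)
  if (a0 < b0 || b0 < 0) stopf("illumination requires a0 >= b0 >= 0")
  if (speckle_contrast < 0 || speckle_contrast > 1) stopf("speckle contrast must be in [0, 1]")
  if (speckle_corr_px < 1) stopf("speckle correlation length must be >= 1 pixel")
  structure(
    list(mode = mode, a0 = a0, b0 = b0, speckle_contrast = speckle_contrast,
         speckle_corr_px = speckle_corr_px, parasitic_amp = parasitic_amp,
         parasitic_freq = parasitic_freq, sigma_I = sigma_I),
    class = "illumination_model"
  )
}

#' Noiseless illumination (for round-trip fidelity checks)
#' @param a0,b0 Background and modulation in counts.
#' @return An `illumination_model` with all noise sources disabled.
#' @export
illum_noiseless <- function(a0 = 600, b0 = 300) {
  illumination_model("pseudo_thermal", a0 = a0, b0 = b0, sigma_I = 0)
}

#' Spatial-carrier specification
#'
#' Spatial frequencies of the off-axis interference fringes in cycles/pixel.
#' The carrier magnitude must stay below Nyquist (0.5 cycles/pixel) and far
#' enough from DC that the object sideband separates from the background
#' term.
#'
#' @param fx,fy Carrier frequencies (cycles/pixel).
#' @param min_dc_distance Minimum allowed carrier distance from DC
#'   (cycles/pixel); a configurable stand-in for twice the object's spectral
#'   half-width.
#' @return A list of class `carrier_spec`.
#' @export
carrier_spec <- function(fx = 0.22, fy = 0.22, min_dc_distance = 0.1) {
  r <- sqrt(fx^2 + fy^2)
  if (r <= 0 || r >= 0.5) stopf("carrier magnitude %.3f must lie in (0, 0.5) cycles/pixel", r)
  if (r < min_dc_distance) {
    stopf("carrier distance from DC (%.3f) is below the required separation %.3f",
          r, min_dc_distance)
  }
  structure(list(fx = fx, fy = fy), class = "carrier_spec")
}

# Correlated complex speckle field: exponentiated correlated complex
# Gaussian, approximately unit-mean amplitude with intensity contrast C and
# a random phase of comparable scale (the phase part is what degrades the
# reconstructed phase map under coherent illumination).
.speckle_field <- function(n, contrast, corr_px) {
  if (contrast == 0) return(matrix(1 + 0i, n, n))
  g1 <- gaussian_blur(matrix(rnorm(n * n), n, n), corr_px)
  g2 <- gaussian_blur(matrix(rnorm(n * n), n, n), corr_px)
  g1 <- (g1 - mean(g1)) / sd(g1)
  g2 <- (g2 - mean(g2)) / sd(g2)
  cc <- sqrt(log(1 + contrast^2))
  exp(cc * (g1 + 1i * g2) / sqrt(2) - cc^2 / 4)
}

#' Synthesize an off-axis hologram
#'
#' Renders `h = a + b * cos(2*pi*(fx*x + fy*y) + dphi)` for a phantom's phase
#' field under the given illumination model, clips at zero, and returns a
#' [hologram()] carrying the acquisition metadata. Fully reproducible from
#' `seed`.
#'
#' @param phantom A `sperm_phantom` (or any object with a `$data` phase
#'   matrix and `$config` with `dx`, `dy`).
#' @param carrier A [carrier_spec()].
#' @param illum An [illumination_model()].
#' @param seed Integer seed for the stochastic illumination terms.
#' @param wavelength_nm Illumination wavelength (nm).
#' @param geometry Interferometer geometry flag.
#' @return A [hologram()].
#' @export
synthesize_hologram <- function(phantom, carrier = carrier_spec(),
                                illum = illumination_model(), seed = 1L,
                                wavelength_nm = 632.8,
                                geometry = c("reflection", "transmission")) {
  geometry <- match.arg(geometry)
  if (!inherits(carrier, "carrier_spec")) stopf("carrier must be a carrier_spec()")
  if (!inherits(illum, "illumination_model")) stopf("illum must be an illumination_model()")
  phase <- if (is.matrix(phantom)) phantom else phantom$data
  nr <- nrow(phase); nc <- ncol(phase)
  dx <- if (is.matrix(phantom)) 0.1 else phantom$config$dx
  dy <- if (is.matrix(phantom)) 0.1 else phantom$config$dy

  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 1, nr, nc)
  arg <- 2 * pi * (carrier$fx * X + carrier$fy * Y) + phase

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  a <- matrix(illum$a0, nr, nc)
  b <- matrix(illum$b0, nr, nc)
  if (illum$mode == "coherent") {
    S <- .speckle_field(nr, illum$speckle_contrast, illum$speckle_corr_px)
    ang <- runif(1, 0, pi)
    ph0 <- runif(1, 0, 2 * pi)
    a <- a + illum$parasitic_amp *
      cos(2 * pi * illum$parasitic_freq * (cos(ang) * X + sin(ang) * Y) + ph0)
    h <- a + b * Re(S * exp(1i * arg))
  } else {
    h <- a + b * cos(arg)
    if (illum$sigma_I > 0) h <- h + matrix(rnorm(nr * nc, 0, illum$sigma_I), nr, nc)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  hologram(pmax(h, 0), wavelength_nm = wavelength_nm, dx = dx, dy = dy,
           geometry = geometry,
           meta = list(seed = seed, illumination = illum$mode,
                       carrier = c(fx = carrier$fx, fy = carrier$fy)))
}
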