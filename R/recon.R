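# Fourier-method phase reconstruction for off-axis holograms.
#
# The interferogram h = a + c*exp(2*pi*i*(fx x + fy y)) + conj(c)*exp(-...)
# with c = (b/2)*exp(i*phi) carries the full complex object field in one
# spectral sideband. Reconstruction: 2D FFT -> pick the sideband in the upper
# half-plane -> window it -> recentre to DC (carrier removal) -> inverse FFT
# -> four-quadrant phase -> 2D unwrap -> polynomial background removal.

#' Forward spectrum of a hologram
#'
#' DC-centred 2D discrete Fourier transform of the intensity grid.
#'
#' @param holo A [hologram()].
#' @return An object of class `spectrum` with the complex DC-centred array
#'   and the frequency step per bin (cycles/pixel).
#' @export
forward_spectrum <- function(holo) {
  if (!inherits(holo, "hologram")) stopf("input must be a hologram")
  if (anyNA(holo$data)) stopf("hologram contains NaN pixels")
  S <- fftshift(fft2(holo$data))
  new_spectrum(S, dfx = 1 / ncol(holo$data), dfy = 1 / nrow(holo$data))
}

#' Locate the object sideband
#'
#' Finds the maximum-magnitude bin in the upper half-plane of the spectrum
#' outside a guard disk around DC, then refines the estimate to sub-bin
#' precision with a 3x3 magnitude centroid.
#'
#' @param spectrum A `spectrum` from [forward_spectrum()].
#' @param dc_guard_radius Guard disk radius around DC (cycles/pixel).
#' @return Named numeric vector `c(fx, fy)` in cycles/pixel.
#' @export
locate_sideband <- function(spectrum, dc_guard_radius = 0.05) {
  if (dc_guard_radius <= 0) stopf("guard radius must be positive")
  S <- spectrum$data
  nr <- nrow(S); nc <- ncol(S)
  fx <- centered_freqs(nc); fy <- centered_freqs(nr)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  mag <- Mod(S)
  upper <- FY > 0 | (FY == 0 & FX > 0)
  ok <- upper & (FX^2 + FY^2 > dc_guard_radius^2)
  if (!any(ok) || max(mag[ok]) <= 0) stopf("no sideband found")
  cand <- mag
  cand[!ok] <- -Inf
  k <- arrayInd(which.max(cand), dim(cand))
  i <- k[1]; j <- k[2]
  # 3x3 centroid refinement (clamped at the array edge)
  ii <- max(2L, min(nr - 1L, i)); jj <- max(2L, min(nc - 1L, j))
  w <- mag[(ii - 1):(ii + 1), (jj - 1):(jj + 1)]
  di <- sum(w * matrix(-1:1, 3, 3)) / sum(w)
  dj <- sum(w * matrix(-1:1, 3, 3, byrow = TRUE)) / sum(w)
  c(fx = fx[j] + dj * spectrum$dfx, fy = fy[i] + di * spectrum$dfy)
}

#' Filter the sideband and recover the complex field
#'
#' Windows the spectrum around the chosen sideband (everything else is
#' zeroed), recentres the sideband to DC (carrier removal, including the
#' sub-bin residual), and inverse-transforms to the complex object field
#' `c(x,y) = b*exp(i*phi)`.
#'
#' @param spectrum A `spectrum`.
#' @param center Carrier estimate `c(fx, fy)` in cycles/pixel (e.g. from
#'   [locate_sideband()]).
#' @param radius Window radius in cycles/pixel: the hard window's cutoff, or
#'   the Gaussian window's 1/e radius.
#' @param window `"gaussian"` (default; suppresses ringing) or `"hard"`.
#' @return A list of class `complex_field` with the complex matrix and a
#'   `carrier_removed` flag.
#' @export
filter_sideband <- function(spectrum, center, radius,
                            window = c("gaussian", "hard")) {
  window <- match.arg(window)
  if (radius <= 0) stopf("window radius must be positive")
  d0 <- sqrt(sum(center^2))
  if (d0 <= radius) stopf("sideband window (radius %.3f) overlaps DC at carrier distance %.3f",
                          radius, d0)
  S <- spectrum$data
  nr <- nrow(S); nc <- ncol(S)
  FX <- matrix(centered_freqs(nc), nr, nc, byrow = TRUE)
  FY <- matrix(centered_freqs(nr), nr, nc)
  r2 <- (FX - center["fx"])^2 + (FY - center["fy"])^2
  W <- if (window == "hard") (r2 <= radius^2) * 1 else exp(-r2 / radius^2)
  # suppress the background (DC) delta so its tail cannot leak through a
  # soft window
  S[floor(nr / 2) + 1L, floor(nc / 2) + 1L] <- 0
  Sf <- S * W
  # integer-bin recentre, then demodulate the sub-bin residual in space
  sj <- round(center["fx"] * nc)
  si <- round(center["fy"] * nr)
  Sf <- circshift(Sf, -si, -sj)
  cfield <- ifft2(ifftshift(Sf))
  dfx <- center["fx"] - sj / nc
  dfy <- center["fy"] - si / nr
  if (dfx != 0 || dfy != 0) {
    X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
    Y <- matrix(seq_len(nr) - 1, nr, nc)
    cfield <- cfield * exp(-2i * pi * (dfx * X + dfy * Y))
  }
  structure(list(data = cfield, carrier_removed = TRUE,
                 wavelength_nm = attr(spectrum, "wavelength_nm")),
            class = "complex_field")
}

#' Wrapped phase of a complex field
#'
#' Four-quadrant angle of `c(x,y)`, principal values in `(-pi, pi]`.
#' Zero-magnitude pixels get phase 0 and are counted in `n_zero_mag`.
#'
#' @param field A `complex_field` from [filter_sideband()].
#' @param wavelength_nm,dx,dy,geometry Calibration carried forward to the
#'   [phase_map()].
#' @return A wrapped [phase_map()].
#' @export
wrapped_phase <- function(field, wavelength_nm = 632.8, dx = 0.1, dy = 0.1,
                          geometry = c("reflection", "transmission")) {
  geometry <- match.arg(geometry)
  cdata <- field$data
  if (any(!is.finite(Re(cdata)) | !is.finite(Im(cdata)))) stopf("complex field must be finite")
  zero <- Mod(cdata) == 0
  ph <- Arg(cdata)
  ph[zero] <- 0
  ph[ph <= -pi] <- pi  # Arg returns [-pi, pi]; fold -pi onto +pi
  phase_map(ph, wavelength_nm = wavelength_nm, dx = dx, dy = dy,
            geometry = geometry, wrapped = TRUE, n_zero_mag = sum(zero))
}

#' Unwrap a wrapped phase map
#'
#' Reliability-ordered 2D unwrapping (second-difference reliability, most
#' reliable pixel pairs joined first). The output differs from the input by
#' an integer multiple of 2*pi at every pixel and is anchored so the
#' background mode is approximately zero.
#'
#' @param wrapped A wrapped [phase_map()].
#' @return An unwrapped [phase_map()].
#' @export
unwrap_phase <- function(wrapped) {
  if (!inherits(wrapped, "phase_map")) stopf("input must be a phase_map")
  if (!wrapped$wrapped) stopf("input phase map is already unwrapped")
  u <- .cpp_unwrap(wrapped$data)
  # anchor: shift by 2*pi*k so the histogram mode sits in (-pi, pi], then
  # subtract nothing else (background removal is a separate step)
  rg <- range(u)
  if (diff(rg) == 0) rg <- rg + c(-1, 1) * 1e-9
  br <- seq(rg[1], rg[2], length.out = 257L)
  cnt <- tabulate(findInterval(u, br, rightmost.closed = TRUE), 256L)
  mode_val <- (br[which.max(cnt)] + br[which.max(cnt) + 1L]) / 2
  u <- u - 2 * pi * round(mode_val / (2 * pi))
  phase_map(u, wavelength_nm = wrapped$wavelength_nm, dx = wrapped$dx,
            dy = wrapped$dy, geometry = wrapped$geometry, wrapped = FALSE,
            n_zero_mag = wrapped$n_zero_mag)
}

#' Remove the background phase surface
#'
#' Least-squares polynomial surface (default order 2) fitted to background
#' pixels and subtracted; the background median is then forced to zero. When
#' no object mask is given, object pixels are excluded by an Otsu threshold
#' on the magnitude of the (median-filtered) phase.
#'
#' @param phase An unwrapped [phase_map()].
#' @param object_mask Optional logical matrix marking object pixels
#'   (`TRUE` = object, excluded from the fit).
#' @param order Polynomial surface order (default 2).
#' @return A background-corrected [phase_map()].
#' @export
remove_background <- function(phase, object_mask = NULL, order = 2L) {
  if (!inherits(phase, "phase_map")) stopf("input must be a phase_map")
  z <- phase$data
  nr <- nrow(z); nc <- ncol(z)
  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) / nc
  Y <- matrix(seq_len(nr) - 1, nr, nc) / nr
  terms <- list()
  for (p in 0:order) for (q in 0:(order - p)) terms[[length(terms) + 1L]] <- X^p * Y^q
  B <- vapply(terms, as.vector, numeric(nr * nc))
  fit_bg <- function(bg) {
    fit <- stats::lm.fit(B[bg, , drop = FALSE], z[bg])
    z - matrix(B %*% fit$coefficients, nr, nc)
  }
  if (is.null(object_mask)) {
    # the residual carrier tilt can dwarf the object, so the object mask is
    # estimated iteratively: fit on everything, re-threshold the residual,
    # refit on the background only
    bg <- rep(TRUE, nr * nc)
    for (it in 1:3) {
      res <- abs(.cpp_median3(fit_bg(bg)))
      bg <- as.vector(res <= otsu_threshold(res))
    }
    object_mask <- matrix(!bg, nr, nc)
  }
  bg <- as.vector(!object_mask)
  if (mean(bg) < 0.20) stopf("background region too small (%.0f%% of pixels; need >= 20%%)",
                             100 * mean(bg))
  out <- fit_bg(bg)
  out <- out - median(out[bg])
  phase_map(out, wavelength_nm = phase$wavelength_nm, dx = phase$dx,
            dy = phase$dy, geometry = phase$geometry, wrapped = FALSE,
            background_corrected = TRUE, n_zero_mag = phase$n_zero_mag)
}

#' Spatial phase sensitivity
#'
#' Standard deviation of the phase over a specimen-free region, in mrad;
#' the figure of merit used to compare illumination modes.
#'
#' @param phase A [phase_map()].
#' @param empty_region_mask Logical matrix marking the specimen-free region.
#' @return Phase std in mrad.
#' @export
phase_sensitivity <- function(phase, empty_region_mask) {
  if (!any(empty_region_mask)) stopf("specimen-free region is empty")
  1000 * sd(phase$data[empty_region_mask])
}

#' Convert phase to optical thickness
#'
#' `OT = phi * lambda / (4*pi)` in reflection geometry (the beam passes the
#' specimen twice) and `phi * lambda / (2*pi)` in transmission; OT is
#' returned in nm.
#'
#' @param phase An unwrapped, background-corrected [phase_map()].
#' @return An [ot_map()] in nm.
#' @export
phase_to_ot <- function(phase) {
  if (!inherits(phase, "phase_map")) stopf("input must be a phase_map")
  if (is.null(phase$wavelength_nm) || is.na(phase$wavelength_nm)) {
    stopf("phase map has no wavelength; cannot convert to optical thickness")
  }
  fac <- if (phase$geometry == "reflection") 4 * pi else 2 * pi
  ot_map(phase$data * phase$wavelength_nm / fac, dx = phase$dx, dy = phase$dy,
         units = "nm")
}

#' One-call phase reconstruction
#'
#' Convenience wrapper running the full chain: forward spectrum, sideband
#' location, sideband windowing (radius = `radius_frac` times the
#' DC-to-carrier distance), wrapped phase, unwrapping and background removal.
#'
#' @param holo A [hologram()].
#' @param radius_frac Window radius as a fraction of the carrier distance
#'   (default 0.6; wide enough to pass the object band of a 4-rad head at
#'   0.1 um/pixel sampling without biasing the peak).
#' @param window Window type, see [filter_sideband()].
#' @param poly_order Background surface order.
#' @param object_mask Optional object mask for background removal.
#' @param dc_guard_radius Guard radius for [locate_sideband()].
#' @return An unwrapped, background-corrected [phase_map()].
#' @export
reconstruct_phase <- function(holo, radius_frac = 0.6,
                              window = c("hard", "gaussian"), poly_order = 2L,
                              object_mask = NULL, dc_guard_radius = 0.05) {
  window <- match.arg(window)
  sp <- forward_spectrum(holo)
  fc <- locate_sideband(sp, dc_guard_radius)
  wrapped <- wrapped_phase(
    filter_sideband(sp, fc, radius = radius_frac * sqrt(sum(fc^2)), window = window),
    wavelength_nm = holo$wavelength_nm, dx = holo$dx, dy = holo$dy,
    geometry = holo$geometry
  )
  remove_background(unwrap_phase(wrapped), object_mask = object_mask,
                    order = poly_order)
}
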