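# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

# Swap quadrants so the DC bin sits at (floor(n/2)+1, floor(m/2)+1).
fftshift <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(seq(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2)))
  ci <- c(seq(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2)))
  x[ri, ci, drop = FALSE]
}

ifftshift <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(seq(ceiling(nr / 2) + 1L, nr), seq_len(ceiling(nr / 2)))
  ci <- c(seq(ceiling(nc / 2) + 1L, nc), seq_len(ceiling(nc / 2)))
  x[ri, ci, drop = FALSE]
}

# DFT bin frequencies in cycles/pixel, DC-centered to match fftshift().
centered_freqs <- function(n) (seq_len(n) - 1L - floor(n / 2)) / n

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular shift of a matrix by (di, dj) (positive = towards higher index).
circshift <- function(x, di, dj) {
  nr <- nrow(x); nc <- ncol(x)
  di <- ((di %% nr) + nr) %% nr
  dj <- ((dj %% nc) + nc) %% nc
  if (di > 0) x <- x[c((nr - di + 1L):nr, 1L:(nr - di)), , drop = FALSE]
  if (dj > 0) x <- x[, c((nc - dj + 1L):nc, 1L:(nc - dj)), drop = FALSE]
  x
}

# FFT-based Gaussian blur (periodic boundaries; objects are kept away from
# the grid edge so wrap-around is negligible). Kernel transfer functions are
# cached per (nr, nc, sigma).
.blur_cache <- new.env(parent = emptyenv())

gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  key <- paste(nrow(x), ncol(x), signif(sigma_px, 12), sep = "_")
  H <- .blur_cache[[key]]
  if (is.null(H)) {
    fr <- centered_freqs(nrow(x))
    fc <- centered_freqs(ncol(x))
    # FT of a unit-mass Gaussian with spatial std sigma_px
    Hr <- exp(-2 * pi^2 * sigma_px^2 * fr^2)
    Hc <- exp(-2 * pi^2 * sigma_px^2 * fc^2)
    H <- ifftshift(outer(Hr, Hc))
    .blur_cache[[key]] <- H
  }
  Re(ifft2(fft2(x) * H))
}

# Deterministic per-cell seed derivation from one base seed (counter-based,
# kept within the 32-bit integer range).
derive_seed <- function(base_seed, counter) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(counter) * 104729) %% 2147483647)
}

wrap_to_pi <- function(x) {
  w <- (x + pi) %% (2 * pi)
  w - pi + 2 * pi * (w == 0 & x > 0)  # principal value in (-pi, pi]
}

# Otsu threshold via EBImage on an arbitrary-range field.
otsu_threshold <- function(x) {
  rg <- range(x, finite = TRUE)
  if (diff(rg) == 0) return(rg[1])
  EBImage::otsu(EBImage::Image(x), range = rg)
}
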