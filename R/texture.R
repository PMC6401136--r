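# Texture statistics of the head-phase distribution: the first four
# (population) moments, Shannon entropy of the equal-width phase histogram,
# and the angular second moment (energy) of a normalized symmetric gray-level
# co-occurrence matrix (GLCM). These are the six statistics tabulated for
# control vs stressed cells; the printed formulas use population (1/N)
# normalisation and excess kurtosis, which is followed exactly.

#' Moment features of a phase sample
#'
#' Population mean, variance, excess kurtosis and skewness, exactly as the
#' printed definitions: `mu = (1/N) sum(phi_i)`,
#' `sigma^2 = (1/N) sum((phi_i - mu)^2)`,
#' `kurtosis = (1/N) sum(((phi_i - mu)/sigma)^4) - 3`,
#' `skewness = (1/N) sum(((phi_i - mu)/sigma)^3)`.
#'
#' @param values Numeric vector of phase samples (N >= 2).
#' @return A named list with `mean`, `variance`, `kurtosis`, `skewness`.
#' @export
moment_features <- function(values) {
  n <- length(values)
  if (n < 2) stopf("need at least 2 samples for moment features")
  mu <- mean(values)
  v <- mean((values - mu)^2)
  if (v == 0) stopf("degenerate distribution: zero variance, kurtosis/skewness undefined")
  z <- (values - mu) / sqrt(v)
  list(mean = mu, variance = v, kurtosis = mean(z^4) - 3, skewness = mean(z^3))
}

#' Histogram entropy of a phase sample
#'
#' Shannon entropy `-sum p_i log2 p_i` of the equal-width histogram over
#' `[min, max]` of the sample; empty bins are excluded from the sum.
#'
#' @param values Numeric vector (N >= 1).
#' @param n_bins Number of equal-width bins (>= 2; default 256).
#' @return Entropy in bits (0 when all values fall in one bin).
#' @export
histogram_entropy <- function(values, n_bins = 256L) {
  if (length(values) < 1) stopf("need at least one sample")
  if (n_bins < 2) stopf("need at least 2 bins")
  rg <- range(values)
  if (diff(rg) == 0) return(0)
  br <- seq(rg[1], rg[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}

# Quantize a matrix to integer levels 0..(levels-1), equal-width over rg.
.quantize <- function(x, levels, rg = range(x)) {
  if (diff(rg) == 0) return(matrix(0L, nrow(x), ncol(x)))
  q <- floor((x - rg[1]) / diff(rg) * levels)
  q[q >= levels] <- levels - 1L
  q[q < 0] <- 0L
  storage.mode(q) <- "integer"
  q
}

#' Co-occurrence energy of a phase ROI
#'
#' Quantizes the ROI to `levels` equal-width gray levels over its min-max,
#' builds the gray-level co-occurrence matrix at the given pixel offset,
#' symmetrizes and normalizes it to sum 1, and returns the angular second
#' moment `sum(p_ij^2)`.
#'
#' @param roi Numeric matrix (at least 2x2, and larger than the offset).
#' @param levels Number of gray levels (>= 2; default 16).
#' @param offset Integer pixel offset `c(di, dj)` (default `c(0, 1)`:
#'   horizontal neighbours).
#' @param quantized If `TRUE`, `roi` is already an integer level matrix in
#'   `0..levels-1` and is used as-is.
#' @param mask Optional logical matrix (same shape as `roi`): only pixel
#'   pairs with *both* members inside the mask are counted. Without it,
#'   background-background pairs dominate the statistic with the mask's
#'   bounding-box fill ratio rather than the cell's texture.
#' @return Energy in `(0, 1]`.
#' @export
glcm_energy <- function(roi, levels = 16L, offset = c(0L, 1L),
                        quantized = FALSE, mask = NULL) {
  if (levels < 2) stopf("need at least 2 gray levels")
  di <- offset[1]; dj <- offset[2]
  nr <- nrow(roi); nc <- ncol(roi)
  if (nr < 2 || nc < 2) stopf("ROI must be at least 2x2")
  if (abs(di) >= nr || abs(dj) >= nc) stopf("ROI smaller than the co-occurrence offset")
  q <- if (quantized) roi else .quantize(roi, levels)
  ri <- seq_len(nr - abs(di)); ci <- seq_len(nc - abs(dj))
  a <- q[ri + max(0, -di), ci + max(0, -dj)]
  b <- q[ri + max(0, di), ci + max(0, dj)]
  if (!is.null(mask)) {
    am <- mask[ri + max(0, -di), ci + max(0, -dj)]
    bm <- mask[ri + max(0, di), ci + max(0, dj)]
    keep <- am & bm
    if (!any(keep)) stopf("no co-occurrence pairs inside the mask")
    a <- a[keep]; b <- b[keep]
  }
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L, levels^2)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)                      # symmetrize
  p <- P / sum(P)
  sum(p^2)
}

#' Extract the texture feature set
#'
#' Moments and histogram entropy are computed on the masked phase samples;
#' energy is computed on the mask's bounding-box ROI. In-mask values are
#' quantized to levels `1..glcm_levels-1` over the masked min-max with level
#' 0 reserved for out-of-mask pixels, and only pixel pairs lying entirely
#' inside the mask enter the co-occurrence matrix: background pairs would
#' otherwise reduce the statistic to the bounding box's fill ratio.
#'
#' @param phase A [phase_map()].
#' @param mask A `head_mask` (or logical matrix).
#' @param entropy_bins Histogram bins for entropy (default 256).
#' @param glcm_levels Gray levels for energy (default 16).
#' @param glcm_offset Co-occurrence offset (default `c(0, 1)`).
#' @return A one-row tibble with columns `mean`, `variance`, `kurtosis`,
#'   `skewness`, `entropy`, `energy`.
#' @export
extract_texture_features <- function(phase, mask, entropy_bins = 256L,
                                     glcm_levels = 16L,
                                     glcm_offset = c(0L, 1L)) {
  m <- .mask_matrix(mask)
  if (!any(m)) stopf("head mask is empty")
  vals <- phase$data[m]
  mom <- moment_features(vals)
  ent <- histogram_entropy(vals, entropy_bins)
  idx <- which(m, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  roi <- phase$data[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mroi <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  q <- .quantize(roi, glcm_levels - 1L, rg = range(vals)) + 1L
  q[!mroi] <- 0L
  en <- glcm_energy(q, levels = glcm_levels, offset = glcm_offset,
                    quantized = TRUE, mask = mroi)
  tibble::tibble(
    mean = mom$mean, variance = mom$variance, kurtosis = mom$kurtosis,
    skewness = mom$skewness, entropy = ent, energy = en
  )
}
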