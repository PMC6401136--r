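# Independent brute-force oracles (direct summation / pair counting), kept
# deliberately naive so they cannot share a code path with the package.

brute_moments <- function(v) {
  n <- length(v)
  mu <- 0
  for (x in v) mu <- mu + x
  mu <- mu / n
  s2 <- 0
  for (x in v) s2 <- s2 + (x - mu)^2
  s2 <- s2 / n
  sk <- 0; ku <- 0
  for (x in v) {
    z <- (x - mu) / sqrt(s2)
    sk <- sk + z^3
    ku <- ku + z^4
  }
  list(mean = mu, variance = s2, skewness = sk / n, kurtosis = ku / n - 3)
}

brute_entropy <- function(v, n_bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(0)
  counts <- rep(0, n_bins)
  for (x in v) {
    b <- floor((x - lo) / (hi - lo) * n_bins) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  H <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / length(v)
      H <- H - p * log2(p)
    }
  }
  H
}

# naive symmetric co-occurrence pair counting on an integer level matrix
brute_glcm_energy <- function(q, levels, offset = c(0L, 1L)) {
  P <- matrix(0, levels, levels)
  di <- offset[1]; dj <- offset[2]
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        a <- q[i, j] + 1; b <- q[i2, j2] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  p <- P / sum(P)
  sum(p^2)
}

brute_volume <- function(ot_nm, mask, dx, dy) {
  v <- 0
  for (k in which(mask)) v <- v + ot_nm[k] / 1000 * dx * dy
  v
}

brute_surface <- function(ot_nm, mask, dx, dy) {
  z <- ot_nm / 1000
  nr <- nrow(z); nc <- ncol(z)
  s <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      jl <- max(1, j - 1); jr <- min(nc, j + 1)
      iu <- max(1, i - 1); id <- min(nr, i + 1)
      gx <- max(abs(z[i, jr] - z[i, j]), abs(z[i, j] - z[i, jl])) / dx
      gy <- max(abs(z[id, j] - z[i, j]), abs(z[i, j] - z[iu, j])) / dy
      s <- s + dx * dy * sqrt(1 + gx^2 + gy^2) + dx * dy
    }
  }
  s
}

# AUC as the normalized Mann-Whitney U statistic by explicit pair counting
brute_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  wins <- 0
  for (a in s1) {
    wins <- wins + sum(a > s0) + 0.5 * sum(a == s0)
  }
  wins / (length(s1) * length(s0))
}

# a compact phantom configuration that keeps tests fast
small_cfg <- function(...) {
  args <- list(n = 256L, tail_length = 18, tail_wave_amp = 1.5,
               mid_length = 2.5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

# synthetic feature table: two Gaussian classes separated by `delta` sds
toy_features <- function(n_per_class, delta = 3, seed = 1) {
  set.seed(seed)
  cols <- feature_columns()
  mk <- function(label, shift) {
    m <- matrix(rnorm(n_per_class * length(cols)), n_per_class)
    m[, 1] <- m[, 1] + shift
    colnames(m) <- cols
    dplyr::bind_cols(tibble::as_tibble(m),
                     tibble::tibble(label = label,
                                    cell_id = sprintf("c%d_%03d", label,
                                                      seq_len(n_per_class))))
  }
  dplyr::bind_rows(mk(0, 0), mk(1, delta))
}
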