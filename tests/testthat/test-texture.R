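test_that("moment features follow the population definitions", {
  m <- moment_features(c(-1, 1))
  expect_equal(m$mean, 0)
  expect_equal(m$variance, 1)
  expect_equal(m$skewness, 0)
  expect_equal(m$kurtosis, -2)

  set.seed(5)
  z <- rnorm(1e6)
  mz <- moment_features(z)
  expect_equal(mz$kurtosis, 0, tolerance = 0.01)
  expect_equal(mz$skewness, 0, tolerance = 0.01)

  expect_error(moment_features(rep(2, 10)), "degenerate")
  expect_error(moment_features(3), "at least 2")
})

test_that("moments transform correctly under shift and scale", {
  set.seed(8)
  v <- rgamma(500, 2)
  base <- moment_features(v)
  sh <- moment_features(v + 3.7)
  expect_equal(sh$mean, base$mean + 3.7)
  expect_equal(sh$variance, base$variance, tolerance = 1e-12)
  expect_equal(sh$skewness, base$skewness, tolerance = 1e-9)
  expect_equal(sh$kurtosis, base$kurtosis, tolerance = 1e-9)
  expect_equal(histogram_entropy(v + 3.7), histogram_entropy(v))
  sc <- moment_features(2.5 * v)
  expect_equal(sc$variance, 2.5^2 * base$variance, tolerance = 1e-12)
  expect_equal(sc$skewness, base$skewness, tolerance = 1e-9)
  expect_equal(sc$kurtosis, base$kurtosis, tolerance = 1e-9)
  expect_equal(histogram_entropy(2.5 * v), histogram_entropy(v))
})

test_that("histogram entropy has its analytic values", {
  v <- rep(seq(0.5, 7.5) / 8, times = 5)  # fills 8 bins equally
  expect_equal(histogram_entropy(v, 8), 3)
  expect_equal(histogram_entropy(rep(1.3, 50), 256), 0)
  # probabilities 0.5 / 0.25 / 0.25 over 3 bins
  v3 <- c(0.15, 0.25, 0.5, 0.9)
  expect_equal(histogram_entropy(v3, 3), 1.5)
  expect_error(histogram_entropy(numeric(0)), "at least one")
  expect_error(histogram_entropy(1:5, 1), "at least 2 bins")
})

test_that("co-occurrence energy has its analytic values", {
  expect_equal(glcm_energy(matrix(2.2, 8, 8)), 1)

  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(glcm_energy(cb, levels = 2, offset = c(0L, 1L)), 0.5)

  set.seed(31)
  L <- 8L
  big <- matrix(sample.int(L, 250 * 250, replace = TRUE) - 1L, 250, 250)
  en <- glcm_energy(big, levels = L, quantized = TRUE)
  expect_equal(en, 1 / L^2, tolerance = 0.05)

  expect_error(glcm_energy(matrix(1, 1, 5)), "at least 2x2")
  expect_error(glcm_energy(matrix(1, 3, 3), offset = c(0L, 5L)), "offset")
})

test_that("texture features agree with brute-force oracles on random ROIs", {
  set.seed(77)
  for (rep in 1:10) {
    nr <- sample(15:40, 1); nc <- sample(15:40, 1)
    roi <- matrix(rgamma(nr * nc, 2, 1), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    mask[sample(nr, 1), ] <- TRUE  # keep it nonempty
    v <- roi[mask]

    mm <- moment_features(v)
    bb <- brute_moments(v)
    for (k in names(bb)) expect_equal(mm[[k]], bb[[k]], tolerance = 1e-10)

    expect_equal(histogram_entropy(v, 64), brute_entropy(v, 64),
                 tolerance = 1e-10)

    q <- spermQPM:::.quantize(roi, 16L, rg = range(v))
    q[!mask] <- 0L
    expect_equal(glcm_energy(q, 16L, quantized = TRUE),
                 brute_glcm_energy(q, 16L), tolerance = 1e-10)
  }
})

test_that("the texture bundle matches its components and rejects empty masks", {
  set.seed(12)
  z <- matrix(rgamma(30 * 30, 2), 30, 30)
  m <- matrix(TRUE, 30, 30)
  tx <- extract_texture_features(phase_map(z), m)
  mom <- moment_features(z[m])
  expect_equal(tx$mean, mom$mean)
  expect_equal(tx$variance, mom$variance)
  expect_equal(tx$entropy, histogram_entropy(z[m], 256))
  expect_true(tx$energy > 0 && tx$energy <= 1)
  expect_error(extract_texture_features(phase_map(z), m & FALSE), "empty")
})

test_that("stressed phantoms shift every texture statistic in the reported direction", {
  # paired control/stressed medians over a few jittered cells; the
  # population-level version is exercised at larger n in the acceptance suite
  feats <- list()
  for (i in 1:5) {
    cfg <- jitter_config(phantom_config(), cv = 0.05,
                         seed = spermQPM:::derive_seed(2024L, i))
    base <- make_phantom(cfg)
    for (s in c(0, 1)) {
      ph <- stress_transform(base, s)
      h <- synthesize_hologram(ph, illum = illumination_model("pseudo_thermal"),
                               seed = spermQPM:::derive_seed(2025L, 2 * i + s))
      pm <- reconstruct_phase(h)
      tx <- extract_texture_features(pm, segment_head(pm))
      feats[[length(feats) + 1]] <- dplyr::bind_cols(tibble::tibble(s = s), tx)
    }
  }
  med <- dplyr::bind_rows(feats) |>
    dplyr::group_by(s) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), median))
  ctl <- med[med$s == 0, ]; str <- med[med$s == 1, ]
  expect_lt(str$mean, ctl$mean)
  expect_lt(str$variance, ctl$variance)
  expect_gt(str$kurtosis, ctl$kurtosis)
  expect_gt(str$skewness, ctl$skewness)
  expect_gt(str$entropy, ctl$entropy)
  expect_lt(str$energy, ctl$energy)
})
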