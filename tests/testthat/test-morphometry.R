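test_that("head segmentation matches the ground-truth mask", {
  ph <- make_phantom(phantom_config())
  h <- synthesize_hologram(ph, illum = illumination_model("pseudo_thermal"),
                           seed = 21)
  pm <- reconstruct_phase(h)
  mk <- segment_head(pm)
  iou <- sum(mk$mask & ph$head_mask) / sum(mk$mask | ph$head_mask)
  expect_gte(iou, 0.90)
  expect_equal(mk$provenance, "auto")
  expect_error(segment_head(phase_map(matrix(0, 64, 64))), "no head")
})

test_that("segmentation tie-break keeps the optically taller blob", {
  n <- 128L
  g <- seq_len(n)
  z <- matrix(0, n, n)
  blob <- function(cx, cy, r, h) {
    d2 <- outer((g - cy)^2, (g - cx)^2, "+")
    h * pmax(1 - d2 / r^2, 0)
  }
  z <- z + blob(40, 40, 12, 1) + blob(90, 90, 12, 3)
  mk <- segment_head(phase_map(z), min_px = 10)
  expect_gt(mean(z[mk$mask]), 1)  # the taller blob was selected
})

test_that("max phase is the median-filtered in-mask maximum", {
  z <- matrix(0, 64, 64)
  m <- matrix(FALSE, 64, 64); m[20:40, 20:40] <- TRUE
  z[m] <- 2
  expect_equal(max_phase(phase_map(z), m), 2)
  z[30, 30] <- 12  # single hot pixel is rejected by the 3x3 median
  expect_equal(max_phase(phase_map(z), m), 2)
  expect_error(max_phase(phase_map(z), matrix(FALSE, 64, 64)), "empty")
})

test_that("optical volume integrates OT over the mask", {
  ot <- ot_map(matrix(10, 20, 20), dx = 0.1, dy = 0.1)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE  # 100 px
  # 100 px * 10 nm * 0.01 um^2 = 10 um^2*nm = 0.01 um^3
  expect_equal(optical_volume(ot, m), 0.01, tolerance = 1e-12)
  ot_bad <- ot; ot_bad$units <- "um"
  expect_error(optical_volume(ot_bad, m), "unit mismatch")
})

test_that("surface area follows the Monge closed forms", {
  # flat field: dS reduces to dxdy, S = 2 * projected area
  ot <- ot_map(matrix(50, 30, 30), dx = 0.1, dy = 0.1)
  m <- matrix(TRUE, 30, 30)
  A <- 30 * 30 * 0.01
  expect_equal(surface_area(ot, m), 2 * A, tolerance = 1e-9)

  # tilted plane with gradients (gx, gy) in consistent units
  gx <- 0.4; gy <- -0.7
  n <- 40L
  X <- matrix(seq_len(n) - 1, n, n, byrow = TRUE) * 0.1
  Y <- matrix(seq_len(n) - 1, n, n) * 0.1
  z_um <- gx * X + gy * Y
  ot2 <- ot_map(z_um * 1000, dx = 0.1, dy = 0.1)
  m2 <- matrix(FALSE, n, n); m2[2:(n - 1), 2:(n - 1)] <- TRUE
  A2 <- sum(m2) * 0.01
  expect_equal(surface_area(ot2, m2), A2 * (sqrt(1 + gx^2 + gy^2) + 1),
               tolerance = 1e-9)
})

test_that("hemisphere fixture recovers its analytic volume and area", {
  hemi <- hemisphere_fixture(r = 5, dx = 0.1)
  V <- optical_volume(hemi$ot, hemi$mask)
  S <- surface_area(hemi$ot, hemi$mask)
  expect_equal(V, hemi$V, tolerance = 0.01)
  expect_equal(S, hemi$S, tolerance = 0.02)
  # mesh refinement: halving the pitch moves V and S by < 0.5%
  hemi2 <- hemisphere_fixture(r = 5, dx = 0.05)
  expect_lt(abs(optical_volume(hemi2$ot, hemi2$mask) / V - 1), 0.005)
  expect_lt(abs(surface_area(hemi2$ot, hemi2$mask) / S - 1), 0.005)
})

test_that("sphericity has the sphere, disk and hemisphere limits", {
  r <- 2.3
  expect_equal(round(sphericity(4 * pi * r^2, 4 / 3 * pi * r^3), 2), 1.00)
  t <- 1e-6 * r
  expect_equal(round(sphericity(2 * pi * r^2 + 2 * pi * r * t, pi * r^2 * t), 2),
               0.00)
  expect_equal(sphericity(3 * pi * r^2, 2 / 3 * pi * r^3), 0.841,
               tolerance = 0.001)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -1), "nonnegative")
})

test_that("the morphological feature bundle is internally consistent", {
  hemi <- hemisphere_fixture(r = 5, dx = 0.1)
  pm <- phase_map(hemi$ot$data * 4 * pi / 632.8)
  f <- extract_morph_features(pm, hemi$ot, hemi$mask)
  expect_equal(f$sphericity, 4.84 * f$V^(2 / 3) / f$S, tolerance = 1e-12)
  expect_equal(f$S_over_V, f$S / f$V, tolerance = 1e-12)
  expect_gt(f$S, sum(hemi$mask) * 0.01)  # S exceeds projected area
  expect_equal(f$ot_max, 5000, tolerance = 0.01)
  expect_error(extract_morph_features(pm, hemi$ot, hemi$mask & FALSE), "empty")
})

test_that("features are robust to phantom rotation", {
  f_of <- function(orient) {
    ph <- make_phantom(phantom_config(orientation = orient))
    h <- synthesize_hologram(ph, illum = illum_noiseless(), seed = 9)
    pm <- reconstruct_phase(h)
    extract_morph_features(pm, phase_to_ot(pm), segment_head(pm))
  }
  a <- f_of(pi / 4)
  b <- f_of(pi / 4 + pi / 6)
  for (col in names(a)) {
    expect_lt(abs(b[[col]] / a[[col]] - 1), 0.02)
  }
})
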