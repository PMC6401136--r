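mk_holo <- function(m) hologram(m)

test_that("forward spectrum behaves like a DC-centred DFT", {
  n <- 64L
  const <- mk_holo(matrix(3, n, n))
  S <- forward_spectrum(const)
  mag <- Mod(S$data)
  dc <- c(n / 2 + 1, n / 2 + 1)
  expect_equal(mag[dc[1], dc[2]], 3 * n^2)
  expect_lt(max(mag[-((dc[2] - 1) * n + dc[1])]), 1e-6)

  # pure cosine: two symmetric peaks
  X <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  Y <- matrix(seq_len(n) - 1, n, n)
  h <- mk_holo(10 + cos(2 * pi * (0.125 * X + 0.25 * Y)))
  S2 <- forward_spectrum(h)
  mag2 <- Mod(S2$data)
  i1 <- c(n / 2 + 1 + 0.25 * n, n / 2 + 1 + 0.125 * n)
  i2 <- c(n / 2 + 1 - 0.25 * n, n / 2 + 1 - 0.125 * n)
  expect_equal(mag2[i1[1], i1[2]], n^2 / 2, tolerance = 1e-6)
  expect_equal(mag2[i2[1], i2[2]], n^2 / 2, tolerance = 1e-6)

  # Parseval
  expect_equal(sum(h$data^2), sum(mag2^2) / n^2, tolerance = 1e-9)
})

test_that("sideband location matches a brute-force half-plane argmax", {
  ph <- make_phantom(small_cfg())
  h <- synthesize_hologram(ph, carrier = carrier_spec(0.22, 0.22),
                           illum = illumination_model("pseudo_thermal"),
                           seed = 3)
  sp <- forward_spectrum(h)
  est <- locate_sideband(sp)
  expect_equal(unname(est), c(0.22, 0.22), tolerance = 1 / 256)

  # brute force: exhaustive argmax over the upper half-plane outside guard
  n <- nrow(sp$data)
  f <- (seq_len(n) - 1 - floor(n / 2)) / n
  best <- c(-Inf, NA, NA)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    fy <- f[i]; fx <- f[j]
    if (!(fy > 0 || (fy == 0 && fx > 0))) next
    if (fx^2 + fy^2 <= 0.05^2) next
    m <- Mod(sp$data[i, j])
    if (m > best[1]) best <- c(m, fx, fy)
  }
  # same bin as the pre-refinement estimate
  expect_equal(round(est[["fx"]] * n), round(best[2] * n))
  expect_equal(round(est[["fy"]] * n), round(best[3] * n))

  # fringe-free image has no sideband
  expect_error(locate_sideband(forward_spectrum(mk_holo(matrix(5, 64, 64)))),
               "no sideband")
})

test_that("sideband filtering isolates the complex object field", {
  n <- 128L
  X <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  Y <- matrix(seq_len(n) - 1, n, n)
  h <- mk_holo(200 + 100 * cos(2 * pi * (0.25 * X + 0.25 * Y)))
  sp <- forward_spectrum(h)
  cf <- filter_sideband(sp, c(fx = 0.25, fy = 0.25), radius = 0.1)
  mag <- Mod(cf$data)
  expect_lt(diff(range(mag)) / mean(mag), 0.01)   # |c| constant within 1%
  expect_equal(mean(mag), 50, tolerance = 0.01)    # b/2
  expect_error(filter_sideband(sp, c(fx = 0.25, fy = 0.25), radius = 0),
               "positive")
  expect_error(filter_sideband(sp, c(fx = 0.05, fy = 0), radius = 0.2),
               "overlaps DC")
})

test_that("wrapped phase is the principal-value four-quadrant angle", {
  cf <- structure(list(data = matrix(exp(1i * 1.0), 8, 8)), class = "complex_field")
  expect_equal(wrapped_phase(cf)$data, matrix(1, 8, 8))
  cf2 <- structure(list(data = matrix(2 + 0i, 8, 8)), class = "complex_field")
  expect_equal(wrapped_phase(cf2)$data, matrix(0, 8, 8))
  cf3 <- structure(list(data = matrix(exp(1i * (pi + 0.1)), 8, 8)),
                   class = "complex_field")
  expect_equal(wrapped_phase(cf3)$data, matrix(-pi + 0.1, 8, 8))
  # zero-magnitude pixels get phase 0 and are counted
  z <- matrix(exp(1i * 0.5), 8, 8); z[1, 1] <- 0
  cf4 <- structure(list(data = z), class = "complex_field")
  pm <- wrapped_phase(cf4)
  expect_equal(pm$n_zero_mag, 1L)
  expect_equal(pm$data[1, 1], 0)
})

test_that("phase unwrapping recovers ramps and bumps and is congruent mod 2pi", {
  n <- 128L
  ramp <- matrix(seq(0, 6 * pi, length.out = n), n, n, byrow = TRUE)
  w <- phase_map(spermQPM:::wrap_to_pi(ramp), wrapped = TRUE)
  u <- unwrap_phase(w)
  d <- u$data - ramp
  expect_lt(diff(range(d)), 1e-6)  # exact up to a global 2*pi*k

  # already-unwrapped smooth field within (-pi, pi): unchanged
  sm <- matrix(0.4, n, n) + outer(sin(seq(0, pi, length.out = n)),
                                  cos(seq(0, pi, length.out = n))) * 0.5
  u2 <- unwrap_phase(phase_map(spermQPM:::wrap_to_pi(sm), wrapped = TRUE))
  expect_equal(max(abs(u2$data - sm)), 0, tolerance = 1e-9)

  # Gaussian bump of peak 4 rad
  g <- seq_len(n) - n / 2 - 0.5
  bump <- 4 * exp(-outer(g^2, g^2, "+") / (2 * 12^2))
  u3 <- unwrap_phase(phase_map(spermQPM:::wrap_to_pi(bump), wrapped = TRUE))
  expect_lt(max(abs(u3$data - bump)), 0.01)

  # congruence: rewrapping reproduces the wrapped input exactly
  rewrapped <- spermQPM:::wrap_to_pi(u3$data)
  wrapped_in <- spermQPM:::wrap_to_pi(bump)
  expect_equal(rewrapped, wrapped_in, tolerance = 1e-9)
  expect_error(unwrap_phase(u3), "already unwrapped")
})

test_that("background removal fits and subtracts a polynomial surface", {
  n <- 96L
  X <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  Y <- matrix(seq_len(n), n, n) / n
  plane <- 0.7 + 2.1 * X - 1.3 * Y
  out <- remove_background(phase_map(plane),
                           object_mask = matrix(FALSE, n, n))
  expect_lt(sd(out$data), 1e-9)

  # zero field stays zero
  z <- remove_background(phase_map(matrix(0, n, n)),
                         object_mask = matrix(FALSE, n, n))
  expect_equal(max(abs(z$data)), 0, tolerance = 1e-12)

  # phantom + tilt: phantom recovered with auto mask estimation
  ph <- make_phantom(small_cfg())
  tilt <- 1.5 * matrix(seq_len(256), 256, 256, byrow = TRUE) / 256
  rec <- remove_background(phase_map(ph$data + tilt, dx = 0.1, dy = 0.1))
  b <- 17:240
  expect_lt(sqrt(mean((rec$data[b, b] - ph$data[b, b])^2)), 0.02)

  expect_error(remove_background(phase_map(plane),
                                 object_mask = matrix(TRUE, n, n)),
               "background region too small")
})

test_that("phase sensitivity measures flat-region noise in mrad", {
  pm <- phase_map(matrix(1.234, 100, 100))
  expect_equal(phase_sensitivity(pm, matrix(TRUE, 100, 100)), 0)
  expect_error(phase_sensitivity(pm, matrix(FALSE, 100, 100)), "empty")

  set.seed(99)
  noise <- matrix(rnorm(1e4, 0, 0.02), 100, 100)
  s <- phase_sensitivity(phase_map(noise), matrix(TRUE, 100, 100))
  expect_equal(s, 20, tolerance = 0.1)  # 20 +/- 2 mrad
})

test_that("pseudo-thermal preset lands in the reported sensitivity band", {
  ph <- make_phantom(phantom_config())
  bg <- ph$data < 1e-4
  bg[1:32, ] <- FALSE; bg[, 1:32] <- FALSE
  bg[481:512, ] <- FALSE; bg[, 481:512] <- FALSE
  er <- EBImage::erode(EBImage::Image(bg * 1), EBImage::makeBrush(9, "disc")) > 0
  h <- synthesize_hologram(ph, illum = illumination_model("pseudo_thermal"),
                           seed = 11)
  s <- phase_sensitivity(reconstruct_phase(h), er)
  expect_gt(s, 20 - 1.5)
  expect_lt(s, 20 + 1.5)
})

test_that("phase converts to optical thickness by the geometry factor", {
  pm <- phase_map(matrix(c(0, 4), 2, 2), wavelength_nm = 632.8,
                  geometry = "reflection")
  ot <- phase_to_ot(pm)
  expect_equal(ot$data[1, 1], 0)
  expect_equal(ot$data[2, 1], 4 * 632.8 / (4 * pi), tolerance = 1e-9)  # ~201.4 nm
  pm_t <- phase_map(pm$data, wavelength_nm = 632.8, geometry = "transmission")
  expect_equal(phase_to_ot(pm_t)$data, 2 * ot$data, tolerance = 1e-12)
  pm_bad <- pm; pm_bad$wavelength_nm <- NA
  expect_error(phase_to_ot(pm_bad), "wavelength")
})

test_that("reconstruction is linear in the object phase below wrap density", {
  n <- 256L
  g <- seq_len(n) - n / 2 - 0.5
  bump <- 0.8 * exp(-outer(g^2, g^2, "+") / (2 * 10^2))
  msk <- bump > 0.01 * max(bump)
  fake <- function(m) structure(list(data = m, config = list(dx = 0.1, dy = 0.1)),
                                class = "sperm_phantom")
  r1 <- reconstruct_phase(synthesize_hologram(fake(bump),
                                              illum = illum_noiseless(), seed = 1),
                          object_mask = msk)
  r2 <- reconstruct_phase(synthesize_hologram(fake(2 * bump),
                                              illum = illum_noiseless(), seed = 1),
                          object_mask = msk)
  expect_equal(max(r2$data[msk]) / max(r1$data[msk]), 2, tolerance = 0.01)
})
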