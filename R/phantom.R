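# Parametric sperm-cell phase phantoms.
#
# The ground-truth phase field is composed in cell-local coordinates
# (u along the cell axis, v across it) from four parts:
#   * an acrosomal/membrane plateau over the whole head ellipse,
#     h_pl * (1 - rho^2)^g_pl,
#   * a nucleus bump (the tallest structure) on the posterior head,
#   * a tapered midpiece ridge,
#   * a low-phase undulating tail ribbon of configurable arc length.
# The composed field is band-limited by a Gaussian PSF (the instrument's
# resolution limit), and the nucleus height is normalised so the field
# maximum equals the configured peak phase exactly.
#
# The oxidative-stress deformation (stress level s in [0,1]) models the
# flattening and heterogeneity reported for H2O2-stressed cells: the peak
# phase scales by (1 - kappa*s); the acrosomal plateau thins; membrane damage
# adds volume-neutral, positively skewed (bleb-like) band-limited roughness
# and vacuole dips; and the plateau extent is rescaled isotropically so the
# head's integrated phase (its optical volume) is conserved to a relative
# tolerance of 1e-6. Midpiece and tail are untouched.

#' Phantom configuration
#'
#' Parameters of the synthetic sperm phase object. Lengths are in
#' micrometres, phases in radians. Defaults model a human sperm on a
#' 512 x 512 grid at 0.1 um/pixel: 4.5 x 3 um head with 4 rad peak phase and
#' a 45 um tail.
#'
#' @param n Grid side length in pixels.
#' @param dx,dy Pixel pitch (um/pixel); the PSF model requires `dx == dy`.
#' @param head_a,head_b Head semi-axes along / across the cell axis (um).
#' @param phi_peak Peak phase of the head (rad); reached in the nucleus.
#' @param plateau_height,plateau_exponent Height (rad) and radial exponent of
#'   the acrosomal plateau `h * (1 - rho^2)^g`.
#' @param nucleus_a,nucleus_b,nucleus_frac,nucleus_exponent Nucleus semi-axes
#'   (um), posterior centre offset as a fraction of `head_a`, and bump
#'   exponent.
#' @param mid_length,mid_width,mid_phase Midpiece ridge length, full width
#'   (um) and peak phase (rad).
#' @param tail_length,tail_width,tail_phase Tail arc length, ribbon full
#'   width (um) and phase amplitude (rad).
#' @param tail_wave_amp,tail_wave_periods Amplitude (um) and period count of
#'   the tail's sinusoidal undulation.
#' @param orientation Cell axis angle (rad, anticlockwise from +x).
#' @param psf_sigma Gaussian PSF sigma (um); 0 disables band-limiting.
#' @param stress_kappa Peak-phase flattening coefficient: the head peak
#'   scales by `(1 - stress_kappa * s)`. The default 0.115 reproduces the
#'   ~0.885 control-to-stressed mean-phase ratio reported for 10 uM H2O2.
#' @param stress_plateau Plateau (acrosome) thinning coefficient: plateau
#'   height scales by `(1 - stress_plateau * s)`.
#' @param stress_condense Lateral nucleus condensation coefficient (axes
#'   scale by `1 - stress_condense * s`; 0 by default).
#' @param stress_roughness Membrane roughness amplitude at `s = 1` (rad);
#'   volume-neutral, band-limited, positively skewed (blebs).
#' @param roughness_corr Roughness correlation length (um).
#' @param roughness_skew Log-normal skew of the roughness field (0 =
#'   symmetric Gaussian; positive values make rare upward blebs).
#' @param roughness_env Exponent of the plateau-shaped envelope confining the
#'   roughness to the head (small = nearly uniform over the head).
#' @param roughness_fine,roughness_fine_corr Amplitude (rad at `s = 1`) and
#'   correlation length (um) of a second, symmetric, fine-grained roughness
#'   component: pixel-scale membrane granularity near the resolution limit.
#' @param n_vacuoles,vacuole_depth Number of vacuole dips and their maximum
#'   depth (rad) at `s = 1`; dips never cut below ~half the local height.
#' @param seed Integer seed for the per-phantom roughness/vacuole fields.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n = 512L, dx = 0.1, dy = 0.1,
                           head_a = 2.25, head_b = 1.5, phi_peak = 4.0,
                           plateau_height = 1.2, plateau_exponent = 0.1,
                           nucleus_a = 1.0, nucleus_b = 0.75,
                           nucleus_frac = -0.25, nucleus_exponent = 0.15,
                           mid_length = 4, mid_width = 0.3, mid_phase = 0.9,
                           tail_length = 45, tail_width = 0.35,
                           tail_phase = 0.3, tail_wave_amp = 2.2,
                           tail_wave_periods = 2.25,
                           orientation = pi / 4, psf_sigma = 0.2,
                           stress_kappa = 0.115, stress_plateau = 0.25,
                           stress_condense = 0,
                           stress_roughness = 0.65, roughness_corr = 0.9,
                           roughness_skew = 1.2, roughness_env = 0.1,
                           roughness_fine = 0.45, roughness_fine_corr = 0.3,
                           n_vacuoles = 8L, vacuole_depth = 0.8,
                           seed = 1L) {
  cfg <- as.list(environment())
  neg <- c("phi_peak", "plateau_height", "mid_phase", "tail_phase",
           "stress_roughness")
  for (p in neg) if (cfg[[p]] < 0) stopf("phase parameter '%s' must be nonnegative", p)
  if (cfg$dx != cfg$dy) stopf("phantom construction requires dx == dy")
  if (cfg$phi_peak <= cfg$plateau_height) {
    stopf("phi_peak (%.3g) must exceed plateau_height (%.3g)", cfg$phi_peak,
          cfg$plateau_height)
  }
  structure(cfg, class = "phantom_config")
}

# Discrete PSF kernel matching gaussian_blur() (frequency-domain Gaussian),
# truncated far into its tails; used for single-point convolution values.
.psf_kernel <- function(sigma_px) {
  m <- 64L
  fr <- centered_freqs(m)
  H <- ifftshift(outer(exp(-2 * pi^2 * sigma_px^2 * fr^2),
                       exp(-2 * pi^2 * sigma_px^2 * fr^2)))
  k <- fftshift(Re(ifft2(H)))  # spatial kernel, centred
  half <- min(16L, ceiling(8 * sigma_px))
  ctr <- m / 2 + 1L
  k[(ctr - half):(ctr + half), (ctr - half):(ctr + half)]
}

# Solve the tail chord length so the undulating centreline has the requested
# arc length, then return sampled centreline points in cell coordinates.
.solve_tail <- function(cfg) {
  A <- cfg$tail_wave_amp; k <- cfg$tail_wave_periods
  tt <- seq(0, 1, length.out = 2001L)
  arc_len <- function(Lc) {
    sp <- sqrt(Lc^2 + (A * 2 * pi * k * cos(2 * pi * k * tt))^2)
    sum((sp[-1] + sp[-length(sp)]) / 2) * diff(tt[1:2])
  }
  f <- function(Lc) arc_len(Lc) - cfg$tail_length
  if (f(cfg$tail_length) < 0) stopf("tail undulation shortens the arc; invalid tail parameters")
  Lc <- uniroot(f, c(1e-3, cfg$tail_length), tol = 1e-10)$root
  u_start <- -(cfg$head_a + cfg$mid_length) + 0.2
  n_s <- max(200L, ceiling(cfg$tail_length / 0.05))
  t_s <- seq(0, 1, length.out = n_s)
  u_s <- u_start - t_s * Lc
  v_s <- A * sin(2 * pi * k * t_s)
  measured <- sum(sqrt(diff(u_s)^2 + diff(v_s)^2))
  list(u = u_s, v = v_s, t = t_s, chord = Lc, measured_length = measured,
       u_min = min(u_s) )
}

# Stamp a ribbon profile along sampled centreline points (grid-space maxima).
.stamp_ribbon <- function(field, px_x, px_y, height, half_width_px) {
  n <- nrow(field)
  r <- ceiling(half_width_px) + 2L
  off <- seq(-r, r)
  for (i in seq_along(px_x)) {
    cx <- px_x[i]; cy <- px_y[i]
    jj <- round(cx) + off; ii <- round(cy) + off
    jok <- jj >= 1L & jj <= n; iok <- ii >= 1L & ii <= n
    if (!any(jok) || !any(iok)) next
    jj <- jj[jok]; ii <- ii[iok]
    d2 <- outer((ii - cy)^2, (jj - cx)^2, "+") / half_width_px^2
    prof <- height[i] * pmax(1 - d2, 0)
    field[ii, jj] <- pmax(field[ii, jj], prof)
  }
  field
}

# Core builder shared by make_phantom() and stress_transform().
.build_phantom <- function(cfg, s = 0, v_target = NULL) {
  n <- cfg$n; dx <- cfg$dx
  half_fov <- n * dx / 2

  tail <- .solve_tail(cfg)
  u_max <- 1.35 * cfg$head_a            # headroom for stress-driven growth
  u_min <- tail$u_min - 1
  off_u <- (u_min + u_max) / 2          # cell centre in local u
  v_ext <- max(1.35 * cfg$head_b, cfg$tail_wave_amp + 1)

  # rotated bounding box against the field of view
  th <- cfg$orientation
  corners_u <- c(u_min, u_min, u_max, u_max) - off_u
  corners_v <- c(-v_ext, v_ext, -v_ext, v_ext)
  bx <- max(abs(cos(th) * corners_u - sin(th) * corners_v))
  by <- max(abs(sin(th) * corners_u + cos(th) * corners_v))
  if (bx > half_fov) stopf("phantom x extent %.1f um exceeds half field of view %.1f um", bx, half_fov)
  if (by > half_fov) stopf("phantom y extent %.1f um exceeds half field of view %.1f um", by, half_fov)

  ctr <- (n + 1) / 2
  gx <- (seq_len(n) - ctr) * dx
  gy <- (seq_len(n) - ctr) * cfg$dy
  GX <- matrix(gx, n, n, byrow = TRUE)
  GY <- matrix(gy, n, n)
  U <- cos(th) * GX + sin(th) * GY + off_u
  V <- -sin(th) * GX + cos(th) * GY

  # --- head window (all lambda-dependent work happens here) ---------------
  head_c_gx <- cos(th) * (0 - off_u); head_c_gy <- sin(th) * (0 - off_u)
  hc_col <- head_c_gx / dx + ctr; hc_row <- head_c_gy / dx + ctr
  wr <- ceiling((1.6 * cfg$head_a + 1.5) / dx)
  rows <- max(1L, round(hc_row) - wr):min(n, round(hc_row) + wr)
  cols <- max(1L, round(hc_col) - wr):min(n, round(hc_col) + wr)
  Uw <- U[rows, cols]; Vw <- V[rows, cols]

  sigma_px <- cfg$psf_sigma / dx

  h_pl <- cfg$plateau_height * (1 - cfg$stress_plateau * s)
  plateau_w <- function(lambda) {
    rho2 <- (Uw / (lambda * cfg$head_a))^2 + (Vw / (lambda * cfg$head_b))^2
    h_pl * pmax(1 - rho2, 0)^cfg$plateau_exponent
  }

  # nucleus shape (unit height), lateral condensation with stress
  na <- cfg$nucleus_a * (1 - cfg$stress_condense * s)
  nb <- cfg$nucleus_b * (1 - cfg$stress_condense * s)
  un <- cfg$nucleus_frac * cfg$head_a
  rhoN2_w <- ((Uw - un) / na)^2 + (Vw / nb)^2
  Nw <- pmax(1 - rhoN2_w, 0)^cfg$nucleus_exponent
  sum_N <- sum(Nw)

  # band-limited roughness, fixed in grid space (independent of lambda):
  # a coarse positively-skewed (bleb) component plus fine-grained symmetric
  # granularity near the resolution limit
  rough_w <- 0
  if (s > 0 && (cfg$stress_roughness > 0 || cfg$roughness_fine > 0)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(derive_seed(cfg$seed, 77L))
    wn1 <- matrix(rnorm(length(Uw)), nrow(Uw), ncol(Uw))
    wn2 <- matrix(rnorm(length(Uw)), nrow(Uw), ncol(Uw))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    rf <- gaussian_blur(wn1, cfg$roughness_corr / dx)
    rf <- (rf - mean(rf)) / sd(rf)
    if (cfg$roughness_skew > 0) {
      rf <- exp(cfg$roughness_skew * rf)
      rf <- (rf - mean(rf)) / sd(rf)
      rf <- pmin(rf, 2.5)  # cap blebs so they can never rival the nucleus peak
    }
    rough_w <- cfg$stress_roughness * s * rf
    if (cfg$roughness_fine > 0) {
      ff <- gaussian_blur(wn2, cfg$roughness_fine_corr / dx)
      ff <- (ff - mean(ff)) / sd(ff)
      rough_w <- rough_w + cfg$roughness_fine * s * ff
    }
  }

  # vacuoles: membrane/chromatin defects of the stressed head, modelled as
  # round dips in the plateau whose depth grows with s; positions are fixed
  # fractions of the (lambda-scaled) head ellipse so they track the head
  vac_par <- NULL
  if (s > 0 && cfg$n_vacuoles > 0 && cfg$vacuole_depth > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(derive_seed(cfg$seed, 101L))
    nv <- cfg$n_vacuoles
    fu <- runif(20L * nv, -0.8, 0.8); fv <- runif(20L * nv, -0.8, 0.8)
    keep <- which(fu^2 + fv^2 < 0.7^2)[seq_len(nv)]
    vac_par <- list(fu = fu[keep], fv = fv[keep],
                    depth = cfg$vacuole_depth * runif(nv, 0.6, 1),
                    rad = runif(nv, 0.35, 0.5))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  head_unblurred <- function(lambda) {
    P <- plateau_w(lambda)
    if (is.matrix(rough_w)) {
      env <- (P / h_pl)^cfg$roughness_env
      # volume-neutral and smooth in lambda: subtract the envelope-weighted
      # mean so the roughness adds no net phase volume
      cshift <- sum(rough_w * env) / max(sum(env), 1e-12)
      P <- pmax(P + (rough_w - cshift) * env, 0)
    }
    if (!is.null(vac_par)) {
      for (vi in seq_along(vac_par$fu)) {
        du <- Uw - vac_par$fu[vi] * lambda * cfg$head_a
        dv <- Vw - vac_par$fv[vi] * lambda * cfg$head_b
        d2 <- (du^2 + dv^2) / vac_par$rad[vi]^2
        dip <- s * vac_par$depth[vi] * pmax(1 - d2, 0)
        P <- P - pmin(dip, 0.45 * P)  # dips never cut below ~half the local height
      }
    }
    P
  }

  # candidate pixels for the field maximum: around the nucleus peak
  kN <- arrayInd(which.max(Nw), dim(Nw))[1, ]
  ci <- (kN[1] - 8L):(kN[1] + 8L); cj <- (kN[2] - 8L):(kN[2] + 8L)
  ci <- ci[ci >= 1 & ci <= nrow(Uw)]; cj <- cj[cj >= 1 & cj <= ncol(Uw)]
  K <- if (sigma_px > 0) .psf_kernel(sigma_px) else matrix(1, 1, 1)
  kh <- (nrow(K) - 1L) / 2L
  point_blur <- function(M, ii, jj) {
    # value of (M * K)(ii, jj); M is the head window, zero outside
    r0 <- ii - kh; r1 <- ii + kh; c0 <- jj - kh; c1 <- jj + kh
    rr <- max(1L, r0):min(nrow(M), r1); cc <- max(1L, c0):min(ncol(M), c1)
    sum(M[rr, cc] * K[rr - r0 + 1L, cc - c0 + 1L])
  }
  Nb_cand <- outer(ci, cj, Vectorize(function(i, j) point_blur(Nw, i, j)))

  target <- cfg$phi_peak * (1 - cfg$stress_kappa * s)

  # beta so that max(base + beta * N) = target; max(.) is nondecreasing and
  # piecewise linear in beta, so bisection after an expanding bracket is
  # robust (Newton on the active piece can jump to a low-N pixel and
  # diverge)
  solve_max_beta <- function(base, Nb) {
    if (max(base) >= target) {
      stopf("stress deformation exceeds the target peak phase (%.2f rad); reduce roughness/bleb amplitudes", target)
    }
    m <- function(b) max(base + b * Nb)
    hi <- (target - max(base)) / max(Nb)
    while (m(hi) < target) hi <- hi * 2
    lo <- 0
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (m(mid) < target) lo <- mid else hi <- mid
      if (hi - lo < 1e-14 * max(1, hi)) break
    }
    hi
  }
  solve_beta <- function(base_cand) solve_max_beta(base_cand, Nb_cand)

  head_volume <- function(lambda) {
    P <- head_unblurred(lambda)
    base_cand <- outer(ci, cj, Vectorize(function(i, j) point_blur(P, i, j)))
    beta <- solve_beta(base_cand)
    list(v = (sum(P) + beta * sum_N) * dx * cfg$dy, beta = beta, P = P)
  }

  if (is.null(v_target)) {
    lambda <- 1
    hv <- head_volume(1)
  } else {
    g <- function(l) head_volume(l)$v - v_target
    lambda <- uniroot(g, c(0.8, 1.9), tol = 1e-11)$root
    hv <- head_volume(lambda)
  }

  # --- full-grid composition ----------------------------------------------
  nuc_field <- matrix(0, n, n)
  nuc_field[rows, cols] <- Nw

  body <- matrix(0, n, n)
  if (cfg$mid_phase > 0 && cfg$mid_length > 0) {
    u0 <- -cfg$head_a + 0.3; u1 <- -(cfg$head_a + cfg$mid_length)
    hw <- cfg$mid_width / 2
    inmid <- U <= u0 & U >= u1 & abs(V) < hw
    hgt <- cfg$mid_phase + (cfg$tail_phase - cfg$mid_phase) *
      (u0 - U[inmid]) / (u0 - u1)
    body[inmid] <- pmax(body[inmid], hgt * (1 - (V[inmid] / hw)^2))
  }
  if (cfg$tail_phase > 0) {
    tg_x <- cos(th) * (tail$u - off_u) - sin(th) * tail$v
    tg_y <- sin(th) * (tail$u - off_u) + cos(th) * tail$v
    px_x <- tg_x / dx + ctr; px_y <- tg_y / cfg$dy + ctr
    taper <- ifelse(tail$t > 0.85, (1 - tail$t) / 0.15, 1)
    body <- .stamp_ribbon(body, px_x, px_y, cfg$tail_phase * taper,
                          (cfg$tail_width / 2) / dx)
  }

  # Exact peak normalisation on the final full-grid field. The lateral
  # scale from the windowed root solve sets the geometry to ~1e-4; the
  # discrete plateau sum is not smooth enough in lambda for 1e-6, so the
  # last step trims the plateau height by a factor eta (~1 +/- 5e-4), in
  # which the volume is exactly linear.
  Nb_full <- if (sigma_px > 0) gaussian_blur(nuc_field, sigma_px) else nuc_field
  body_blur <- if (sigma_px > 0) gaussian_blur(body, sigma_px) else body
  refine_beta <- function(base_full, beta0) solve_max_beta(base_full, Nb_full)
  P <- hv$P
  head_field <- matrix(0, n, n)
  head_field[rows, cols] <- P
  head_blur <- if (sigma_px > 0) gaussian_blur(head_field, sigma_px) else head_field
  eta <- 1
  beta <- hv$beta
  for (pass in 1:8) {
    base_full <- eta * head_blur + body_blur
    beta <- refine_beta(base_full, beta)
    if (is.null(v_target)) break
    v_now <- (eta * sum(P) + beta * sum_N) * dx * cfg$dy
    if (abs(v_now / v_target - 1) < 1e-9) break
    eta <- (v_target / (dx * cfg$dy) - beta * sum_N) / sum(P)
  }
  field <- pmax(base_full + beta * Nb_full, 0)

  # ground-truth head support: the geometric ellipse plus the PSF halo (the
  # band-limited phase field genuinely extends beyond the geometric edge)
  halo <- cfg$psf_sigma / 2
  mask <- matrix(FALSE, n, n)
  rho2_full <- (U / (lambda * cfg$head_a + halo))^2 +
    (V / (lambda * cfg$head_b + halo))^2
  mask[rho2_full < 1] <- TRUE

  v_head <- (eta * sum(P) + beta * sum_N) * dx * cfg$dy

  structure(
    list(
      data = field, config = cfg, s = s, lambda = lambda,
      head_mask = mask, seed = cfg$seed,
      tail_length_measured = tail$measured_length,
      truth = list(
        max_phase = target,
        head_phase_volume = v_head,                       # rad * um^2
        head_area = pi * lambda^2 * cfg$head_a * cfg$head_b,  # um^2
        nucleus_height = beta,
        tail_chord = tail$chord
      )
    ),
    class = "sperm_phantom"
  )
}

#' Generate a sperm phase phantom
#'
#' Builds the ground-truth phase field and head mask for one synthetic sperm
#' cell at stress level 0. See [phantom_config()] for the geometry and
#' [stress_transform()] for the oxidative-stress deformation.
#'
#' @param config A [phantom_config()].
#' @return An object of class `sperm_phantom` with elements `data` (phase
#'   matrix, rad), `head_mask` (logical matrix), `truth` (stored ground-truth
#'   features), `tail_length_measured`, `lambda`, `s` and `config`.
#' @examples
#' ph <- make_phantom(phantom_config(n = 256L, tail_length = 20))
#' max(ph$data)  # 4 rad by default
#' @export
make_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) stopf("config must be a phantom_config()")
  .build_phantom(config, s = 0)
}

#' Apply the oxidative-stress deformation
#'
#' Deforms a control phantom to stress level `s`: the head peak phase scales
#' by `(1 - kappa * s)`, the nucleus condenses laterally, membrane roughness
#' proportional to `s` is added, and the head's lateral extent is rescaled
#' isotropically so its integrated phase (optical volume) is conserved to a
#' relative tolerance of 1e-6. Midpiece and tail are unchanged.
#'
#' @param phantom A `sperm_phantom` (its stored stress level must be 0).
#' @param s Stress level in `[0, 1]`.
#' @return A deformed `sperm_phantom`.
#' @export
stress_transform <- function(phantom, s) {
  if (!inherits(phantom, "sperm_phantom")) stopf("phantom must be a sperm_phantom")
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
    stopf("stress level s must be a single value in [0, 1]")
  }
  if (s == 0) return(phantom)
  base <- if (phantom$s == 0) phantom else .build_phantom(phantom$config, 0)
  .build_phantom(phantom$config, s = s, v_target = base$truth$head_phase_volume)
}

#' @export
print.sperm_phantom <- function(x, ...) {
  cat(sprintf("<sperm_phantom> %d x %d px, s = %.2f, peak = %.3f rad, head area = %.2f um^2\n",
              nrow(x$data), ncol(x$data), x$s, x$truth$max_phase, x$truth$head_area))
  cat(sprintf("  tail arc %.2f um (configured %.2f)\n",
              x$tail_length_measured, x$config$tail_length))
  invisible(x)
}

#' @rdname autoplot.phase_map
#' @export
autoplot.sperm_phantom <- function(object, ...) {
  pm <- phase_map(object$data, dx = object$config$dx, dy = object$config$dy)
  autoplot(pm, ...)
}
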