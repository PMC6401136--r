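# Deterministic fixture set used by the test suite and the documentation
# examples: analytic fields with known closed forms plus a few small
# phantoms. Everything is generated in code; checksums make regeneration
# verifiable.

#' Hemisphere optical-thickness fixture
#'
#' A discretized hemisphere height field `z = sqrt(r^2 - x^2 - y^2)` as an
#' OT map (nm). Closed forms: volume `(2/3)*pi*r^3`, cap surface area
#' `2*pi*r^2` (plus projected `pi*r^2` under the surface-area convention
#' used here).
#'
#' @param r Radius in um.
#' @param dx Pixel pitch (um/pixel).
#' @param pad Background margin in pixels.
#' @return List with `ot` ([ot_map()] in nm), `mask` (logical), and the
#'   analytic `V` (um^3) and `S` (um^2).
#' @export
hemisphere_fixture <- function(r = 5, dx = 0.1, pad = 10L) {
  half <- ceiling(r / dx) + pad
  n <- 2L * half + 1L
  g <- (seq_len(n) - half - 1L) * dx
  R2 <- outer(g^2, g^2, "+")
  z <- sqrt(pmax(r^2 - R2, 0))            # um
  list(ot = ot_map(z * 1000, dx = dx, dy = dx), mask = R2 < r^2,
       V = 2 / 3 * pi * r^3, S = 3 * pi * r^2)
}

#' Write the standard fixture set
#'
#' Writes a small deterministic dataset: the hemisphere OT field with its
#' analytic values, a wrapped planar phase ramp, a two-level checkerboard
#' ROI, and 3 phantoms x 2 classes rendered to holograms; records MD5
#' checksums of every file in `checksums.json`.
#'
#' @param dir Output directory.
#' @param seed Base seed.
#' @return Named list of file checksums, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hemi <- hemisphere_fixture()
  write_ot_map(hemi$ot, file.path(dir, "hemisphere_ot.tif"))
  jsonlite::write_json(list(V_um3 = hemi$V, S_um2 = hemi$S, r_um = 5),
                       file.path(dir, "hemisphere_analytic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  n <- 128L
  ramp <- matrix(seq(0, 6 * pi, length.out = n), n, n, byrow = TRUE)
  write_phase_map(phase_map(wrap_to_pi(ramp), wrapped = TRUE),
                  file.path(dir, "ramp_wrapped.tif"))

  cb <- matrix(rep_len(c(0L, 1L), 16L * 16L), 16L, 16L)
  readr::write_csv(tibble::as_tibble(cb, .name_repair = "minimal"),
                   file.path(dir, "checkerboard.csv"))

  cfg <- phantom_config(n = 256L, tail_length = 18, tail_wave_amp = 1.5)
  generate_dataset(file.path(dir, "cells"), n_per_class = 3L,
                   class_defs = list(list(label = 0, s = 0),
                                     list(label = 1, s = 1)),
                   base_seed = seed, config = cfg, overwrite = TRUE)

  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "checksums.json"]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", dir), "/?"),
                     "", names(sums))
  jsonlite::write_json(as.list(sums), file.path(dir, "checksums.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(as.list(sums))
}
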