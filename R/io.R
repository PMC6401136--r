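# File interfaces: holograms as 16-bit grayscale TIFF, phase/OT maps as
# 32-bit float TIFF, each with a JSON metadata sidecar (<file>.json). TIFF
# sample values are stored normalized to [0, 1]; the sidecar records the
# offset/scale needed to restore physical units (a lossless affine map at
# float-32 precision), plus wavelength, pixel pitch and geometry.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a hologram (16-bit TIFF + JSON sidecar)
#'
#' @param holo A [hologram()].
#' @param path Output TIFF path.
#' @return `path`, invisibly. `read_hologram()` returns a [hologram()].
#' @export
write_hologram <- function(holo, path) {
  scale <- max(holo$data, 1e-12)
  tiff::writeTIFF(holo$data / scale, path, bits.per.sample = 16L)
  meta <- list(kind = "hologram", scale = scale,
               wavelength_nm = holo$wavelength_nm, dx_um = holo$dx,
               dy_um = holo$dy, geometry = holo$geometry, meta = holo$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale
  hologram(m, wavelength_nm = meta$wavelength_nm, dx = meta$dx_um,
           dy = meta$dy_um, geometry = meta$geometry,
           meta = as.list(meta$meta))
}

.write_float_field <- function(data, path, meta) {
  off <- min(data)
  scale <- max(data) - off
  if (scale == 0) scale <- 1
  tiff::writeTIFF((data - off) / scale, path, bits.per.sample = 32L)
  meta$offset <- off
  meta$scale <- scale
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.read_float_field <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  list(data = tiff::readTIFF(path) * meta$scale + meta$offset, meta = meta)
}

#' Write / read a phase map (32-bit float TIFF + JSON sidecar)
#' @param phase A [phase_map()].
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_phase_map()` returns a [phase_map()].
#' @export
write_phase_map <- function(phase, path) {
  .write_float_field(phase$data, path,
                     list(kind = "phase_map", units = "rad",
                          wavelength_nm = phase$wavelength_nm,
                          dx_um = phase$dx, dy_um = phase$dy,
                          geometry = phase$geometry, wrapped = phase$wrapped,
                          background_corrected = phase$background_corrected))
}

#' @rdname write_phase_map
#' @export
read_phase_map <- function(path) {
  f <- .read_float_field(path)
  phase_map(f$data, wavelength_nm = f$meta$wavelength_nm, dx = f$meta$dx_um,
            dy = f$meta$dy_um, geometry = f$meta$geometry,
            wrapped = f$meta$wrapped,
            background_corrected = f$meta$background_corrected)
}

#' Write / read an optical-thickness map (32-bit float TIFF + JSON sidecar)
#' @param ot An [ot_map()].
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_ot_map()` returns an [ot_map()].
#' @export
write_ot_map <- function(ot, path) {
  .write_float_field(ot$data, path,
                     list(kind = "ot_map", units = ot$units,
                          dx_um = ot$dx, dy_um = ot$dy))
}

#' @rdname write_ot_map
#' @export
read_ot_map <- function(path) {
  f <- .read_float_field(path)
  ot_map(f$data, dx = f$meta$dx_um, dy = f$meta$dy_um, units = f$meta$units)
}
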