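# Plain-text / TIFF interchange for the analysis inputs.

#' Read / write I-V recordings as CSV
#'
#' Columns `voltage_mV`, `current_pA`; the junction offset travels in a
#' `junction_offset_mV` column (constant).
#'
#' @param iv an [iv_recording].
#' @param path file path.
#' @return `read_iv_csv` returns an [iv_recording].
#' @export
write_iv_csv <- function(iv, path) {
  stopifnot(inherits(iv, "iv_recording"))
  utils::write.csv(data.frame(voltage_mV = iv$voltage,
                              current_pA = iv$current,
                              junction_offset_mV =
                                attr(iv, "junction_offset")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  d <- utils::read.csv(path)
  iv_recording(d$voltage_mV, d$current_pA,
               junction_offset = d$junction_offset_mV[1])
}

#' Read / write particle sets as CSV
#'
#' Columns `x_nm`, `y_nm`, `lamina`, `cutoff_nm`.
#'
#' @param particles a [particle_set].
#' @param path file path.
#' @return `read_particles_csv` returns a [particle_set].
#' @export
write_particles_csv <- function(particles, path) {
  stopifnot(inherits(particles, "particle_set"))
  utils::write.csv(data.frame(x_nm = particles$coords[, 1],
                              y_nm = particles$coords[, 2],
                              lamina = particles$lamina,
                              cutoff_nm = particles$cutoff),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles_csv
#' @export
read_particles_csv <- function(path) {
  d <- utils::read.csv(path)
  particle_set(cbind(d$x_nm, d$y_nm), lamina = d$lamina[1],
               cutoff = d$cutoff_nm[1])
}

#' Read / write a laminar image as TIFF channels with a JSON sidecar
#'
#' Each channel is written as a 32-bit float TIFF next to a JSON sidecar
#' carrying the pixel size and channel names. Annotations (masks,
#' polylines) are in-memory objects and are not serialized.
#'
#' @param image a `laminar_image` (see [gen_laminar_image]).
#' @param prefix path prefix; files become `<prefix>_<channel>.tif` and
#'   `<prefix>.json`.
#' @return `read_laminar_tiff` returns a `laminar_image` (without
#'   annotations).
#' @export
write_laminar_tiff <- function(image, prefix) {
  stopifnot(inherits(image, "laminar_image"))
  for (nm in names(image$channels))
    tiff::writeTIFF(image$channels[[nm]] / 4096,
                    paste0(prefix, "_", nm, ".tif"),
                    bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size,
                            channels = names(image$channels),
                            intensity_scale = 4096),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_laminar_tiff
#' @export
read_laminar_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ch <- lapply(meta$channels, function(nm)
    tiff::readTIFF(paste0(prefix, "_", nm, ".tif")) * meta$intensity_scale)
  names(ch) <- meta$channels
  structure(list(channels = ch, pixel_size = meta$pixel_size_um,
                 annotations = NULL), class = "laminar_image")
}
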