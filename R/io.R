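# Standard-format I/O. Physical units are carried in column/field names
# (_um, _nm, _px); readers refuse to guess a missing pixel size.

#' Write / read a pixel image as TIFF
#'
#' Images are written as 32-bit TIFF, linearly rescaled to [0, 1]; the pixel
#' size (um) and the intensity scaling are stored in a JSON sidecar
#' `<file>.json` so values and geometry round-trip (to 32-bit float
#' precision). `read_image()` errors when no pixel size is available from the
#' sidecar or the `pixel_size` argument.
#'
#' @param image a `pixel_image`.
#' @param path output TIFF path.
#' @return `write_image` returns `path` invisibly; `read_image` returns a
#'   `pixel_image`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "pixel_image"))
  rng <- range(image$data)
  scl <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((image$data - rng[1]) / scl, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size,
                            intensity_offset = rng[1], intensity_scale = scl),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size pixel size in um, overriding the sidecar.
#' @export
read_image <- function(path, pixel_size = NULL) {
  m <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  if (!is.null(meta))
    m <- m * meta$intensity_scale + meta$intensity_offset
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  if (is.null(pixel_size))
    stop("pixel size metadata missing: supply `pixel_size` (um)")
  pixel_image(m, pixel_size)
}

loc_columns <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons",
                 "uncertainty_nm")

#' Write / read a localization table as CSV
#'
#' The fixed header `frame, x_nm, y_nm, sigma_nm, photons, uncertainty_nm`
#' comes first; any extra columns are preserved after it.
#'
#' @param table a localization table.
#' @param path CSV path.
#' @return `write_localizations` returns `path` invisibly;
#'   `read_localizations` returns the table.
#' @export
write_localizations <- function(table, path) {
  stopifnot(all(loc_columns %in% names(table)))
  extra <- setdiff(names(table), loc_columns)
  utils::write.csv(table[, c(loc_columns, extra), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(loc_columns %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(loc_columns, names(tab)), collapse = ", "))
  tab
}

#' Write / read a drift trace as CSV
#' @param trace a `drift_trace` (from [drift_correct()]).
#' @param path CSV path.
#' @export
write_drift_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drift_trace
#' @export
read_drift_trace <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("drift_trace", "data.frame")
  tr
}

#' Write / read an MSI cube as a plain-text array bundle
#'
#' The bundle is a directory with `intensity.csv` (pixels in row-major order
#' by rows, one spectrum per line), `mz.csv`, and `meta.json` (grid
#' dimensions, pixel size, mask, metadata) -- a text equivalent of a
#' continuous-mode datacube.
#'
#' @param cube an `msi_cube`.
#' @param dir bundle directory (created if needed).
#' @export
write_msi <- function(cube, dir) {
  stopifnot(inherits(cube, "msi_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$intensity)
  mat <- matrix(cube$intensity, d[1] * d[2], d[3])  # pixel-major spectra
  utils::write.table(mat, file.path(dir, "intensity.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(mz = cube$mz), file.path(dir, "mz.csv"),
                     sep = ",", row.names = FALSE)
  jsonlite::write_json(list(dims = d[1:2], pixel_size_um = cube$pixel_size_um,
                            mask = as.vector(cube$mask),
                            normalized = cube$normalized,
                            metadata = cube$metadata),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_msi
#' @export
read_msi <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mz <- utils::read.csv(file.path(dir, "mz.csv"))$mz
  mat <- as.matrix(utils::read.table(file.path(dir, "intensity.csv"),
                                     sep = ","))
  dims <- as.integer(meta$dims)
  cube <- msi_cube(array(mat, c(dims, length(mz))), mz,
                   pixel_size_um = meta$pixel_size_um,
                   metadata = as.list(meta$metadata),
                   mask = matrix(meta$mask, dims[1], dims[2]))
  cube$normalized <- isTRUE(meta$normalized)
  cube
}

#' Save a rigid transform as JSON
#' @param tf a [rigid_transform()].
#' @param path JSON path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(unclass(tf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$theta_deg, x$tx_um, x$ty_um, x$scale, x$center_um)
}
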