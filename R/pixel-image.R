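#' Pixel image with physical pixel size
#'
#' The basic image container used throughout the package: a numeric matrix of
#' intensities together with the physical size of one pixel in micrometers.
#' Rows run along the image y axis, columns along x. The physical coordinate
#' system has its origin at the top-left corner of the top-left pixel, so a
#' position `p` (in um) falls into 0-based pixel index `floor(p / pixel_size)`
#' and the center of 0-based pixel `i` is at `(i + 0.5) * pixel_size`.
#'
#' @param data numeric matrix (rows = y, columns = x) or 3D array
#'   (rows, cols, channels) of intensities.
#' @param pixel_size physical edge length of one pixel, in micrometers.
#' @param channels optional character vector of channel names for 3D data.
#' @return an object of class `pixel_image`.
#' @export
pixel_image <- function(data, pixel_size, channels = NULL) {
  if (!is.numeric(data) || !(length(dim(data)) %in% c(2L, 3L)))
    stop("`data` must be a numeric matrix or 3D array")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um)")
  x <- list(data = data, pixel_size = as.numeric(pixel_size))
  if (length(dim(data)) == 3L) {
    if (is.null(channels)) channels <- dimnames(data)[[3]]
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[3]))
    x$channels <- channels
  }
  class(x) <- "pixel_image"
  x
}

#' @export
dim.pixel_image <- function(x) dim(x$data)

#' @export
print.pixel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pixel_image> %d x %d px%s, %.4g um/px (%.4g x %.4g um)\n",
              d[1], d[2],
              if (length(d) == 3L) sprintf(" x %d channels", d[3]) else "",
              x$pixel_size, d[1] * x$pixel_size, d[2] * x$pixel_size))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.pixel_image <- function(x, channel = 1L, ...) {
  m <- if (length(dim(x$data)) == 3L) x$data[, , channel] else x$data
  # transpose/flip so the displayed orientation matches matrix indexing
  graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                  asp = nrow(m) / ncol(m), axes = FALSE, ...)
  invisible(x)
}

#' Extract one channel of a multichannel image
#' @param x a `pixel_image`.
#' @param channel channel index or name.
#' @return a single-channel `pixel_image`.
#' @export
get_channel <- function(x, channel) {
  stopifnot(inherits(x, "pixel_image"))
  if (length(dim(x$data)) == 2L) return(x)
  if (is.character(channel)) channel <- match(channel, x$channels)
  pixel_image(x$data[, , channel], x$pixel_size)
}

# pixel centers along one axis, in um (n pixels)
pixel_centers <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

#' Bilinear interpolation of image intensities at physical positions
#'
#' Samples a 2D `pixel_image` at arbitrary physical coordinates using
#' bilinear interpolation between pixel centers. Positions outside the image
#' return `fill`.
#'
#' @param image a 2D `pixel_image`.
#' @param x,y physical coordinates in um (x = column direction,
#'   y = row direction).
#' @param fill value returned outside the image support.
#' @return numeric vector of interpolated intensities.
#' @export
interp_bilinear <- function(image, x, y, fill = NA_real_) {
  stopifnot(inherits(image, "pixel_image"))
  m <- image$data
  px <- image$pixel_size
  # continuous pixel coordinates where integer k means center of row/col k (1-based)
  cx <- x / px + 0.5
  cy <- y / px + 0.5
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0;   fy <- cy - i0
  nr <- nrow(m); nc <- ncol(m)
  # clamp neighbours to the border so positions within the outer half-pixel
  # band are still defined
  j0c <- pmin(pmax(j0, 1L), nc); j1c <- pmin(pmax(j0 + 1, 1L), nc)
  i0c <- pmin(pmax(i0, 1L), nr); i1c <- pmin(pmax(i0 + 1, 1L), nr)
  v <- (1 - fx) * (1 - fy) * m[cbind(i0c, j0c)] +
       fx       * (1 - fy) * m[cbind(i0c, j1c)] +
       (1 - fx) * fy       * m[cbind(i1c, j0c)] +
       fx       * fy       * m[cbind(i1c, j1c)]
  outside <- x < 0 | y < 0 | x > nc * px | y > nr * px
  v[outside] <- fill
  v
}

# full width at half maximum of a Gaussian with standard deviation sigma
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert a Gaussian standard deviation to FWHM (and back)
#'
#' For a Gaussian profile the full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param sigma Gaussian standard deviation.
#' @return the FWHM in the same units.
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' @rdname sigma_to_fwhm
#' @param fwhm full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

#' Derive a reproducible child seed for a named pipeline stage
#'
#' Fans a single global seed out to per-stage seeds by stable string hashing,
#' so that adding or reordering stages does not shift the random streams of
#' the others.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}
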