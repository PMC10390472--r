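#' Synthetic fibrillar-network phantom
#'
#' Generates the geometry of a collagen-like fiber network with known ground
#' truth: a list of straight fiber segments with Gaussian cross-section
#' `sigma_nm`, laid out so that the gaps between fibers measured along image
#' rows and columns follow an exponential distribution with rate `gap_rate`
#' (per um) -- the generative model underlying characteristic pore-size
#' estimation.
#'
#' The construction divides the field into horizontal bands, each filled with
#' two families of diagonal fiber segments (+45 and -45 degrees) spanning the
#' band, whose intercepts form independent Poisson processes of rate
#' `gap_rate`/2 each. Diagonal segments cross every image row of their band
#' exactly once and image columns at the same rate, so fiber crossings along
#' any row or column form a Poisson process of rate `gap_rate`; by
#' memorylessness, the gap from the end of any fiber run to the next fiber is
#' then exactly Exp(`gap_rate`) along both scan directions, and the two
#' families slide against each other from row to row, decorrelating transects
#' within a band. The "on" extent of a fiber is the region within FWHM/2 of
#' its centerline (where rendered intensity exceeds half the peak); along a
#' row or column the corresponding footprint of a diagonal fiber is
#' `sqrt(2) * FWHM`.
#'
#' Alternatively an explicit `fibers` data frame can be supplied (columns
#' `x0, y0, x1, y1` in um, optional `sigma_nm`, `amplitude`), bypassing the
#' random layout; this is how deterministic single-fiber phantoms for
#' width-morphometry tests are built.
#'
#' @param field_um field size `c(width, height)` in um.
#' @param pixel_size um per pixel of images rendered from this phantom.
#' @param gap_rate rate of the exponential inter-fiber gap law, per um
#'   (characteristic pore size = 1/`gap_rate`).
#' @param sigma_nm true Gaussian cross-section standard deviation of the
#'   fibers, in nm. The default 150 nm gives fibers rendered at roughly the
#'   width a diffraction-limited microscope reports for sub-resolution
#'   collagen fibers.
#' @param amplitude peak fiber intensity (arbitrary units).
#' @param band_um band height (= diagonal segment extent) of the layout
#'   construction, in um.
#' @param fibers optional explicit segment table (see Details).
#' @param seed integer seed; the same seed reproduces the identical phantom.
#' @return an object of class `fiber_phantom`: list with `fibers` (segment
#'   data frame), `field_um`, `pixel_size`, `gap_rate`, `sigma_nm`, `seed`,
#'   and `gaps_true`: the gap sample measured geometrically along one
#'   reference row per band (iid Exp(`gap_rate`) draws).
#' @export
fiber_network_phantom <- function(field_um = c(204.8, 204.8),
                                  pixel_size = 0.1,
                                  gap_rate = 1 / 3,
                                  sigma_nm = 150,
                                  amplitude = 1,
                                  band_um = 5,
                                  fibers = NULL,
                                  seed = 1L) {
  stopifnot(length(field_um) == 2L, all(field_um > 0), pixel_size > 0,
            sigma_nm > 0)
  W <- field_um[1]; H <- field_um[2]

  if (!is.null(fibers)) {
    fibers <- as.data.frame(fibers)
    stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(fibers)))
    if (is.null(fibers$sigma_nm)) fibers$sigma_nm <- rep(sigma_nm, nrow(fibers))
    if (is.null(fibers$amplitude)) fibers$amplitude <- rep(amplitude, nrow(fibers))
    out <- list(fibers = fibers, field_um = field_um,
                pixel_size = pixel_size, gap_rate = gap_rate,
                sigma_nm = sigma_nm, seed = seed, gaps_true = numeric(0))
    class(out) <- "fiber_phantom"
    return(out)
  }

  stopifnot(gap_rate > 0, band_um > 0)
  set.seed(seed)
  w <- sigma_to_fwhm(sigma_nm) / 1000   # on-structure width (perpendicular), um
  fp <- sqrt(2) * w                     # footprint along a row/column, um

  # gaps between merged on-intervals [onset, onset + fp] whose left end lies
  # in [0, len]; by memorylessness of the Poisson onsets these are iid
  # Exp(gap_rate) draws. The onset window extends well past the field so that
  # every gap starting inside it is measured at full length (no censoring).
  interior_gaps <- function(onsets, len) {
    if (length(onsets) < 2L) return(numeric(0))
    gaps <- numeric(0)
    run_end <- onsets[1] + fp
    for (k in 2:length(onsets)) {
      if (onsets[k] > run_end) {
        if (run_end >= 0 && run_end <= len)
          gaps <- c(gaps, onsets[k] - run_end)
        run_end <- onsets[k] + fp
      } else {
        run_end <- max(run_end, onsets[k] + fp)
      }
    }
    gaps
  }

  # clip a diagonal segment to the field in x (y follows the 45 degree
  # slope); returns NULL when fully outside
  clip_seg <- function(x0, y0, x1, y1) {
    sl <- (y1 - y0) / (x1 - x0)          # +1 or -1
    xa <- max(x0, 0); xb <- min(x1, W)
    if (xb <= xa) return(NULL)
    c(xa, y0 + sl * (xa - x0), xb, y0 + sl * (xb - x0))
  }

  ybreaks <- seq(0, H, by = band_um)
  if (ybreaks[length(ybreaks)] < H) ybreaks <- c(ybreaks, H)
  buffer <- 30 / gap_rate
  segs <- list(); gaps <- list()
  for (b in seq_len(length(ybreaks) - 1L)) {
    y0 <- ybreaks[b]; y1 <- ybreaks[b + 1L]; h <- y1 - y0
    span <- W + h + fp + buffer
    # x-intercepts (at the bottom edge of the band) of the two families
    cp <- sort(stats::runif(stats::rpois(1L, gap_rate / 2 * span),
                            -h - fp, W + buffer))
    cm <- sort(stats::runif(stats::rpois(1L, gap_rate / 2 * span),
                            -h - fp, W + buffer))
    for (c0 in cp) {
      s <- clip_seg(c0, y0, c0 + h, y1)
      if (!is.null(s))
        segs[[length(segs) + 1L]] <- s
    }
    for (c0 in cm) {
      s <- clip_seg(c0, y1, c0 + h, y0)
      if (!is.null(s))
        segs[[length(segs) + 1L]] <- s
    }
    # reference-row gap sample: crossings of the band mid row
    ym <- (y0 + y1) / 2
    cross <- c(cp + (ym - y0), cm + (y1 - ym))
    gaps[[length(gaps) + 1L]] <- interior_gaps(sort(cross) - fp / 2, W)
  }
  fib <- as.data.frame(do.call(rbind, segs))
  names(fib) <- c("x0", "y0", "x1", "y1")
  fib$sigma_nm <- sigma_nm
  fib$amplitude <- amplitude
  out <- list(fibers = fib, field_um = field_um, pixel_size = pixel_size,
              gap_rate = gap_rate, sigma_nm = sigma_nm, seed = seed,
              gaps_true = unlist(gaps))
  class(out) <- "fiber_phantom"
  out
}

#' @export
print.fiber_phantom <- function(x, ...) {
  cat(sprintf(paste0("<fiber_phantom> %d fibers in %.4g x %.4g um, ",
                     "sigma %.4g nm, gap rate %.4g /um (1/rate = %.3g um)\n"),
              nrow(x$fibers), x$field_um[1], x$field_um[2], x$sigma_nm,
              x$gap_rate, 1 / x$gap_rate))
  invisible(x)
}

# point spread function FWHM (nm) assumed per imaging modality; chosen to
# mirror the rank order of the modalities' resolutions, not measured values
modality_psf_fwhm_nm <- function(modality) {
  switch(modality,
         widefield = 250, confocal = 210, airyscan = 140, sim = 120,
         storm_render = 0,
         stop("unknown modality: ", modality))
}

#' Render a fiber phantom as seen by an imaging modality
#'
#' Each fiber contributes a Gaussian cross-section of standard deviation
#' `sigma_nm` (its true width); imaging through a modality with Gaussian PSF
#' of the given FWHM widens this analytically to
#' `sqrt(sigma_true^2 + sigma_psf^2)`. Depth-dependent degradation is modelled
#' as multiplicative contrast loss plus additive background, both linear in
#' imaging depth; shot noise is Poisson.
#'
#' @param phantom a [fiber_network_phantom()].
#' @param modality one of `"widefield"`, `"confocal"`, `"airyscan"`, `"sim"`,
#'   `"storm_render"`. `storm_render` renders the true structure with no PSF
#'   widening (the super-resolved limit).
#' @param depth_um imaging depth into the 3D sample, in um (0 = at the
#'   section surface).
#' @param psf_fwhm_nm override of the modality PSF FWHM (nm).
#' @param noise add Poisson shot noise?
#' @param background mean background level (intensity units) at depth 0.
#' @param photon_scale intensity-to-photon scale used for shot noise; peak
#'   fiber amplitude 1 corresponds to this many photons.
#' @param depth_bg_per_um relative background increase per um of depth.
#' @param depth_contrast_per_um relative signal contrast loss per um of depth.
#' @param seed seed for the noise draw.
#' @return a `pixel_image`; the phantom (ground truth) is attached as
#'   attribute `ground_truth`.
#' @export
generate_fiber_image <- function(phantom,
                                 modality = c("widefield", "confocal",
                                              "airyscan", "sim", "storm_render"),
                                 depth_um = 0,
                                 psf_fwhm_nm = NULL,
                                 noise = TRUE,
                                 background = 0.05,
                                 photon_scale = 200,
                                 depth_bg_per_um = 0.05,
                                 depth_contrast_per_um = 0.02,
                                 seed = 1L) {
  stopifnot(inherits(phantom, "fiber_phantom"), depth_um >= 0)
  modality <- match.arg(modality)
  if (is.null(psf_fwhm_nm)) psf_fwhm_nm <- modality_psf_fwhm_nm(modality)
  if (any(phantom$field_um <= 0)) stop("non-positive field")
  if (psf_fwhm_nm > 0 && phantom$pixel_size * 1000 > psf_fwhm_nm / 2)
    warning("pixel size exceeds PSF FWHM / 2: undersampled (Nyquist violation)")

  px <- phantom$pixel_size
  nc <- max(1L, round(phantom$field_um[1] / px))
  nr <- max(1L, round(phantom$field_um[2] / px))
  xs <- pixel_centers(nc, px)
  ys <- pixel_centers(nr, px)
  img <- matrix(0, nr, nc)
  sig_psf_um <- fwhm_to_sigma(psf_fwhm_nm) / 1000

  fib <- phantom$fibers
  if (!is.null(fib) && nrow(fib) > 0) {
    for (k in seq_len(nrow(fib))) {
      s_um <- sqrt((fib$sigma_nm[k] / 1000)^2 + sig_psf_um^2)
      reach <- 4 * s_um
      x0 <- fib$x0[k]; y0 <- fib$y0[k]; x1 <- fib$x1[k]; y1 <- fib$y1[k]
      jj <- which(xs >= min(x0, x1) - reach & xs <= max(x0, x1) + reach)
      ii <- which(ys >= min(y0, y1) - reach & ys <= max(y0, y1) + reach)
      if (!length(jj) || !length(ii)) next
      gx <- matrix(xs[jj], length(ii), length(jj), byrow = TRUE)
      gy <- matrix(ys[ii], length(ii), length(jj))
      dx <- x1 - x0; dy <- y1 - y0
      len2 <- dx * dx + dy * dy
      if (len2 == 0) {
        d2 <- (gx - x0)^2 + (gy - y0)^2
      } else {
        t <- pmin(1, pmax(0, ((gx - x0) * dx + (gy - y0) * dy) / len2))
        d2 <- (gx - (x0 + t * dx))^2 + (gy - (y0 + t * dy))^2
      }
      img[ii, jj] <- img[ii, jj] + fib$amplitude[k] * exp(-d2 / (2 * s_um^2))
    }
  }

  contrast <- 1 / (1 + depth_contrast_per_um * depth_um)
  bg <- background * (1 + depth_bg_per_um * depth_um)
  img <- img * contrast + bg
  if (noise) {
    set.seed(seed)
    img[] <- stats::rpois(length(img), img * photon_scale) / photon_scale
  }
  out <- pixel_image(img, px)
  attr(out, "ground_truth") <- phantom
  out
}
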