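#' Filter localizations by photon count and fitted PSF width
#'
#' Retains exactly the records with `photons > min_photons` and
#' `sigma_min_nm < sigma_nm < sigma_max_nm` (strict inequalities), the
#' standard quality filter removing dim localizations and poor fits.
#'
#' @param table localization table (data frame with `photons`, `sigma_nm`).
#' @param min_photons minimum photon count (exclusive).
#' @param sigma_min_nm,sigma_max_nm exclusive bounds on the fitted Gaussian
#'   standard deviation, in nm.
#' @return the filtered table (extra columns preserved).
#' @export
filter_localizations <- function(table, min_photons = 100,
                                 sigma_min_nm = 50, sigma_max_nm = 250) {
  keep <- table$photons > min_photons &
    table$sigma_nm > sigma_min_nm & table$sigma_nm < sigma_max_nm
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all localizations removed by filter")
  rownames(out) <- NULL
  out
}

#' Remove spatially isolated localizations with DBSCAN
#'
#' Runs DBSCAN on the (x, y) coordinates and discards records labelled noise;
#' core points (at least `min_pts` neighbours within `epsilon_nm`, counting
#' the point itself) and border points (within `epsilon_nm` of a core point)
#' are retained. Neighbour search is grid-accelerated; results are identical
#' to the textbook algorithm.
#'
#' @param table localization table with `x_nm`, `y_nm`.
#' @param epsilon_nm neighbourhood radius in nm.
#' @param min_pts minimum neighbourhood size for a core point.
#' @return the table restricted to cluster members.
#' @export
dbscan_filter <- function(table, epsilon_nm = 50, min_pts = 5) {
  n <- nrow(table)
  if (n == 0) return(table)
  x <- table$x_nm; y <- table$y_nm
  eps2 <- epsilon_nm^2
  cx <- floor(x / epsilon_nm); cy <- floor(y / epsilon_nm)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  neighbour_count <- integer(n)
  neighbour_of_core <- logical(n)
  # pass 1: neighbour counts -> core flags
  nb_idx <- function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      c0 <- cells[[k]]
      if (!is.null(c0)) cand <- c(cand, c0)
    }
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps2]
  }
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    nbrs[[i]] <- nb_idx(i)
    neighbour_count[i] <- length(nbrs[[i]])
  }
  core <- neighbour_count >= min_pts
  for (i in which(core)) neighbour_of_core[nbrs[[i]]] <- TRUE
  member <- core | neighbour_of_core
  out <- table[member, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drift correction by binned cross-correlation
#'
#' Splits the movie into `n_bins` equal temporal bins, renders each bin as a
#' 2D localization histogram, estimates the displacement of every bin relative
#' to the first by the sub-pixel (parabolic) peak of their cross-correlation,
#' linearly interpolates drift between bin centers (constant extrapolation at
#' the ends), and subtracts the per-frame drift from the coordinates.
#'
#' @param table localization table with `frame`, `x_nm`, `y_nm`.
#' @param n_bins number of temporal bins.
#' @param hist_px_nm pixel size of the correlation histograms, in nm.
#' @return list with `table` (drift-corrected), `trace` (per-bin displacement,
#'   class `drift_trace`), and `per_frame` (interpolated drift per frame).
#' @export
drift_correct <- function(table, n_bins = 5, hist_px_nm = 20) {
  stopifnot(n_bins >= 2, nrow(table) > 0)
  fr <- range(table$frame)
  breaks <- seq(fr[1] - 0.5, fr[2] + 0.5, length.out = n_bins + 1)
  bin <- cut(table$frame, breaks, labels = FALSE)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2

  xr <- range(table$x_nm); yr <- range(table$y_nm)
  nx <- max(8L, ceiling(diff(xr) / hist_px_nm) + 8L)
  ny <- max(8L, ceiling(diff(yr) / hist_px_nm) + 8L)
  hist2d <- function(idx) {
    h <- matrix(0, ny, nx)
    ix <- pmin(nx, pmax(1L, floor((table$x_nm[idx] - xr[1]) / hist_px_nm) + 4L))
    iy <- pmin(ny, pmax(1L, floor((table$y_nm[idx] - yr[1]) / hist_px_nm) + 4L))
    for (k in seq_along(ix)) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1
    h
  }

  counts <- tabulate(bin, n_bins)
  sparse <- counts < 10
  if (any(sparse))
    warning(sprintf("%d drift bin(s) with < 10 localizations; interpolated",
                    sum(sparse)))
  ref <- hist2d(which(bin == which(!sparse)[1]))
  Fref <- stats::fft(ref)
  dx <- dy <- rep(NA_real_, n_bins)
  dx[1] <- dy[1] <- 0
  for (b in seq_len(n_bins)[-1]) {
    if (sparse[b]) next
    h <- hist2d(which(bin == b))
    cc <- Re(stats::fft(Conj(Fref) * stats::fft(h), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    # parabolic sub-pixel refinement with circular indexing
    wrap <- function(i, n) ((i - 1) %% n) + 1
    sub <- function(i, n, f) {
      fm <- f(wrap(i - 1, n)); f0 <- f(i); fp <- f(wrap(i + 1, n))
      den <- fm - 2 * f0 + fp
      if (den == 0) 0 else 0.5 * (fm - fp) / den
    }
    si <- sub(pk[1], ny, function(i) cc[i, pk[2]])
    sj <- sub(pk[2], nx, function(j) cc[pk[1], j])
    # peak position -> displacement (account for circular shift origin at 1)
    sh <- function(p, s, n) { v <- (p - 1 + s); if (v > n / 2) v <- v - n; v }
    dy[b] <- sh(pk[1], si, ny) * hist_px_nm
    dx[b] <- sh(pk[2], sj, nx) * hist_px_nm
  }
  # fill sparse bins from neighbours
  if (any(is.na(dx))) {
    ok <- which(!is.na(dx))
    dx[-ok] <- stats::approx(centers[ok], dx[ok], xout = centers[-ok], rule = 2)$y
    dy[-ok] <- stats::approx(centers[ok], dy[ok], xout = centers[-ok], rule = 2)$y
  }
  frames <- seq(fr[1], fr[2])
  pf_dx <- stats::approx(centers, dx, xout = frames, rule = 2)$y
  pf_dy <- stats::approx(centers, dy, xout = frames, rule = 2)$y
  per_frame <- data.frame(frame = frames, dx_nm = pf_dx, dy_nm = pf_dy)
  idx <- match(table$frame, frames)
  out <- table
  out$x_nm <- table$x_nm - pf_dx[idx]
  out$y_nm <- table$y_nm - pf_dy[idx]
  trace <- data.frame(bin = seq_len(n_bins), frame_center = centers,
                      dx_nm = dx, dy_nm = dy)
  class(trace) <- c("drift_trace", "data.frame")
  list(table = out, trace = trace, per_frame = per_frame)
}

#' Render localizations as a normalized-Gaussian image
#'
#' Each record is splatted as a unit-integral 2D Gaussian of standard
#' deviation `uncertainty_nm` on a grid of `pixel_nm` pixels, so the rendered
#' image integrates to the record count (up to far-tail truncation).
#'
#' @param table localization table with `x_nm`, `y_nm`.
#' @param pixel_nm rendering pixel size (nm).
#' @param uncertainty_nm lateral rendering uncertainty (nm).
#' @param extent_nm optional `c(xmin, xmax, ymin, ymax)`; default covers the
#'   data padded by 5 uncertainties.
#' @return a `pixel_image` (pixel size in um).
#' @export
render_localizations <- function(table, pixel_nm = 10, uncertainty_nm = 10,
                                 extent_nm = NULL) {
  stopifnot(nrow(table) > 0)
  pad <- 5 * uncertainty_nm
  if (is.null(extent_nm))
    extent_nm <- c(min(table$x_nm) - pad, max(table$x_nm) + pad,
                   min(table$y_nm) - pad, max(table$y_nm) + pad)
  nx <- max(1L, ceiling((extent_nm[2] - extent_nm[1]) / pixel_nm))
  ny <- max(1L, ceiling((extent_nm[4] - extent_nm[3]) / pixel_nm))
  img <- matrix(0, ny, nx)
  xedges <- extent_nm[1] + (0:nx) * pixel_nm
  yedges <- extent_nm[3] + (0:ny) * pixel_nm
  r <- ceiling(5 * uncertainty_nm / pixel_nm)
  for (k in seq_len(nrow(table))) {
    jc <- floor((table$x_nm[k] - extent_nm[1]) / pixel_nm) + 1L
    ic <- floor((table$y_nm[k] - extent_nm[3]) / pixel_nm) + 1L
    jj <- max(1L, jc - r):min(nx, jc + r)
    ii <- max(1L, ic - r):min(ny, ic + r)
    if (!length(jj) || !length(ii)) next
    fx <- diff(stats::pnorm(xedges[c(jj, jj[length(jj)] + 1L)],
                            table$x_nm[k], uncertainty_nm))
    fy <- diff(stats::pnorm(yedges[c(ii, ii[length(ii)] + 1L)],
                            table$y_nm[k], uncertainty_nm))
    img[ii, jj] <- img[ii, jj] + fy %o% fx
  }
  out <- pixel_image(img, pixel_nm / 1000)
  attr(out, "extent_nm") <- extent_nm
  out
}

#' Median Thompson-style localization precision of a table
#'
#' Per record, the precision is
#' `sigma_loc^2 = (s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2)`
#' with `s` the fitted PSF sigma, `a` the camera pixel size, `N` the photon
#' count and `b` the background (photons/pixel). Records with `N = 0` are
#' skipped.
#'
#' @param table localization table.
#' @param camera a [camera_model()].
#' @param background_photons_per_px background level; defaults to the table's
#'   per-record fitted `background` column when present, else 0.
#' @param aggregate summary function across records (default median).
#' @return aggregated precision in nm.
#' @export
estimate_precision <- function(table, camera,
                               background_photons_per_px = NULL,
                               aggregate = stats::median) {
  stopifnot(nrow(table) > 0)
  b <- if (!is.null(background_photons_per_px)) background_photons_per_px
       else if (!is.null(table$background)) table$background else 0
  keep <- table$photons > 0
  prec <- thompson_precision(table$sigma_nm[keep], table$photons[keep],
                             camera$pixel_size_nm,
                             if (length(b) > 1) b[keep] else b)
  aggregate(prec)
}

#' Nyquist resolution from localization density
#'
#' Uses the 2D density convention `R = 2 / sqrt(rho)` with `rho` the number of
#' localizations per unit area. The exponent convention is pluggable via
#' `dimension` (`R = 2 / rho^(1/D)`).
#'
#' @param table localization table.
#' @param roi_area_um2 area over which the localizations were collected (um^2).
#' @param dimension dimensionality of the density convention (default 2).
#' @return Nyquist resolution in nm.
#' @export
estimate_nyquist <- function(table, roi_area_um2, dimension = 2) {
  stopifnot(roi_area_um2 > 0)
  n <- nrow(table)
  if (n == 0) stop("no localizations: Nyquist resolution undefined")
  rho <- n / roi_area_um2            # per um^dimension
  1000 * 2 / rho^(1 / dimension)     # nm
}

#' Combined SMLM resolution estimate
#'
#' Combines localization precision and Nyquist resolution in quadrature:
#' `resolution = sqrt(precision^2 + nyquist^2)`.
#'
#' @param precision_nm localization precision (nm), > 0.
#' @param nyquist_nm Nyquist resolution (nm), > 0.
#' @return an object of class `resolution_estimate` with fields
#'   `localization_precision`, `nyquist_resolution`, `combined_resolution`
#'   (all nm).
#' @export
combined_resolution <- function(precision_nm, nyquist_nm) {
  if (!(precision_nm > 0) || !(nyquist_nm > 0))
    stop("both inputs must be positive")
  structure(list(localization_precision = precision_nm,
                 nyquist_resolution = nyquist_nm,
                 combined_resolution = sqrt(precision_nm^2 + nyquist_nm^2)),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  cat(sprintf(paste0("<resolution_estimate> precision %.3g nm, ",
                     "Nyquist %.3g nm, combined %.3g nm\n"),
              x$localization_precision, x$nyquist_resolution,
              x$combined_resolution))
  invisible(x)
}

#' Resolution and apparent fiber width versus movie length
#'
#' Runs the full reconstruction chain (detection, quality filter, DBSCAN,
#' drift correction, rendering) on truncations of a movie and reports the
#' combined resolution and, when the movie images a fiber structure, the
#' apparent fiber FWHM of the rendering, as a convergence curve. Both
#' quantities are expected to saturate once localization density stops being
#' limiting.
#'
#' @param movie an `smlm_movie`.
#' @param frame_counts increasing frame counts (each <= movie length).
#' @param roi_area_um2 area for the Nyquist density; defaults to the movie
#'   field of view.
#' @param min_photons,sigma_min_nm,sigma_max_nm,epsilon_nm,min_pts,drift_bins,
#'   render_px_nm,uncertainty_nm chain parameters (standard defaults).
#' @param n_transects number of automatic transects for the apparent-FWHM
#'   measurement (0 disables it).
#' @param detect_threshold detection threshold passed to [detect_and_fit()].
#' @param seed seed for transect placement.
#' @return data frame `frames, n_locs, precision_nm, nyquist_nm,
#'   resolution_nm, fiber_fwhm_nm`.
#' @export
resolution_vs_frames <- function(movie, frame_counts,
                                 roi_area_um2 = NULL,
                                 min_photons = 100,
                                 sigma_min_nm = 50, sigma_max_nm = 250,
                                 epsilon_nm = 50, min_pts = 5,
                                 drift_bins = 5,
                                 render_px_nm = 10, uncertainty_nm = 10,
                                 n_transects = 20,
                                 detect_threshold = 5,
                                 seed = 1L) {
  stopifnot(inherits(movie, "smlm_movie"),
            all(frame_counts <= dim(movie$data)[3]))
  if (is.null(roi_area_um2)) {
    d <- dim(movie$data)
    roi_area_um2 <- prod(d[1:2]) * (movie$pixel_size_nm / 1000)^2
  }
  full <- detect_and_fit(movie, detect_threshold = detect_threshold)
  rows <- lapply(sort(frame_counts), function(fc) {
    tab <- full[full$frame <= fc, , drop = FALSE]
    tab <- filter_localizations(tab, min_photons, sigma_min_nm, sigma_max_nm)
    tab <- dbscan_filter(tab, epsilon_nm, min_pts)
    if (nrow(tab) == 0)
      return(data.frame(frames = fc, n_locs = 0L, precision_nm = NA,
                        nyquist_nm = NA, resolution_nm = NA,
                        fiber_fwhm_nm = NA))
    if (length(unique(tab$frame)) >= drift_bins * 2)
      tab <- drift_correct(tab, n_bins = drift_bins)$table
    prec <- estimate_precision(tab, movie$camera)
    nyq <- estimate_nyquist(tab, roi_area_um2)
    res <- combined_resolution(prec, nyq)$combined_resolution
    fw <- NA_real_
    if (n_transects > 0) {
      pad <- 40 * render_px_nm   # room for transects around the structure
      ext <- c(min(tab$x_nm) - pad, max(tab$x_nm) + pad,
               min(tab$y_nm) - pad, max(tab$y_nm) + pad)
      img <- render_localizations(tab, render_px_nm, uncertainty_nm,
                                  extent_nm = ext)
      rois <- auto_transects(img, n_transects, seed = seed)
      if (length(rois)) {
        rep <- tryCatch(fiber_width_report(img, rois),
                        error = function(e) NULL)
        if (!is.null(rep)) fw <- rep$mean_fwhm * 1000  # um -> nm
      }
    }
    data.frame(frames = fc, n_locs = nrow(tab), precision_nm = prec,
               nyquist_nm = nyq, resolution_nm = res, fiber_fwhm_nm = fw)
  })
  do.call(rbind, rows)
}
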