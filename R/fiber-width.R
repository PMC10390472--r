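#' Line-transect region of interest
#'
#' A straight transect between two physical points, intended to be drawn
#' perpendicular to a fiber's long axis, along which an intensity profile is
#' sampled.
#'
#' @param x0,y0,x1,y1 endpoints in um.
#' @param step sampling step in um; defaults to the image pixel size at
#'   extraction time.
#' @return an object of class `profile_roi`.
#' @export
profile_roi <- function(x0, y0, x1, y1, step = NULL) {
  if (x0 == x1 && y0 == y1) stop("ROI endpoints must be distinct")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, step = step),
            class = "profile_roi")
}

#' Sample an intensity profile along a transect
#'
#' Bilinear interpolation of the image along the ROI at the sampling step;
#' positions are physical distances (um) from the first endpoint. The number
#' of samples is `ceiling(length / step) + 1`.
#'
#' @param image a 2D `pixel_image`.
#' @param roi a [profile_roi()].
#' @return data frame with `position` (um) and `intensity`.
#' @export
extract_profile <- function(image, roi) {
  stopifnot(inherits(image, "pixel_image"), inherits(roi, "profile_roi"))
  step <- if (is.null(roi$step)) image$pixel_size else roi$step
  len <- sqrt((roi$x1 - roi$x0)^2 + (roi$y1 - roi$y0)^2)
  n <- ceiling(len / step) + 1L
  if (n < 5L) stop("transect shorter than 5 samples")
  t <- seq(0, 1, length.out = n)
  x <- roi$x0 + t * (roi$x1 - roi$x0)
  y <- roi$y0 + t * (roi$y1 - roi$y0)
  v <- interp_bilinear(image, x, y)
  if (anyNA(v)) stop("ROI extends outside the image")
  data.frame(position = t * len, intensity = v)
}

#' Fit a Gaussian to an intensity profile
#'
#' Nonlinear least squares of
#' `y = y0 + A * exp(-(x - x0)^2 / (2 sigma^2))`
#' to a sampled cross-section. Fits with adjusted R^2 below 0.95 (computed
#' with p = 4 parameters), negative fitted amplitude, or non-convergence are
#' marked rejected; the FWHM is `2 sqrt(2 log 2) * sigma`.
#'
#' @param profile data frame with `position` and `intensity` (>= 5 samples),
#'   as returned by [extract_profile()].
#' @param r2_min acceptance threshold on adjusted R^2 (>= is accepted).
#' @return an object of class `gauss_profile_fit` with elements `y0`, `A`,
#'   `x0`, `sigma`, `fwhm`, `adj_r_squared`, `accepted`, `reason`.
#' @export
fit_gaussian_profile <- function(profile, r2_min = 0.95) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 5)
  x <- profile$position; y <- profile$intensity
  n <- length(y)
  start <- list(y0 = min(y), A = max(y) - min(y), x0 = x[which.max(y)],
                sigma = diff(range(x)) / 6)
  rejected <- function(reason) {
    structure(list(y0 = NA_real_, A = NA_real_, x0 = NA_real_,
                   sigma = NA_real_, fwhm = NA_real_,
                   adj_r_squared = NA_real_, accepted = FALSE,
                   reason = reason),
              class = "gauss_profile_fit")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * exp(-(x - x0)^2 / (2 * sigma^2)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(rejected("fit did not converge"))
  p <- stats::coef(fit)
  if (!all(is.finite(p))) return(rejected("non-finite parameters"))
  if (p[["A"]] <= 0) return(rejected("negative fitted amplitude"))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(rejected("constant profile"))
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - 4 - 1)
  sigma <- abs(p[["sigma"]])
  structure(list(y0 = p[["y0"]], A = p[["A"]], x0 = p[["x0"]], sigma = sigma,
                 fwhm = sigma_to_fwhm(sigma), adj_r_squared = adj,
                 accepted = adj >= r2_min, reason = NULL),
            class = "gauss_profile_fit")
}

#' @export
print.gauss_profile_fit <- function(x, ...) {
  if (!x$accepted && is.na(x$sigma)) {
    cat("<gauss_profile_fit> rejected:", x$reason, "\n")
  } else {
    cat(sprintf(paste0("<gauss_profile_fit> x0 %.4g, sigma %.4g, FWHM %.4g, ",
                       "adj R^2 %.4f (%s)\n"),
                x$x0, x$sigma, x$fwhm, x$adj_r_squared,
                if (x$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' @export
coef.gauss_profile_fit <- function(object, ...) {
  c(y0 = object$y0, A = object$A, x0 = object$x0, sigma = object$sigma)
}

#' Apparent fiber width from a set of transects
#'
#' Fits every transect profile with [fit_gaussian_profile()], discards
#' rejected fits, and reports the mean FWHM over accepted fits as the
#' apparent fiber width.
#'
#' @param image a 2D `pixel_image`.
#' @param rois list of [profile_roi()].
#' @param r2_min acceptance threshold on adjusted R^2.
#' @return an object of class `fiber_width_report`: `mean_fwhm` and `sd_fwhm`
#'   (um), `n_accepted`, `n_rejected`, and the individual `fits`.
#' @export
fiber_width_report <- function(image, rois, r2_min = 0.95) {
  stopifnot(length(rois) >= 1)
  fits <- lapply(rois, function(r)
    tryCatch(fit_gaussian_profile(extract_profile(image, r), r2_min),
             error = function(e) structure(
               list(accepted = FALSE, fwhm = NA_real_,
                    reason = conditionMessage(e)),
               class = "gauss_profile_fit")))
  acc <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  if (!any(acc))
    stop("no accepted fits: all ", length(fits),
         " transects rejected (first reason: ",
         if (!is.null(fits[[1]]$reason)) fits[[1]]$reason else
           sprintf("adj R^2 %.3f < %.2f", fits[[1]]$adj_r_squared, r2_min),
         ")")
  fw <- vapply(fits[acc], `[[`, numeric(1), "fwhm")
  structure(list(mean_fwhm = mean(fw), sd_fwhm = stats::sd(fw),
                 n_accepted = sum(acc), n_rejected = sum(!acc),
                 fwhm = fw, fits = fits),
            class = "fiber_width_report")
}

#' @export
print.fiber_width_report <- function(x, ...) {
  cat(sprintf(paste0("<fiber_width_report> mean FWHM %.4g um (SD %.3g), ",
                     "%d accepted / %d rejected fits\n"),
              x$mean_fwhm, x$sd_fwhm, x$n_accepted, x$n_rejected))
  invisible(x)
}

#' Modality resolution from bead point spread functions
#'
#' Measures the FWHM of the point spread function from isolated bead images,
#' in the same way fiber widths are measured: two orthogonal transects through
#' each bead centroid are fitted with [fit_gaussian_profile()], and the mean
#' accepted FWHM defines the resolution (and the minimum expected apparent
#' fiber width) of the modality.
#'
#' @param image a 2D `pixel_image` of a bead field.
#' @param bead_centroids data frame with `x`, `y` (um).
#' @param expected_fwhm_um rough expected PSF FWHM, used for the transect
#'   length (6x) and the isolation criterion (nearest neighbour > 5x).
#' @param r2_min acceptance threshold on adjusted R^2.
#' @return list with `fwhm_um`, `fwhm_nm`, `n_beads_used`, `per_bead_fwhm`.
#' @export
bead_psf_resolution <- function(image, bead_centroids, expected_fwhm_um = 0.3,
                                r2_min = 0.95) {
  bc <- as.data.frame(bead_centroids)
  stopifnot(all(c("x", "y") %in% names(bc)), nrow(bc) >= 1)
  keep <- rep(TRUE, nrow(bc))
  if (nrow(bc) > 1) {
    d <- as.matrix(stats::dist(bc[, c("x", "y")]))
    diag(d) <- Inf
    keep <- apply(d, 1, min) > 5 * expected_fwhm_um
    if (!all(keep))
      warning(sum(!keep), " overlapping bead(s) excluded")
  }
  half <- 3 * expected_fwhm_um
  fwhms <- c()
  per_bead <- numeric(0)
  for (k in which(keep)) {
    rois <- list(profile_roi(bc$x[k] - half, bc$y[k], bc$x[k] + half, bc$y[k]),
                 profile_roi(bc$x[k], bc$y[k] - half, bc$x[k], bc$y[k] + half))
    vals <- c()
    for (r in rois) {
      f <- tryCatch(fit_gaussian_profile(extract_profile(image, r), r2_min),
                    error = function(e) NULL)
      if (!is.null(f) && isTRUE(f$accepted)) vals <- c(vals, f$fwhm)
    }
    if (length(vals)) {
      per_bead <- c(per_bead, mean(vals))
      fwhms <- c(fwhms, vals)
    }
  }
  if (!length(fwhms)) stop("no accepted bead fits")
  list(fwhm_um = mean(fwhms), fwhm_nm = 1000 * mean(fwhms),
       n_beads_used = length(per_bead), per_bead_fwhm = per_bead)
}

#' Automatic placement of fiber-perpendicular transects
#'
#' Detects ridge-like pixels from the Hessian of a smoothed copy of the image
#' and places transects through them, oriented along the across-ridge Hessian
#' eigenvector (perpendicular to the local fiber axis). Deterministic for a
#' given seed.
#'
#' @param image a 2D `pixel_image` containing ridge-like structures.
#' @param n number of transects requested.
#' @param length_um transect length; default 30 pixels.
#' @param smooth_px Gaussian smoothing (pixels) before the Hessian.
#' @param seed integer seed for sampling among candidate ridge points.
#' @return list of [profile_roi()] (possibly fewer than `n`, with a warning).
#' @export
auto_transects <- function(image, n, length_um = NULL, smooth_px = 1,
                           seed = 1L) {
  stopifnot(inherits(image, "pixel_image"))
  px <- image$pixel_size
  if (is.null(length_um)) length_um <- 30 * px
  m <- gauss_blur(image$data, smooth_px)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 5 || nc < 5) { warning("image too small"); return(list()) }
  ii <- 2:(nr - 1); jj <- 2:(nc - 1)
  Ixx <- m[ii, jj - 1] - 2 * m[ii, jj] + m[ii, jj + 1]
  Iyy <- m[ii - 1, jj] - 2 * m[ii, jj] + m[ii + 1, jj]
  Ixy <- (m[ii + 1, jj + 1] - m[ii + 1, jj - 1] -
            m[ii - 1, jj + 1] + m[ii - 1, jj - 1]) / 4
  # most negative eigenvalue of [[Ixx, Ixy], [Ixy, Iyy]] marks across-ridge;
  # a true ridge also has |l2| << |l1| (excludes blob-like fiber end caps)
  tr <- (Ixx + Iyy) / 2
  dlt <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  l1 <- tr - dlt
  l2 <- tr + dlt
  thr <- stats::quantile(l1, 0.02)   # strongest 2% ridge responses
  ridge <- l1 < pmin(thr, 0) & abs(l2) < 0.25 * abs(l1)
  cand <- which(ridge, arr.ind = TRUE)
  if (nrow(cand) == 0) { warning("no ridges found"); return(list()) }
  # margin: keep candidates whose transect stays inside the image
  margin <- length_um / 2 + px
  cx <- (cand[, 2] + 1 - 0.5) * px   # +1: offset of the interior grid
  cy <- (cand[, 1] + 1 - 0.5) * px
  ok <- cx > margin & cx < nc * px - margin & cy > margin & cy < nr * px - margin
  cand <- cand[ok, , drop = FALSE]; cx <- cx[ok]; cy <- cy[ok]
  if (nrow(cand) == 0) { warning("no ridges away from the border"); return(list()) }
  set.seed(seed)
  pick <- sample(seq_len(nrow(cand)), min(n, nrow(cand)))
  if (length(pick) < n)
    warning(sprintf("only %d ridge points available (%d requested)",
                    length(pick), n))
  rois <- lapply(pick, function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    a <- Ixx[i, j]; b <- Ixy[i, j]; c <- Iyy[i, j]
    lam <- (a + c) / 2 - sqrt(((a - c) / 2)^2 + b^2)
    # eigenvector for lam (across-ridge direction)
    v <- if (abs(b) > 1e-12) c(lam - c, b) else if (a <= c) c(1, 0) else c(0, 1)
    v <- v / sqrt(sum(v^2))
    profile_roi(cx[k] - v[1] * length_um / 2, cy[k] - v[2] * length_um / 2,
                cx[k] + v[1] * length_um / 2, cy[k] + v[2] * length_um / 2)
  })
  rois
}
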