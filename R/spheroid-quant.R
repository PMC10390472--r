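#' Normalized intensity profile along a line bisecting a spheroid
#'
#' Samples the image edge-to-edge along a line through `center_um` at
#' `angle_deg` and normalizes the profile to its own maximum, the standard
#' readout for staining uniformity across a section.
#'
#' @param image a 2D `pixel_image` (use [get_channel()] for multichannel).
#' @param center_um line anchor `c(x, y)` in um; default image centre.
#' @param angle_deg line angle in degrees (0 = horizontal).
#' @param step sampling step in um (default: pixel size).
#' @return an object of class `intensity_profile`: data frame `position`
#'   (um along the line), `intensity`, `normalized`; attribute `flagged` is
#'   `TRUE` when the line is all zero and normalization was skipped.
#' @export
bisecting_profile <- function(image, center_um = NULL, angle_deg = 0,
                              step = NULL) {
  stopifnot(inherits(image, "pixel_image"), length(dim(image$data)) == 2L)
  px <- image$pixel_size
  if (is.null(step)) step <- px
  W <- ncol(image$data) * px; H <- nrow(image$data) * px
  if (is.null(center_um)) center_um <- c(W, H) / 2
  th <- angle_deg * pi / 180
  d <- c(cos(th), sin(th))
  # clip the infinite line to the image rectangle (with a half-pixel inset so
  # interpolation stays defined)
  lim <- function(p, v, lo, hi) {
    if (abs(v) < 1e-12) return(c(-Inf, Inf))
    sort(c((lo - p) / v, (hi - p) / v))
  }
  tx <- lim(center_um[1], d[1], px / 2, W - px / 2)
  ty <- lim(center_um[2], d[2], px / 2, H - px / 2)
  t0 <- max(tx[1], ty[1]); t1 <- min(tx[2], ty[2])
  if (!(t1 > t0)) stop("line does not intersect the image")
  n <- ceiling((t1 - t0) / step) + 1L
  t <- seq(t0, t1, length.out = n)
  x <- center_um[1] + t * d[1]; y <- center_um[2] + t * d[2]
  v <- interp_bilinear(image, x, y)
  mx <- max(v)
  flagged <- !(mx > 0)
  out <- data.frame(position = t - t0, intensity = v,
                    normalized = if (flagged) NA_real_ else v / mx)
  class(out) <- c("intensity_profile", "data.frame")
  attr(out, "flagged") <- flagged
  out
}

#' Per-slice summary of normalized intensity profiles
#'
#' Averages the normalized intensity of each profile and groups the values by
#' slice, the quantity plotted as per-slice box-and-whisker distributions when
#' assessing staining uniformity.
#'
#' @param profiles list of [bisecting_profile()] results.
#' @param slices integer slice index per profile (defaults to each profile's
#'   `slice` attribute, else a single slice).
#' @return list with `per_slice` (data frame `slice, mean_normalized, sd, n`)
#'   and `values` (per-profile means with their slice, for plotting).
#' @export
per_slice_summary <- function(profiles, slices = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(slices))
    slices <- vapply(profiles, function(p) {
      s <- attr(p, "slice"); if (is.null(s)) 1L else as.integer(s)
    }, integer(1))
  vals <- vapply(profiles, function(p) mean(p$normalized), numeric(1))
  values <- data.frame(slice = slices, mean_normalized = vals)
  agg <- do.call(rbind, lapply(split(values, values$slice), function(d)
    data.frame(slice = d$slice[1], mean_normalized = mean(d$mean_normalized),
               sd = stats::sd(d$mean_normalized), n = nrow(d))))
  rownames(agg) <- NULL
  list(per_slice = agg, values = values)
}

# evaluate a circular ROI as a logical mask
circle_mask <- function(image, x, y, r) {
  px <- image$pixel_size
  xs <- pixel_centers(ncol(image$data), px)
  ys <- pixel_centers(nrow(image$data), px)
  outer(ys, xs, function(Y, X) (X - x)^2 + (Y - y)^2 <= r^2)
}

#' Signal-to-background ratio from region maxima
#'
#' Divides the maximum intensity over signal regions (cells or their local
#' extracellular environment) by the maximum over background regions outside
#' them.
#'
#' @param image a 2D `pixel_image`.
#' @param signal_rois,background_rois data frames of circular ROIs with
#'   columns `x`, `y`, `r` (um), or logical masks matching the image.
#' @return an object of class `sb_ratio` with `ratio`, `signal_max`,
#'   `background_max`.
#' @export
signal_to_background <- function(image, signal_rois, background_rois) {
  stopifnot(inherits(image, "pixel_image"))
  as_mask <- function(rois) {
    if (is.matrix(rois) && is.logical(rois)) return(rois)
    rois <- as.data.frame(rois)
    stopifnot(all(c("x", "y", "r") %in% names(rois)), nrow(rois) >= 1)
    m <- matrix(FALSE, nrow(image$data), ncol(image$data))
    for (k in seq_len(nrow(rois)))
      m <- m | circle_mask(image, rois$x[k], rois$y[k], rois$r[k])
    m
  }
  sm <- as_mask(signal_rois); bm <- as_mask(background_rois)
  if (!any(sm) || !any(bm)) stop("ROI sets must be non-empty")
  if (any(sm & bm)) stop("signal and background ROIs must be disjoint")
  smax <- max(image$data[sm]); bmax <- max(image$data[bm])
  if (bmax <= 0) stop("background maximum is zero: ratio undefined")
  structure(list(ratio = smax / bmax, signal_max = smax,
                 background_max = bmax),
            class = "sb_ratio")
}

#' @export
print.sb_ratio <- function(x, ...) {
  cat(sprintf("<sb_ratio> %.4g (signal max %.4g / background max %.4g)\n",
              x$ratio, x$signal_max, x$background_max))
  invisible(x)
}

#' Invasion measurement from core and front radii
#'
#' The invasive distance is the circumference of the circle enclosing at
#' least 90 percent of the invasive front minus the circumference of the
#' circle fully enclosing the initial core:
#' `2 pi (r_front - r_core)`.
#'
#' @param r_core_um radius fully enclosing the core at the initial time point.
#' @param r_front_um radius enclosing >= 90 percent of invasive-cell
#'   centroids at the final time point.
#' @param flagged diagnostic flag (e.g. no invasive cells detected).
#' @return an object of class `invasion_measurement`.
#' @export
invasion_measurement <- function(r_core_um, r_front_um, flagged = FALSE) {
  stopifnot(r_core_um >= 0, r_front_um >= 0)
  structure(list(r_core_um = r_core_um, r_front_um = r_front_um,
                 invasive_distance_um = 2 * pi * (r_front_um - r_core_um),
                 flagged = flagged),
            class = "invasion_measurement")
}

#' @export
print.invasion_measurement <- function(x, ...) {
  cat(sprintf(paste0("<invasion_measurement> r_core %.4g um, r_front %.4g um,",
                     " invasive distance %.4g um%s\n"),
              x$r_core_um, x$r_front_um, x$invasive_distance_um,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# smallest radius about the centre covering >= frac of the radial distances
radial_percentile <- function(r, frac = 0.9) {
  r <- sort(r)
  r[ceiling(frac * length(r))]
}

# Otsu threshold -> largest connected component -> fill holes
segment_core <- function(image) {
  m <- image$data
  z <- (m - min(m)) / max(1e-12, diff(range(m)))
  thr <- EBImage::otsu(EBImage::Image(t(z)))
  mask <- z > thr
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  if (max(lab) == 0) stop("no core object found")
  sizes <- tabulate(as.integer(lab@.Data[lab@.Data > 0]))
  core <- EBImage::fillHull(lab == which.max(sizes))
  t(core@.Data) > 0
}

#' Invasive distance between two time points
#'
#' Segments the spheroid core in the early image (Otsu threshold, largest
#' connected component, filled holes), takes `r_core` as the radius about the
#' core centroid that fully encloses the core mask, segments cell objects in
#' the late image, and takes `r_front` as the 90th-percentile radial distance
#' of the centroids of objects lying outside the core circle. Returns
#' [invasion_measurement()] of the two radii; when no invasive object is
#' found, `r_front = r_core` and the result is flagged.
#'
#' @param image_t0 early-time `pixel_image` (core only).
#' @param image_t1 late-time `pixel_image` (core + invading cells).
#' @param front_fraction fraction of the invasive front to enclose.
#' @return an `invasion_measurement`.
#' @export
invasive_distance <- function(image_t0, image_t1, front_fraction = 0.9) {
  stopifnot(inherits(image_t0, "pixel_image"), inherits(image_t1, "pixel_image"))
  px0 <- image_t0$pixel_size
  core <- segment_core(image_t0)
  idx <- which(core, arr.ind = TRUE)
  cx <- mean((idx[, 2] - 0.5) * px0)
  cy <- mean((idx[, 1] - 0.5) * px0)
  r_core <- max(sqrt(((idx[, 2] - 0.5) * px0 - cx)^2 +
                       ((idx[, 1] - 0.5) * px0 - cy)^2))
  # late image: all above-threshold objects
  px1 <- image_t1$pixel_size
  m <- image_t1$data
  z <- (m - min(m)) / max(1e-12, diff(range(m)))
  thr <- EBImage::otsu(EBImage::Image(t(z)))
  lab <- EBImage::bwlabel(EBImage::Image(t(z > thr)))
  nlab <- max(lab)
  if (nlab == 0) return(invasion_measurement(r_core, r_core, flagged = TRUE))
  cent <- do.call(rbind, lapply(seq_len(nlab), function(l) {
    ij <- which(t(lab@.Data) == l, arr.ind = TRUE)
    c(x = mean((ij[, 2] - 0.5) * px1), y = mean((ij[, 1] - 0.5) * px1))
  }))
  rr <- sqrt((cent[, "x"] - cx)^2 + (cent[, "y"] - cy)^2)
  out <- rr[rr > r_core]
  if (!length(out)) return(invasion_measurement(r_core, r_core, flagged = TRUE))
  invasion_measurement(r_core, radial_percentile(out, front_fraction))
}

#' Significance stars for p values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, and a dagger
#' for p >= 0.05.
#'
#' @param p numeric p values.
#' @return character annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "†")))
}

#' Pairwise group comparisons with star annotation
#'
#' Two-sided Welch t-tests (or Mann-Whitney tests) between all pairs of
#' groups at alpha = 0.05, annotated with the star convention of
#' [significance_stars()]. No multiplicity correction is applied unless
#' requested.
#'
#' @param values numeric measurements.
#' @param groups group label per measurement (>= 2 groups, each n >= 2).
#' @param method `"welch"` or `"wilcoxon"`.
#' @param p_adjust method passed to [stats::p.adjust()] (default `"none"`).
#' @param alpha significance level (annotation only; fixed convention 0.05 /
#'   0.01 / 0.001).
#' @return data frame `group1, group2, n1, n2, statistic, p_value, annotation`.
#' @export
compare_groups <- function(values, groups, method = c("welch", "wilcoxon"),
                           p_adjust = "none", alpha = 0.05) {
  method <- match.arg(method)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  g <- split(values, groups)
  g <- g[vapply(g, length, integer(1)) >= 2]
  if (length(g) < 2) stop("need at least 2 groups with n >= 2")
  nm <- names(g)
  pairs <- utils::combn(length(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- g[[pr[1]]]; b <- g[[pr[2]]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate variance: exact-equality shortcut
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      stat <- NA_real_
    } else if (method == "welch") {
      t <- stats::t.test(a, b)
      p <- t$p.value; stat <- unname(t$statistic)
    } else {
      w <- suppressWarnings(stats::wilcox.test(a, b))
      p <- w$p.value; stat <- unname(w$statistic)
    }
    data.frame(group1 = nm[pr[1]], group2 = nm[pr[2]],
               n1 = length(a), n2 = length(b),
               statistic = stat, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$annotation <- significance_stars(out$p_value)
  rownames(out) <- NULL
  out
}
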