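#' Rigid / similarity transform in physical coordinates
#'
#' Maps moving-image physical coordinates onto the fixed frame:
#' `p' = s * R(theta) * (p - c) + c + t`, where `c` is the rotation centre
#' (um), `theta` the rotation in degrees, `t = (tx, ty)` the translation in
#' um, and `s` an isotropic scale (1 for rigid).
#'
#' @param theta_deg rotation angle (degrees, counter-clockwise).
#' @param tx_um,ty_um translation (um).
#' @param scale isotropic scale (> 0).
#' @param center_um rotation centre `c(x, y)` in um.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta_deg = 0, tx_um = 0, ty_um = 0, scale = 1,
                            center_um = c(0, 0)) {
  stopifnot(scale > 0)
  structure(list(theta_deg = theta_deg, tx_um = tx_um, ty_um = ty_um,
                 scale = scale, center_um = center_um),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(paste0("<rigid_transform> theta %.4g deg, t = (%.4g, %.4g) um,",
                     " scale %.4g, centre (%.4g, %.4g)\n"),
              x$theta_deg, x$tx_um, x$ty_um, x$scale,
              x$center_um[1], x$center_um[2]))
  invisible(x)
}

# forward map of points (um)
transform_points <- function(tf, x, y) {
  th <- tf$theta_deg * pi / 180
  xr <- x - tf$center_um[1]; yr <- y - tf$center_um[2]
  list(x = tf$scale * (cos(th) * xr - sin(th) * yr) + tf$center_um[1] + tf$tx_um,
       y = tf$scale * (sin(th) * xr + cos(th) * yr) + tf$center_um[2] + tf$ty_um)
}

#' Invert a rigid/similarity transform
#'
#' @param tf a [rigid_transform()].
#' @return the inverse transform (same rotation centre); composing the two
#'   yields the identity to numerical precision.
#' @export
invert_transform <- function(tf) {
  th <- -tf$theta_deg * pi / 180
  s <- 1 / tf$scale
  # p = s' R' (p' - c - t) + c  ->  express as standard form about c
  tx <- s * (cos(th) * (-tf$tx_um) - sin(th) * (-tf$ty_um))
  ty <- s * (sin(th) * (-tf$tx_um) + cos(th) * (-tf$ty_um))
  rigid_transform(-tf$theta_deg, tx, ty, s, tf$center_um)
}

#' Resample a moving image through a transform onto a fixed grid
#'
#' For every pixel of the output grid the transform is inverted and the moving
#' image sampled bilinearly.
#'
#' @param moving a 2D `pixel_image`.
#' @param tf a [rigid_transform()] mapping moving to fixed coordinates.
#' @param fixed a `pixel_image` defining the output grid (or `NULL` to keep
#'   the moving grid).
#' @param fill value outside the moving support.
#' @return the registered `pixel_image` on the fixed grid.
#' @export
apply_transform <- function(moving, tf, fixed = NULL, fill = 0) {
  stopifnot(inherits(moving, "pixel_image"))
  grid <- if (is.null(fixed)) moving else fixed
  px <- grid$pixel_size
  nr <- nrow(grid$data); nc <- ncol(grid$data)
  xs <- pixel_centers(nc, px); ys <- pixel_centers(nr, px)
  gx <- matrix(xs, nr, nc, byrow = TRUE)
  gy <- matrix(ys, nr, nc)
  inv <- invert_transform(tf)
  p <- transform_points(inv, as.vector(gx), as.vector(gy))
  v <- interp_bilinear(moving, p$x, p$y, fill = NA_real_)
  v[is.na(v)] <- fill
  pixel_image(matrix(v, nr, nc), px)
}

# resample an image to a target pixel size (bilinear)
resample_image <- function(image, pixel_size) {
  if (isTRUE(all.equal(pixel_size, image$pixel_size))) return(image)
  W <- ncol(image$data) * image$pixel_size
  H <- nrow(image$data) * image$pixel_size
  nc <- max(2L, round(W / pixel_size)); nr <- max(2L, round(H / pixel_size))
  xs <- pixel_centers(nc, pixel_size); ys <- pixel_centers(nr, pixel_size)
  gx <- matrix(xs, nr, nc, byrow = TRUE); gy <- matrix(ys, nr, nc)
  v <- interp_bilinear(image, as.vector(gx), as.vector(gy), fill = 0)
  pixel_image(matrix(v, nr, nc), pixel_size)
}

# normalized cross-correlation of the overlap of two equal-grid matrices
ncc_overlap <- function(a, b, support) {
  va <- a[support]; vb <- b[support]
  if (length(va) < 16) return(-1)
  va <- va - mean(va); vb <- vb - mean(vb)
  den <- sqrt(sum(va^2) * sum(vb^2))
  if (den == 0) return(-1)
  sum(va * vb) / den
}

#' Intensity-based rigid/similarity registration
#'
#' Registers `moving` onto `fixed` without fiducial markers by maximizing
#' normalized cross-correlation: the images are resampled to a common working
#' grid, a coarse search over rotations (1 degree steps over
#' `+/- rotation_range_deg`) with FFT translation estimation seeds a
#' Nelder-Mead refinement of (theta, tx, ty[, scale]). Designed to cope with
#' large resolution gaps (e.g. a 40 um/px ion image against a sub-um optical
#' image of the same section).
#'
#' @param moving,fixed 2D `pixel_image`s with known pixel sizes.
#' @param model `"rigid"` or `"similarity"`.
#' @param rotation_range_deg half-width of the coarse rotation search.
#' @param working_px_um pixel size of the working grid; defaults to the
#'   coarser of the two inputs.
#' @param min_score registration failure threshold on the final NCC score.
#' @return list with `transform` (a [rigid_transform()] in physical units,
#'   centred on the fixed-image centre), `registered` (moving resampled onto
#'   the fixed grid), and `score` (final NCC).
#' @export
register_images <- function(moving, fixed, model = c("rigid", "similarity"),
                            rotation_range_deg = 20,
                            working_px_um = NULL, min_score = 0.2) {
  stopifnot(inherits(moving, "pixel_image"), inherits(fixed, "pixel_image"))
  model <- match.arg(model)
  if (is.null(working_px_um))
    working_px_um <- max(moving$pixel_size, fixed$pixel_size)
  fw <- resample_image(fixed, working_px_um)
  mw <- resample_image(moving, working_px_um)
  # common grid: pad both to the same size
  nr <- max(nrow(fw$data), nrow(mw$data))
  nc <- max(ncol(fw$data), ncol(mw$data))
  pad <- function(m) { out <- matrix(0, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  F0 <- pad(fw$data); M0 <- pad(mw$data)
  F0 <- F0 - mean(F0); Fc <- stats::fft(F0)
  center <- c(nc, nr) / 2 * working_px_um

  rot_about_center <- function(theta) {
    tf <- rigid_transform(theta, 0, 0, 1, center)
    apply_transform(pixel_image(M0, working_px_um), tf,
                    pixel_image(F0, working_px_um))$data
  }
  best <- list(score = -Inf)
  for (th in seq(-rotation_range_deg, rotation_range_deg, by = 1)) {
    Mr <- rot_about_center(th)
    cc <- Re(stats::fft(Conj(Fc) * stats::fft(Mr - mean(Mr)), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sh <- function(p, n) { v <- p - 1; if (v > n / 2) v <- v - n; v }
    # peak at shift of M relative to F: M approx F shifted by +d -> moving
    # must be translated by -d to match
    dx <- -sh(pk[2], nc) * working_px_um
    dy <- -sh(pk[1], nr) * working_px_um
    if (max(cc) > best$score)
      best <- list(score = max(cc), theta = th, tx = dx, ty = dy)
  }
  Fimg <- pixel_image(F0, working_px_um)
  Mimg <- pixel_image(M0, working_px_um)
  objective <- function(p) {
    tf <- rigid_transform(p[1], p[2], p[3],
                          if (model == "similarity") exp(p[4]) else 1, center)
    reg <- apply_transform(Mimg, tf, Fimg, fill = NA_real_)
    supp <- !is.na(reg$data)
    -ncc_overlap(F0, ifelse(supp, reg$data, 0), supp)
  }
  p0 <- c(best$theta, best$tx, best$ty)
  if (model == "similarity") p0 <- c(p0, 0)
  opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                      control = list(maxit = 400,
                                     parscale = c(1, working_px_um,
                                                  working_px_um,
                                                  if (model == "similarity") 0.05)))
  score <- -opt$value
  if (score < min_score)
    stop(sprintf("registration failed: NCC score %.3f below %.2f",
                 score, min_score))
  tf <- rigid_transform(opt$par[1], opt$par[2], opt$par[3],
                        if (model == "similarity") exp(opt$par[4]) else 1,
                        center)
  list(transform = tf,
       registered = apply_transform(moving, tf, fixed),
       score = score)
}

#' Overlay a registered image onto the fixed image as an RGB composite
#'
#' Linearly rescales each channel to [0, 1] and composites fixed (green) and
#' registered (magenta) for visual inspection of a correlative registration.
#'
#' @param fixed,registered `pixel_image`s on the same grid.
#' @return a `pixel_image` with 3 channels (R, G, B).
#' @export
overlay_images <- function(fixed, registered) {
  stopifnot(all(dim(fixed$data) == dim(registered$data)))
  sc <- function(m) { r <- range(m); if (diff(r) == 0) m * 0 else (m - r[1]) / diff(r) }
  f <- sc(fixed$data); g <- sc(registered$data)
  arr <- array(c(g, f, g), c(dim(f), 3),
               dimnames = list(NULL, NULL, c("R", "G", "B")))
  pixel_image(arr, fixed$pixel_size)
}
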