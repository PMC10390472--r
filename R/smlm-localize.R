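# Single-molecule detection and sub-pixel Gaussian fitting.
#
# The localization table produced here is a plain data.frame with the fixed
# columns [frame, x_nm, y_nm, sigma_nm, photons, uncertainty_nm] plus a
# fitted per-record background column; downstream filters preserve any extra
# columns.

# Gaussian blur with replicated edges; direct separable convolution for
# small kernels, FFT (EBImage::filter2) for large ones
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  if (sigma > 4) {
    k1 <- stats::dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
    return(EBImage::filter2(m, k1 %o% k1, boundary = "replicate"))
  }
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  # rows direction
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
    out <- out + k[o + r + 1L] * m[idx, , drop = FALSE]
  }
  m2 <- out; out <- matrix(0, nr, nc)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(nc) + o, 1L), nc)
    out <- out + k[o + r + 1L] * m2[, idx, drop = FALSE]
  }
  out
}

# difference-of-Gaussians band-pass used as the detection pre-filter
dog_filter <- function(m, sigma_small = 1, sigma_large = 2.5) {
  gauss_blur(m, sigma_small) - gauss_blur(m, sigma_large)
}

# 8-connected local maxima above `thr`; plateau ties keep the lexicographically
# smallest (row, col) pixel
local_maxima <- function(m, thr) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(cbind(integer(0), integer(0)))
  ok <- m > thr
  shift <- function(di, dj) {
    ii <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    jj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    m[ii, jj]
  }
  # strictly greater than the lexicographically earlier neighbours, >= later,
  # so a flat plateau keeps only its smallest (row, col) pixel
  ge <- ok
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1)))
    ge <- ge & (m > shift(d[1], d[2]))
  for (d in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1)))
    ge <- ge & (m >= shift(d[1], d[2]))
  which(ge, arr.ind = TRUE)
}

# Levenberg-Marquardt fit of b + A exp(-((x-x0)^2+(y-y0)^2)/(2 s^2)) to a
# small pixel window. Weighted least squares with Poisson variance weights
# (var ~ intensity), which approaches maximum-likelihood efficiency for
# shot-noise-limited spots; analytic Jacobian.
fit_gaussian2d <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  ys <- rep(seq_len(nr), nc); xs <- rep(seq_len(nc), each = nr)
  zz <- as.vector(z)
  b <- min(zz); A <- max(zz) - b
  i <- which.max(zz)
  p <- c(b, A, xs[i], ys[i], max(1.0, min(nr, nc) / 6))
  model <- function(p) p[1] + p[2] * exp(-((xs - p[3])^2 + (ys - p[4])^2) / (2 * p[5]^2))
  # iteratively reweighted: weights follow the current model intensity
  sw <- 1 / sqrt(pmax(model(p), 1))
  cur <- sum((sw * (model(p) - zz))^2)
  lambda <- 1e-3
  for (it in 1:60) {
    E <- exp(-((xs - p[3])^2 + (ys - p[4])^2) / (2 * p[5]^2))
    f0 <- p[1] + p[2] * E
    sw <- 1 / sqrt(pmax(f0, 1))
    cur <- sum((sw * (f0 - zz))^2)
    r <- sw * (f0 - zz)
    d2 <- (xs - p[3])^2 + (ys - p[4])^2
    J <- sw * cbind(1, E,
                    p[2] * E * (xs - p[3]) / p[5]^2,
                    p[2] * E * (ys - p[4]) / p[5]^2,
                    p[2] * E * d2 / p[5]^3)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    pn <- p - as.vector(step)
    newv <- sum((sw * (model(pn) - zz))^2)
    if (is.finite(newv) && newv < cur) {
      done <- (cur - newv) < 1e-10 * (cur + 1e-12)
      p <- pn; cur <- newv
      lambda <- max(lambda / 10, 1e-12)
      if (done) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e9) break
    }
  }
  p[5] <- abs(p[5])
  conv <- is.finite(cur) && p[2] > 0 && p[5] > 0 &&
    p[3] >= 0.5 && p[3] <= nc + 0.5 && p[4] >= 0.5 && p[4] <= nr + 0.5
  list(b = p[1], A = p[2], x0 = p[3], y0 = p[4], s = p[5], converged = conv)
}

# Thompson-style localization precision (nm):
# sigma_loc^2 = (s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2)
thompson_precision <- function(sigma_nm, photons, pixel_nm, background_photons) {
  sqrt((sigma_nm^2 + pixel_nm^2 / 12) / photons +
         8 * pi * sigma_nm^4 * background_photons^2 / (pixel_nm^2 * photons^2))
}

empty_localization_table <- function() {
  data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             sigma_nm = numeric(0), photons = numeric(0),
             uncertainty_nm = numeric(0), background = numeric(0))
}

#' Detect and fit single-molecule localizations in a raw movie
#'
#' Per frame: converts A/D counts to photons, applies a difference-of-Gaussians
#' band-pass, finds 8-connected local maxima above a robust noise threshold,
#' and least-squares fits a 2D Gaussian in a window around each maximum. The
#' per-record localization uncertainty is computed from the Thompson-style
#' precision formula using the fitted PSF width, photon count, and local
#' background.
#'
#' @param movie an `smlm_movie` (from [generate_smlm_movie()]) or a 3D array
#'   of A/D counts.
#' @param camera a [camera_model()]; defaults to the movie's own.
#' @param detect_threshold detection threshold in robust standard deviations
#'   (MAD) of the band-passed frame.
#' @param fit_window side length (pixels, odd) of the fitting window.
#' @param sigma_small,sigma_large band-pass scales in pixels.
#' @return a localization table: data frame with columns
#'   `frame, x_nm, y_nm, sigma_nm, photons, uncertainty_nm, background`.
#'   The number of dropped (non-converged) fits is attached as attribute
#'   `n_dropped`.
#' @export
detect_and_fit <- function(movie, camera = NULL, detect_threshold = 5,
                           fit_window = 7, sigma_small = 1, sigma_large = 2.5) {
  if (inherits(movie, "smlm_movie")) {
    if (is.null(camera)) camera <- movie$camera
    dat <- movie$data
  } else {
    dat <- movie
    if (is.null(camera)) stop("`camera` must be supplied for a raw array")
  }
  stopifnot(length(dim(dat)) == 3L, fit_window %% 2 == 1)
  a <- camera$pixel_size_nm
  half <- (fit_window - 1L) %/% 2L
  nr <- dim(dat)[1]; nc <- dim(dat)[2]
  out <- list(); dropped <- 0L
  for (f in seq_len(dim(dat)[3])) {
    ph <- adu_to_photons(dat[, , f], camera)
    dg <- dog_filter(ph, sigma_small, sigma_large)
    noise <- stats::mad(dg)
    thr <- stats::median(dg) + detect_threshold * noise
    mx <- local_maxima(dg, thr)
    if (nrow(mx) == 0) next
    keep <- mx[, 1] > half & mx[, 1] <= nr - half &
            mx[, 2] > half & mx[, 2] <= nc - half
    mx <- mx[keep, , drop = FALSE]
    for (k in seq_len(nrow(mx))) {
      i0 <- mx[k, 1]; j0 <- mx[k, 2]
      win <- ph[(i0 - half):(i0 + half), (j0 - half):(j0 + half)]
      fit <- fit_gaussian2d(win)
      if (!fit$converged) { dropped <- dropped + 1L; next }
      gx <- (j0 - half - 1) + fit$x0   # global pixel coordinate (1-based)
      gy <- (i0 - half - 1) + fit$y0
      N <- 2 * pi * fit$A * fit$s^2
      if (!is.finite(N) || N <= 0) { dropped <- dropped + 1L; next }
      sig_nm <- fit$s * a
      bg <- max(0, fit$b)
      out[[length(out) + 1L]] <- data.frame(
        frame = f,
        x_nm = (gx - 0.5) * a,
        y_nm = (gy - 0.5) * a,
        sigma_nm = sig_nm,
        photons = N,
        uncertainty_nm = thompson_precision(sig_nm, N, a, bg),
        background = bg)
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else empty_localization_table()
  if (dropped > 0)
    message(sprintf("detect_and_fit: %d non-converged fits dropped", dropped))
  attr(tab, "n_dropped") <- dropped
  tab
}
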