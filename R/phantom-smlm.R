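#' Specification of a synthetic SMLM blinking movie
#'
#' Describes a stochastic optical reconstruction (STORM) acquisition of
#' blinking emitters: positions, photon budget, two-state telegraph blinking
#' kinetics, movie length, camera model and background. Defaults mirror the
#' acquisition the package emulates (20 ms exposure; camera of
#' [camera_model()]); movie length is chosen per experiment.
#'
#' @param emitters data frame with columns `x_nm`, `y_nm`: true emitter
#'   positions. See [emitters_on_fibers()] to place emitters on a fiber
#'   phantom's centerlines.
#' @param n_frames number of frames (>= 1).
#' @param mean_photons mean photons emitted per active frame.
#' @param on_rate per-frame probability that a dark emitter switches on.
#' @param mean_on_frames mean duration of an on-state, in frames (geometric);
#'   `Inf` keeps emitters on permanently once switched on.
#' @param bleach_frames mean total number of on-frames an emitter survives
#'   before irreversible photobleaching (geometric); `Inf` disables
#'   bleaching. Finite values make localization density saturate over the
#'   movie, as fluorophore depletion does in a real acquisition.
#' @param always_on if `TRUE`, all emitters are active in every frame.
#' @param exposure_ms exposure time per frame (metadata only).
#' @param background_photons mean background photons per pixel per frame.
#' @param field_px movie size `c(rows, cols)` in camera pixels.
#' @param psf_sigma_nm Gaussian PSF standard deviation of the microscope (nm).
#' @param camera a [camera_model()].
#' @param seed integer seed; identical spec + seed gives an identical movie.
#' @return an object of class `smlm_movie_spec`.
#' @export
smlm_movie_spec <- function(emitters,
                            n_frames,
                            mean_photons = 1000,
                            on_rate = 0.02,
                            mean_on_frames = 1,
                            bleach_frames = Inf,
                            always_on = FALSE,
                            exposure_ms = 20,
                            background_photons = 2,
                            field_px = c(64L, 64L),
                            psf_sigma_nm = 130,
                            camera = camera_model(),
                            seed = 1L) {
  emitters <- as.data.frame(emitters)
  if (nrow(emitters) > 0)
    stopifnot(all(c("x_nm", "y_nm") %in% names(emitters)))
  stopifnot(n_frames >= 1, mean_photons >= 0, background_photons >= 0,
            inherits(camera, "camera_model"), psf_sigma_nm > 0,
            length(field_px) == 2L, all(field_px >= 1))
  structure(list(emitters = emitters, n_frames = as.integer(n_frames),
                 mean_photons = mean_photons, on_rate = on_rate,
                 mean_on_frames = mean_on_frames,
                 bleach_frames = bleach_frames, always_on = always_on,
                 exposure_ms = exposure_ms,
                 background_photons = background_photons,
                 field_px = as.integer(field_px),
                 psf_sigma_nm = psf_sigma_nm, camera = camera,
                 seed = as.integer(seed)),
            class = "smlm_movie_spec")
}

#' Place emitters along the centerlines of a fiber phantom
#'
#' @param phantom a [fiber_network_phantom()].
#' @param per_um mean number of emitters per um of fiber length.
#' @param jitter_nm Gaussian positional jitter perpendicular to the fiber
#'   (defaults to the phantom's cross-section sigma).
#' @param seed integer seed.
#' @return data frame with `x_nm`, `y_nm`.
#' @export
emitters_on_fibers <- function(phantom, per_um = 20, jitter_nm = NULL,
                               seed = 1L) {
  stopifnot(inherits(phantom, "fiber_phantom"))
  if (is.null(jitter_nm)) jitter_nm <- phantom$sigma_nm
  set.seed(seed)
  fib <- phantom$fibers
  pts <- lapply(seq_len(nrow(fib)), function(k) {
    len <- sqrt((fib$x1[k] - fib$x0[k])^2 + (fib$y1[k] - fib$y0[k])^2)
    n <- stats::rpois(1L, per_um * len)
    if (n == 0) return(NULL)
    t <- stats::runif(n)
    x <- fib$x0[k] + t * (fib$x1[k] - fib$x0[k])
    y <- fib$y0[k] + t * (fib$y1[k] - fib$y0[k])
    # unit normal to the segment
    nx <- -(fib$y1[k] - fib$y0[k]); ny <- fib$x1[k] - fib$x0[k]
    nl <- sqrt(nx^2 + ny^2); if (nl == 0) { nx <- 1; ny <- 0; nl <- 1 }
    off <- stats::rnorm(n, 0, jitter_nm / 1000)
    data.frame(x_nm = (x + off * nx / nl) * 1000,
               y_nm = (y + off * ny / nl) * 1000)
  })
  do.call(rbind, pts)
}

#' Simulate a blinking SMLM movie with full ground truth
#'
#' Each frame is rendered in photon units (integrated Gaussian PSF per active
#' emitter plus uniform background) and converted to camera A/D counts:
#' `ADU = Poisson(photons) / gain + baseline + read noise`. The per-frame
#' active-emitter table (with true positions and injected photon counts) is
#' returned as ground truth.
#'
#' @param spec an [smlm_movie_spec()].
#' @param noise if `FALSE`, Poisson shot noise and read noise are disabled
#'   (expected photons are converted deterministically), which is useful for
#'   photon-bookkeeping checks.
#' @return an object of class `smlm_movie`: list with `data` (rows x cols x
#'   frames array, A/D counts), `camera`, `spec`, and `truth` (data frame
#'   `frame, id, x_nm, y_nm, photons`).
#' @export
generate_smlm_movie <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "smlm_movie_spec"))
  set.seed(spec$seed)
  cam <- spec$camera
  a <- cam$pixel_size_nm
  nr <- spec$field_px[1]; nc <- spec$field_px[2]
  ne <- nrow(spec$emitters)
  s <- spec$psf_sigma_nm

  # telegraph blinking states, ne x n_frames
  active <- matrix(FALSE, max(ne, 1L), spec$n_frames)
  if (ne > 0) {
    if (spec$always_on) {
      active[] <- TRUE
    } else {
      p_off <- if (is.infinite(spec$mean_on_frames)) 0 else 1 / spec$mean_on_frames
      p_bleach <- if (is.infinite(spec$bleach_frames)) 0 else 1 / spec$bleach_frames
      state <- rep(FALSE, ne)
      alive <- rep(TRUE, ne)
      for (f in seq_len(spec$n_frames)) {
        u <- stats::runif(ne)
        state <- ifelse(state, u > p_off, alive & u < spec$on_rate)
        active[, f] <- state
        if (p_bleach > 0) {
          died <- state & stats::runif(ne) < p_bleach
          alive <- alive & !died
          state <- state & !died
        }
      }
    }
  }

  xe <- if (ne) spec$emitters$x_nm else numeric(0)
  ye <- if (ne) spec$emitters$y_nm else numeric(0)
  xedges <- (0:nc) * a
  yedges <- (0:nr) * a
  movie <- array(0, c(nr, nc, spec$n_frames))
  truth <- vector("list", spec$n_frames)

  for (f in seq_len(spec$n_frames)) {
    img <- matrix(spec$background_photons, nr, nc)
    idx <- if (ne) which(active[, f]) else integer(0)
    if (length(idx)) {
      for (e in idx) {
        # photon flux integrated over pixel areas (exact bookkeeping)
        fx <- diff(stats::pnorm(xedges, xe[e], s))
        fy <- diff(stats::pnorm(yedges, ye[e], s))
        img <- img + spec$mean_photons * (fy %o% fx)
      }
      truth[[f]] <- data.frame(frame = f, id = idx,
                               x_nm = xe[idx], y_nm = ye[idx],
                               photons = spec$mean_photons)
    }
    if (noise) {
      adu <- stats::rpois(length(img), img) / cam$photoelectrons_per_adu +
        cam$baseline_adu +
        stats::rnorm(length(img), 0, cam$read_noise_e / cam$photoelectrons_per_adu)
    } else {
      adu <- img / cam$photoelectrons_per_adu + cam$baseline_adu
    }
    movie[, , f] <- adu
  }

  structure(list(data = movie, camera = cam, spec = spec,
                 pixel_size_nm = a,
                 truth = if (length(truth)) do.call(rbind, truth) else NULL),
            class = "smlm_movie")
}

#' @export
print.smlm_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<smlm_movie> %d x %d px, %d frames, %d emitters, %.4g nm/px\n",
              d[1], d[2], d[3], nrow(x$spec$emitters), x$pixel_size_nm))
  invisible(x)
}
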