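#' Mass spectrometry imaging cube
#'
#' A pixel grid in which every pixel carries a full mass spectrum on a shared
#' (continuous-mode) m/z axis.
#'
#' @param intensity array `rows x cols x length(mz)` of non-negative
#'   intensities.
#' @param mz strictly increasing m/z axis.
#' @param pixel_size_um pixel size in um.
#' @param metadata named list (mass range, polarity, capillary temperature
#'   label, ...).
#' @param mask optional logical matrix of valid pixels.
#' @return an object of class `msi_cube`.
#' @export
msi_cube <- function(intensity, mz, pixel_size_um = 40, metadata = list(),
                     mask = NULL) {
  stopifnot(length(dim(intensity)) == 3L, dim(intensity)[3] == length(mz),
            !is.unsorted(mz, strictly = TRUE), min(intensity) >= 0)
  if (is.null(mask)) mask <- matrix(TRUE, dim(intensity)[1], dim(intensity)[2])
  structure(list(intensity = intensity, mz = mz,
                 pixel_size_um = pixel_size_um, metadata = metadata,
                 mask = mask, normalized = FALSE),
            class = "msi_cube")
}

#' @export
print.msi_cube <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(paste0("<msi_cube> %d x %d px (%.4g um), %d m/z bins ",
                     "[%.4g, %.4g]%s\n"),
              d[1], d[2], x$pixel_size_um, d[3], min(x$mz), max(x$mz),
              if (x$normalized) ", TIC-normalized" else ""))
  invisible(x)
}

#' Specification of a synthetic MSI cube
#'
#' Defines ion species with theoretical m/z values, spatial localization
#' patterns (core-only, uniform, or enriched at the invasive front), and a
#' Poisson-like noise model over a spheroid-section geometry.
#'
#' @param dims grid `c(rows, cols)`.
#' @param pixel_size_um pixel size (um).
#' @param species data frame with `name`, `mz`, `pattern` (one of
#'   `"core"`, `"uniform"`, `"front"`), `intensity` (base peak intensity).
#' @param mz_range mass axis range.
#' @param bin_width m/z bin width.
#' @param core_radius_frac core radius as a fraction of the grid half-size.
#' @param front_width_frac width of the invasive-front annulus (fraction).
#' @param noise mean intensity of the uniform noise floor per bin.
#' @param peak_sigma_bins peak width (Gaussian sigma) in bins.
#' @param seed integer seed.
#' @return an object of class `msi_cube_spec`.
#' @export
msi_cube_spec <- function(dims = c(24, 24), pixel_size_um = 40,
                          species = data.frame(
                            name = c("FA 16:1", "PE O-40:5", "SM 34:1;O2"),
                            mz = c(253.2190, 778.5570, 703.5719),
                            pattern = c("core", "uniform", "front"),
                            intensity = c(100, 80, 60)),
                          mz_range = c(50, 1200), bin_width = 0.05,
                          core_radius_frac = 0.45, front_width_frac = 0.35,
                          noise = 0.2, peak_sigma_bins = 1,
                          seed = 1L) {
  species <- as.data.frame(species)
  stopifnot(all(c("name", "mz", "pattern", "intensity") %in% names(species)),
            all(species$mz > mz_range[1] & species$mz < mz_range[2]),
            all(species$intensity >= 0),
            all(species$pattern %in% c("core", "uniform", "front")))
  structure(list(dims = as.integer(dims), pixel_size_um = pixel_size_um,
                 species = species, mz_range = mz_range,
                 bin_width = bin_width,
                 core_radius_frac = core_radius_frac,
                 front_width_frac = front_width_frac,
                 noise = noise, peak_sigma_bins = peak_sigma_bins,
                 seed = as.integer(seed)),
            class = "msi_cube_spec")
}

#' Simulate an MSI cube with ground truth
#'
#' Renders each species as a Gaussian mass peak centred on its theoretical
#' m/z, with per-pixel amplitude set by its spatial pattern over a disk-shaped
#' section (core disk, uniform section, or front annulus), plus Poisson noise.
#'
#' @param spec an [msi_cube_spec()].
#' @return an `msi_cube`; ground truth (core/front/section masks, spec) is
#'   attached as attribute `ground_truth`.
#' @export
generate_msi_cube <- function(spec) {
  stopifnot(inherits(spec, "msi_cube_spec"))
  set.seed(spec$seed)
  nr <- spec$dims[1]; nc <- spec$dims[2]
  mz <- seq(spec$mz_range[1], spec$mz_range[2], by = spec$bin_width)
  if (any(diff(sort(spec$species$mz)) < spec$bin_width))
    warning("species closer than one m/z bin overlap")
  # section geometry (normalized radius about the grid centre)
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  rad <- outer(seq_len(nr), seq_len(nc),
               function(i, j) sqrt(((i - ci) / (nr / 2))^2 +
                                     ((j - cj) / (nc / 2))^2))
  core <- rad <= spec$core_radius_frac
  front <- rad > spec$core_radius_frac &
    rad <= spec$core_radius_frac + spec$front_width_frac
  section <- core | front

  cube <- array(0, c(nr, nc, length(mz)))
  for (k in seq_len(nrow(spec$species))) {
    sp <- spec$species[k, ]
    amp <- matrix(0, nr, nc)
    if (sp$pattern == "core") amp[core] <- sp$intensity
    if (sp$pattern == "uniform") amp[section] <- sp$intensity
    if (sp$pattern == "front") {
      amp[front] <- sp$intensity
      amp[core] <- 0.25 * sp$intensity   # present but weaker in the core
    }
    b0 <- which.min(abs(mz - sp$mz))
    bb <- max(1, b0 - 4 * spec$peak_sigma_bins):
      min(length(mz), b0 + 4 * spec$peak_sigma_bins)
    shape <- exp(-((mz[bb] - sp$mz) / (spec$peak_sigma_bins * spec$bin_width))^2 / 2)
    for (b in seq_along(bb))
      cube[, , bb[b]] <- cube[, , bb[b]] + amp * shape[b]
  }
  # sparse uniform noise floor over the section
  nnz <- round(spec$noise * sum(section))
  if (nnz > 0) {
    px <- which(section, arr.ind = TRUE)
    sel <- px[sample(nrow(px), nnz, replace = TRUE), , drop = FALSE]
    bins <- sample(length(mz), nnz, replace = TRUE)
    for (k in seq_len(nnz))
      cube[sel[k, 1], sel[k, 2], bins[k]] <-
        cube[sel[k, 1], sel[k, 2], bins[k]] + stats::rexp(1, 1)
  }
  cube[] <- stats::rpois(length(cube), cube * 50) / 50
  out <- msi_cube(cube, mz, spec$pixel_size_um,
                  metadata = list(mass_range = spec$mz_range),
                  mask = section)
  attr(out, "ground_truth") <- list(core = core, front = front,
                                    section = section, spec = spec)
  out
}

#' Total-ion-current normalization
#'
#' Divides each pixel's spectrum by its summed intensity so that every
#' unmasked pixel's spectrum sums to one. Zero-TIC pixels are masked out and
#' counted, not divided.
#'
#' @param cube an `msi_cube`.
#' @return the normalized `msi_cube` (attribute `n_masked` counts newly
#'   masked pixels).
#' @export
tic_normalize <- function(cube) {
  stopifnot(inherits(cube, "msi_cube"))
  tic <- apply(cube$intensity, c(1, 2), sum)
  zero <- tic <= 0
  n_new <- sum(zero & cube$mask)
  if (n_new > 0)
    warning(sprintf("%d zero-TIC pixel(s) masked", n_new))
  tic[zero] <- 1
  cube$intensity <- cube$intensity / as.vector(tic)  # recycles over bins
  cube$mask <- cube$mask & !zero
  cube$normalized <- TRUE
  attr(cube, "n_masked") <- n_new
  cube
}

#' Mean intensity in an m/z window over a section mask
#'
#' Sums each pixel's (normalized) spectrum over the window and averages over
#' the masked pixels, the quantity used to compare overall signal across
#' acquisition conditions within broad m/z regions.
#'
#' @param cube an `msi_cube`.
#' @param window `c(lo, hi)` m/z window (within the axis).
#' @param section_mask logical matrix; defaults to the cube's mask.
#' @param group optional group label (e.g. capillary temperature).
#' @return an object of class `window_stat` with `mean_intensity`, `window`,
#'   `n_pixels`, `group`.
#' @export
window_mean <- function(cube, window, section_mask = NULL, group = NA) {
  stopifnot(inherits(cube, "msi_cube"), length(window) == 2L,
            window[1] < window[2])
  if (window[1] < min(cube$mz) || window[2] > max(cube$mz))
    stop("window outside the mass axis")
  if (is.null(section_mask)) section_mask <- cube$mask
  if (!any(section_mask)) stop("empty section mask")
  bins <- which(cube$mz >= window[1] & cube$mz <= window[2])
  ws <- apply(cube$intensity[, , bins, drop = FALSE], c(1, 2), sum)
  structure(list(mean_intensity = mean(ws[section_mask]),
                 window = window, n_pixels = sum(section_mask),
                 group = group),
            class = "window_stat")
}

#' @export
print.window_stat <- function(x, ...) {
  cat(sprintf("<window_stat> [%.4g, %.4g] m/z: mean %.4g over %d px%s\n",
              x$window[1], x$window[2], x$mean_intensity, x$n_pixels,
              if (!is.na(x$group)) paste0(" (group ", x$group, ")") else ""))
  invisible(x)
}

#' Pairwise comparison of window statistics across conditions
#'
#' Groups per-section window means by condition (e.g. transfer-capillary
#' temperature) and runs the shared pairwise testing engine
#' ([compare_groups()]) with star annotations.
#'
#' @param stats list of `window_stat` objects (with `group` set), or a data
#'   frame with `mean_intensity` and `group`.
#' @param ... passed to [compare_groups()].
#' @return the pairwise comparison table.
#' @export
temperature_series <- function(stats, ...) {
  if (is.data.frame(stats)) {
    df <- stats
  } else {
    df <- data.frame(
      mean_intensity = vapply(stats, `[[`, numeric(1), "mean_intensity"),
      group = vapply(stats, function(s) as.character(s$group), character(1)))
  }
  tab <- table(df$group)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    warning("group(s) with n < 2 excluded: ", paste(drop, collapse = ", "))
    df <- df[!(df$group %in% drop), ]
  }
  compare_groups(df$mean_intensity, df$group, ...)
}

#' Extract an ion image at a target m/z with ppm tolerance
#'
#' Integrates each pixel's (normalized) spectrum over the window
#' `target_mz * (1 +/- ppm * 1e-6)`.
#'
#' @param cube an `msi_cube`.
#' @param target_mz target m/z (within the axis).
#' @param ppm tolerance in parts per million.
#' @return an object of class `ion_image`: `image` (`pixel_image`),
#'   `target_mz`, `ppm`, `window`.
#' @export
ion_image <- function(cube, target_mz, ppm = 5) {
  stopifnot(inherits(cube, "msi_cube"))
  lo <- target_mz * (1 - ppm * 1e-6)
  hi <- target_mz * (1 + ppm * 1e-6)
  if (lo < min(cube$mz) || hi > max(cube$mz))
    stop("ppm window exits the mass range")
  bins <- which(cube$mz >= lo & cube$mz <= hi)
  img <- if (length(bins))
    apply(cube$intensity[, , bins, drop = FALSE], c(1, 2), sum)
  else matrix(0, dim(cube$intensity)[1], dim(cube$intensity)[2])
  structure(list(image = pixel_image(img, cube$pixel_size_um),
                 target_mz = target_mz, ppm = ppm, window = c(lo, hi)),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f +/- %g ppm [%.4f, %.4f]\n",
              x$target_mz, x$ppm, x$window[1], x$window[2]))
  invisible(x)
}

#' Annotate observed peaks against a mass table
#'
#' Matches each observed m/z to all table entries within the ppm tolerance
#' (monoisotopic masses; the table is user-supplied). Ambiguous matches are
#' all reported, not resolved.
#'
#' @param peaks numeric observed m/z values.
#' @param mass_table data frame with `name` and `mz` (theoretical).
#' @param ppm mass tolerance in ppm.
#' @return data frame `observed_mz, name, theoretical_mz, ppm_error`
#'   (zero rows when nothing matches).
#' @export
annotate_peaks <- function(peaks, mass_table, ppm = 5) {
  mass_table <- as.data.frame(mass_table)
  if (nrow(mass_table) == 0) stop("empty mass table")
  stopifnot(all(c("name", "mz") %in% names(mass_table)))
  rows <- lapply(peaks, function(p) {
    err <- (p - mass_table$mz) / mass_table$mz * 1e6
    hit <- abs(err) <= ppm
    if (!any(hit)) return(NULL)
    data.frame(observed_mz = p, name = mass_table$name[hit],
               theoretical_mz = mass_table$mz[hit], ppm_error = err[hit])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(observed_mz = numeric(0), name = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0))
  rownames(out) <- NULL
  out
}
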