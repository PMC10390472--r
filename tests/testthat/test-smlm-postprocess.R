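make_table <- function(x, y, frame = NULL, photons = 500, sigma = 130) {
  n <- length(x)
  data.frame(frame = if (is.null(frame)) rep(1L, n) else frame,
             x_nm = x, y_nm = y, sigma_nm = rep_len(sigma, n),
             photons = rep_len(photons, n),
             uncertainty_nm = rep_len(5, n), background = rep_len(1, n))
}

test_that("photon/sigma filter keeps exactly the records satisfying the strict predicate", {
  tab <- make_table(1:6 * 100, 1:6 * 100,
                    photons = c(90, 100, 101, 500, 500, 1e4),
                    sigma = c(120, 120, 120, 50, 260, 250))
  # brute-force enumeration of the predicate
  keep <- tab$photons > 100 & tab$sigma_nm > 50 & tab$sigma_nm < 250
  out <- filter_localizations(tab)
  expect_equal(nrow(out), sum(keep))
  expect_equal(out$x_nm, tab$x_nm[keep])
  # boundary records are excluded (strict inequalities)
  expect_false(any(out$photons == 100) || any(out$sigma_nm %in% c(50, 250)))
  # idempotence
  expect_identical(filter_localizations(out), out)
  expect_warning(filter_localizations(make_table(1, 1, photons = 10)), "removed")
})

test_that("DBSCAN filter removes isolated points and matches the naive oracle", {
  set.seed(4)
  # 20 points inside a 30 nm disk plus one point 1 um away
  th <- runif(20, 0, 2 * pi); r <- 15 * sqrt(runif(20))
  tab <- make_table(c(1000 + r * cos(th), 2000), c(1000 + r * sin(th), 1000))
  out <- dbscan_filter(tab, epsilon_nm = 50, min_pts = 5)
  expect_equal(nrow(out), 20)
  expect_true(all(out$x_nm < 1500))

  # mutually distant points are all noise
  far <- make_table(seq(0, 2000, by = 100), seq(0, 6000, by = 300))
  expect_equal(nrow(dbscan_filter(far, 50, 5)), 0)

  # random table: identical to the O(n^2) oracle, several parameter settings
  for (n in c(120, 400)) {
    set.seed(n)
    x <- runif(n, 0, 2000); y <- runif(n, 0, 2000)
    tab <- make_table(x, y)
    for (prm in list(c(50, 5), c(120, 3), c(200, 8))) {
      mine <- dbscan_filter(tab, prm[1], prm[2])
      oracle <- naive_dbscan_members(x, y, prm[1], prm[2])
      expect_equal(mine$x_nm, x[oracle])
      # idempotence on the filtered output
      expect_equal(nrow(dbscan_filter(mine, prm[1], prm[2])), nrow(mine))
    }
  }
})

test_that("rendering deposits unit mass per record and is linear", {
  tab <- make_table(500, 500)
  img <- render_localizations(tab, pixel_nm = 10, uncertainty_nm = 10)
  expect_equal(sum(img$data), 1, tolerance = 1e-3)
  # two coincident records double the peak exactly
  tab2 <- make_table(c(500, 500), c(500, 500))
  img2 <- render_localizations(tab2, 10, 10,
                               extent_nm = attr(img, "extent_nm"))
  expect_equal(max(img2$data), 2 * max(img$data))
  expect_equal(sum(img2$data), 2, tolerance = 1e-3)
  # grid sum matches the analytic Gaussian integral over the extent
  ext <- attr(img, "extent_nm")
  analytic <- (stats::pnorm(ext[2], 500, 10) - stats::pnorm(ext[1], 500, 10)) *
    (stats::pnorm(ext[4], 500, 10) - stats::pnorm(ext[3], 500, 10))
  expect_equal(sum(img$data), analytic, tolerance = 1e-6)
})

test_that("Thompson precision matches the closed form and its limits", {
  tab <- make_table(1:50 * 10, 1:50 * 10, photons = 1000, sigma = 150)
  cam <- camera_model()
  # direct evaluation of the stated formula
  expect_equal(estimate_precision(tab, cam, background_photons_per_px = 0),
               sqrt((150^2 + 97^2 / 12) / 1000))
  expect_equal(sqrt((150^2 + 97^2 / 12) / 1000), 4.825, tolerance = 1e-3)
  # shot-noise limit: b = 0 and vanishing pixel size -> sigma / sqrt(N)
  tiny <- camera_model(pixel_size_nm = 1e-3)
  expect_equal(estimate_precision(tab, tiny, background_photons_per_px = 0),
               150 / sqrt(1000), tolerance = 1e-6)
})

test_that("Nyquist resolution follows the 2D density convention", {
  tab <- make_table(runif(400, 0, 1000), runif(400, 0, 1000))
  expect_equal(estimate_nyquist(tab, roi_area_um2 = 1), 100)  # rho = 400/um^2
  # doubling density divides resolution by sqrt(2)
  expect_equal(estimate_nyquist(tab, 2) / estimate_nyquist(tab, 1), sqrt(2))
  # 4x fewer localizations, same area: resolution x2
  expect_equal(estimate_nyquist(tab[1:100, ], 1) / estimate_nyquist(tab, 1), 2)
  expect_error(estimate_nyquist(tab[0, ], 1), "no localizations")
})

test_that("combined resolution is the quadrature sum", {
  r <- combined_resolution(3, 4)
  expect_equal(r$combined_resolution, 5)
  expect_equal(combined_resolution(10, 10)$combined_resolution, sqrt(200))
  expect_equal(combined_resolution(10, 1e-9)$combined_resolution, 10,
               tolerance = 1e-6)
  expect_error(combined_resolution(0, 4))
  expect_error(combined_resolution(3, -1))
  # invariant: combined^2 = precision^2 + nyquist^2
  expect_equal(r$combined_resolution^2,
               r$localization_precision^2 + r$nyquist_resolution^2)
})

test_that("drift correction recovers injected linear drift and conserves records", {
  ph <- single_fiber_phantom(sigma_nm = 30, pixel_size = 0.01,
                             field = c(6, 6), y_um = 3)
  em <- emitters_on_fibers(ph, per_um = 60, seed = 3)
  nf <- 500
  spec <- smlm_movie_spec(em, n_frames = nf, mean_photons = 1500,
                          on_rate = 0.02, background_photons = 1,
                          field_px = c(64, 64), seed = 9)
  tab <- filter_localizations(detect_and_fit(generate_smlm_movie(spec)))

  # zero drift: estimated displacements stay below half a histogram bin
  dc0 <- drift_correct(tab, n_bins = 5, hist_px_nm = 20)
  expect_true(all(abs(c(dc0$trace$dx_nm, dc0$trace$dy_nm)) < 10))
  expect_identical(dc0$trace$dx_nm[1], 0)

  # injected 100 nm linear drift over the movie
  drift <- 100 * (tab$frame - 1) / (nf - 1)
  tabd <- tab; tabd$x_nm <- tabd$x_nm + drift
  dc <- drift_correct(tabd, n_bins = 5, hist_px_nm = 20)
  expect_equal(nrow(dc$table), nrow(tabd))   # conservation
  # recovered total drift from the bin displacements
  span <- dc$trace$frame_center[5] - dc$trace$frame_center[1]
  total <- dc$trace$dx_nm[5] * (nf - 1) / span
  expect_lt(abs(total - 100), 10)
  expect_true(all(abs(dc$trace$dy_nm) < 10))

  # fixed point: re-estimating drift on the corrected table gives ~0
  dc2 <- drift_correct(dc$table, n_bins = 5, hist_px_nm = 20)
  expect_true(all(abs(dc2$trace$dx_nm) < 10))
})

test_that("a sparse temporal bin is interpolated with a warning", {
  set.seed(1)
  tab <- make_table(runif(200, 0, 3000), runif(200, 0, 3000),
                    frame = sample(c(1:40, 81:200), 200, replace = TRUE))
  expect_warning(drift_correct(tab, n_bins = 5), "interpolated")
})

test_that("the end-to-end chain reproduces the quadrature fiber width", {
  ph <- single_fiber_phantom(sigma_nm = 30, pixel_size = 0.01,
                             field = c(6, 6), y_um = 3)
  em <- emitters_on_fibers(ph, per_um = 2500, seed = 2)
  spec <- smlm_movie_spec(em, n_frames = 6000, mean_photons = 1500,
                          on_rate = 1e-4, mean_on_frames = 1, bleach_frames = 3,
                          background_photons = 1, field_px = c(64, 64), seed = 3)
  mov <- generate_smlm_movie(spec)
  tab <- dbscan_filter(filter_localizations(detect_and_fit(mov)))
  img <- render_localizations(tab, 10, 10,
                              extent_nm = c(min(tab$x_nm) - 400, max(tab$x_nm) + 400,
                                            min(tab$y_nm) - 400, max(tab$y_nm) + 400))
  rep <- fiber_width_report(img, auto_transects(img, 25, length_um = 0.4, seed = 5))
  prec <- estimate_precision(tab, mov$camera)
  expected <- sigma_to_fwhm(sqrt(30^2 + 10^2 + prec^2)) / 1000
  expect_equal(rep$mean_fwhm, expected, tolerance = 0.1)
})
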