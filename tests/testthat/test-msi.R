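fine_spec <- function(seed = 1, species = NULL) {
  if (is.null(species))
    species <- data.frame(name = c("FA 16:1", "PE O-40:5", "SM 34:1;O2"),
                          mz = c(253.2190, 778.5570, 703.5719),
                          pattern = c("core", "uniform", "front"),
                          intensity = c(100, 80, 60))
  msi_cube_spec(dims = c(14, 14), species = species,
                mz_range = c(240, 800), bin_width = 0.05, seed = seed)
}

test_that("the MSI phantom is deterministic and places peaks on the mass axis", {
  a <- generate_msi_cube(fine_spec(3)); b <- generate_msi_cube(fine_spec(3))
  expect_identical(a$intensity, b$intensity)
  gt <- attr(a, "ground_truth")
  # mean spectrum peak within one bin of each theoretical m/z
  sp <- apply(a$intensity, 3, sum)
  for (mz in c(253.2190, 778.5570, 703.5719)) {
    bins <- which(abs(a$mz - mz) <= 2)
    pk <- a$mz[bins[which.max(sp[bins])]]
    expect_lte(abs(pk - mz), 0.05)
  }
  # core-only species has only noise-floor signal outside the core
  co <- ion_image(a, 253.2190, ppm = 400)$image$data
  expect_lt(mean(co[!gt$core & gt$section]), 0.05 * mean(co[gt$core]))
  # species closer than one bin warn
  twin <- data.frame(name = c("a", "b"), mz = c(500.00, 500.02),
                     pattern = c("uniform", "uniform"), intensity = c(10, 10))
  expect_warning(generate_msi_cube(fine_spec(1, twin)), "overlap")
})

test_that("TIC normalization conserves unit mass per pixel and is scale-invariant", {
  cube <- generate_msi_cube(fine_spec(2))
  cn <- tic_normalize(cube)
  tic <- apply(cn$intensity, c(1, 2), sum)
  expect_true(all(abs(tic[cn$mask] - 1) < 1e-9))
  # scaling one pixel's raw spectrum leaves its normalized spectrum unchanged
  cube2 <- cube
  px <- which(cube$mask, arr.ind = TRUE)[1, ]
  cube2$intensity[px[1], px[2], ] <- 5 * cube2$intensity[px[1], px[2], ]
  cn2 <- tic_normalize(cube2)
  expect_equal(cn2$intensity[px[1], px[2], ], cn$intensity[px[1], px[2], ])
  # an all-zero pixel is masked with a warning, not divided
  cube3 <- cube
  cube3$intensity[1, 1, ] <- 0
  cube3$mask[1, 1] <- TRUE
  expect_warning(cn3 <- tic_normalize(cube3), "masked")
  expect_false(cn3$mask[1, 1])
})

test_that("window means match a naive double loop and conserve the full axis", {
  cube <- tic_normalize(generate_msi_cube(fine_spec(4)))
  gt <- attr(cube, "ground_truth")
  ws <- window_mean(cube, c(700, 790))
  # naive oracle: explicit loops over pixels and bins
  bins <- which(cube$mz >= 700 & cube$mz <= 790)
  tot <- 0; n <- 0
  for (i in seq_len(nrow(cube$mask))) for (j in seq_len(ncol(cube$mask))) {
    if (!cube$mask[i, j]) next
    s <- 0
    for (b in bins) s <- s + cube$intensity[i, j, b]
    tot <- tot + s; n <- n + 1
  }
  expect_equal(ws$mean_intensity, tot / n)
  # full-axis window on a TIC-normalized cube has mean 1
  full <- window_mean(cube, range(cube$mz))
  expect_equal(full$mean_intensity, 1, tolerance = 1e-9)
  # windows with signal vs without
  expect_gt(window_mean(cube, c(700, 710))$mean_intensity,
            window_mean(cube, c(300, 310))$mean_intensity)
  # additivity over disjoint sub-windows (split point between bins)
  a <- window_mean(cube, c(700, 740.02))$mean_intensity
  b <- window_mean(cube, c(740.03, 790))$mean_intensity
  expect_equal(a + b, window_mean(cube, c(700, 790))$mean_intensity)
  expect_error(window_mean(cube, c(100, 300)), "outside")
  expect_error(window_mean(cube, c(300, 400),
                           matrix(FALSE, 14, 14)), "empty")
})

test_that("condition series comparisons share the stats engine", {
  set.seed(5)
  stats <- c(lapply(rnorm(8, 1, 0.05), function(v)
    structure(list(mean_intensity = v, group = "24C"), class = "window_stat")),
    lapply(rnorm(8, 3, 0.05), function(v)
      structure(list(mean_intensity = v, group = "350C"), class = "window_stat")),
    lapply(rnorm(8, 3.01, 0.05), function(v)
      structure(list(mean_intensity = v, group = "400C"), class = "window_stat")))
  res <- temperature_series(stats)
  expect_equal(nrow(res), choose(3, 2))
  expect_equal(res$annotation[res$group1 == "24C" & res$group2 == "350C"], "***")
  expect_equal(res$annotation[res$group1 == "350C" & res$group2 == "400C"], "†")
  # a group with n < 2 is excluded with a warning
  one <- c(stats, list(structure(list(mean_intensity = 1, group = "150C"),
                                 class = "window_stat")))
  expect_warning(res2 <- temperature_series(one), "excluded")
  expect_equal(nrow(res2), choose(3, 2))
})

test_that("ion images honour the ppm window", {
  # fine axis so 5 ppm windows contain bins
  spec <- msi_cube_spec(dims = c(10, 10), mz_range = c(703, 704.5),
                        bin_width = 0.001,
                        species = data.frame(name = c("SM", "other"),
                                             mz = c(703.5719, 703.5719 * (1 + 50e-6)),
                                             pattern = c("front", "uniform"),
                                             intensity = c(50, 50)),
                        noise = 0, seed = 6)
  cube <- generate_msi_cube(spec)
  ii <- ion_image(cube, 703.5719, ppm = 5)
  expect_equal(ii$window[2] - ii$target_mz, 703.5719 * 5e-6, tolerance = 1e-9)
  expect_equal(dim(ii$image$data), dim(cube$mask))
  # two species 50 ppm apart are fully separated at 5 ppm
  jj <- ion_image(cube, 703.5719 * (1 + 50e-6), ppm = 5)
  gt <- attr(cube, "ground_truth")
  core_only <- gt$core & !gt$front
  expect_gt(mean(jj$image$data[gt$section]), 0)         # uniform species present
  # front pattern: full amplitude in the annulus, quarter amplitude in core
  expect_gt(mean(ii$image$data[gt$front]), 2 * mean(ii$image$data[core_only]))
  expect_error(ion_image(cube, 703.0005, ppm = 5), "exits")
})

test_that("annotation matches within tolerance and reports ambiguity", {
  tab <- data.frame(name = c("SM 34:1;O2", "twin"),
                    mz = c(703.5719, 703.5719 * (1 + 3e-6)))
  hit <- annotate_peaks(703.5719, tab, ppm = 5)
  expect_equal(nrow(hit), 2)            # both entries within 5 ppm
  expect_equal(hit$ppm_error[1], 0)
  miss <- annotate_peaks(703.5719 * (1 + 10e-6), tab[1, ], ppm = 5)
  expect_equal(nrow(miss), 0)
  expect_error(annotate_peaks(500, tab[0, ]), "empty")
})

test_that("MSI cubes round-trip through the text bundle", {
  cube <- tic_normalize(generate_msi_cube(
    msi_cube_spec(dims = c(6, 6), mz_range = c(700, 705), bin_width = 0.01,
                  species = data.frame(name = "SM", mz = 703.5719,
                                       pattern = "uniform", intensity = 20),
                  seed = 2)))
  d <- tempfile("msi")
  write_msi(cube, d)
  back <- read_msi(d)
  expect_equal(back$intensity, cube$intensity, tolerance = 1e-12)
  expect_equal(back$mz, cube$mz)
  expect_identical(back$mask, cube$mask)
  expect_true(back$normalized)
  unlink(d, recursive = TRUE)
})
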