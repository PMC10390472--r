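test_that("preprocessing flattens constant images and suppresses salt noise", {
  img <- pixel_image(matrix(7, 128, 128), 0.1)
  out <- pore_preprocess(img, 1, 20, 30)
  expect_true(all(out$data < 1e-8))
  # single-pixel salt is attenuated relative to a fiber-scale feature
  m <- matrix(0, 128, 128); m[64, 64] <- 1          # salt
  m2 <- matrix(0, 128, 128); m2[60:68, 30:38] <- 1  # extended feature
  a <- pore_preprocess(pixel_image(m, 0.1), 2, 20, 0)
  b <- pore_preprocess(pixel_image(m2, 0.1), 2, 20, 0)
  expect_lt(max(a$data), 0.5 * max(b$data))
  expect_error(pore_preprocess(img, 20, 10, 5), "degenerate")
})

test_that("binarization recovers crisp structures and respects polarity", {
  m <- matrix(0.05, 120, 120)
  stripes <- (col(m) %% 30) < 10
  m[stripes] <- 1
  img <- pixel_image(m, 0.1)
  bin <- pore_binarize(img, window_px = 15)
  expect_gt(sum(bin$mask & stripes) / sum(bin$mask | stripes), 0.9)  # IoU
  # inverted contrast with the polarity flag gives the same mask
  inv <- pixel_image(max(m) - m, 0.1)
  bin2 <- pore_binarize(inv, window_px = 15, invert = TRUE)
  expect_identical(bin2$mask, bin$mask)
  # constant image cannot be binarized
  expect_error(pore_binarize(pixel_image(matrix(1, 50, 50), 0.1)), "all-on or all-off")
})

test_that("gap counting matches constructions and the naive scanner", {
  # vertical on-stripes: period 10 px, width 2 px, pixel 0.1 um
  m <- matrix(FALSE, 40, 60)
  m[, (col(m)[1, ] %% 10) < 2] <- TRUE
  g <- count_gaps(m, 0.1)
  # on-runs {1}, {10,11}, ..., {50,51}, {60}: six 8-px interior gaps per row
  expect_true(all(abs(g - 0.8) < 1e-12))
  expect_equal(length(g), 40 * 6)          # columns contribute none
  # checkerboard: all gaps are one pixel
  cb <- (row(matrix(0, 21, 21)) + col(matrix(0, 21, 21))) %% 2 == 0
  expect_true(all(count_gaps(cb, 0.5) == 0.5))
  # random masks against the independent run scanner, with and without border
  for (s in 1:3) {
    set.seed(s)
    rm <- matrix(runif(80 * 70) < 0.3, 80, 70)
    expect_equal(sort(count_gaps(rm, 0.2)), sort(naive_count_gaps(rm, 0.2)))
  }
  expect_error(count_gaps(matrix(TRUE, 5, 5), 0.1), "both phases")
})

test_that("exponential fit: closed-form MLE, identities, and diagnostics", {
  g <- rep(2.5, 200)
  fit <- fit_exponential(g)
  expect_equal(fit$lambda, 1 / 2.5)
  expect_equal(fit$pore_size, 2.5)
  expect_identical(fit$pore_size * fit$lambda, 1)
  expect_equal(fit$n_gaps, 200)
  set.seed(11)
  g2 <- rexp(5000, 0.5)
  fit2 <- fit_exponential(g2)
  # MLE equals the brute-force minimizer of the negative log-likelihood
  expect_equal(fit2$lambda, naive_exp_mle(g2), tolerance = 1e-4)
  expect_error(fit_exponential(rexp(50, 1)), "at least")
  expect_error(fit_exponential(c(1, -1, 2), min_gaps = 3), "positive")
  # histogram fit lands near the MLE on a clean sample
  fit3 <- fit_exponential(g2, method = "histogram")
  expect_equal(fit3$lambda, fit2$lambda, tolerance = 0.1)
})

test_that("pore size is scale-equivariant and the 1/lambda identity is exact", {
  set.seed(3)
  m <- matrix(runif(60 * 60) < 0.2, 60, 60)
  f1 <- fit_exponential(count_gaps(m, 0.1), min_gaps = 10)
  f2 <- fit_exponential(count_gaps(m, 0.3), min_gaps = 10)
  expect_equal(f2$pore_size, 3 * f1$pore_size)
  expect_equal(f1$lambda * f1$pore_size, 1)
})

test_that("adding fibers never increases the estimated pore size", {
  est <- function(msk) fit_exponential(count_gaps(msk, 0.1), min_gaps = 5)$pore_size
  # strict nesting: vertical stripes only, so added fibers can only subdivide
  # existing row gaps
  set.seed(8)
  msk <- matrix(FALSE, 60, 90)
  msk[, c(5, 30, 55, 82)] <- TRUE
  prev <- est(msk)
  for (j in c(47, 70, 12, 61, 25)) {
    msk[, j] <- TRUE
    cur <- est(msk)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
  # nested random networks: the union of two phantoms' masks has a smaller
  # pore size than either alone
  m1 <- generate_fiber_image(
    fiber_network_phantom(field_um = c(51.2, 51.2), pixel_size = 0.1,
                          gap_rate = 1 / 3, band_um = 5, seed = 1),
    "storm_render", noise = FALSE, background = 0)$data > 0.5
  m2 <- generate_fiber_image(
    fiber_network_phantom(field_um = c(51.2, 51.2), pixel_size = 0.1,
                          gap_rate = 1 / 3, band_um = 5, seed = 2),
    "storm_render", noise = FALSE, background = 0)$data > 0.5
  expect_lt(est(m1 | m2), min(est(m1), est(m2)))
})

test_that("gap-law recovery from phantom geometry is within 5% at n >= 10,000", {
  ph <- fiber_network_phantom(field_um = c(614.4, 614.4), pixel_size = 0.1,
                              gap_rate = 1 / 3, band_um = 5, seed = 7)
  fit <- fit_exponential(ph$gaps_true)
  expect_gte(fit$n_gaps, 10000)
  expect_lt(abs(fit$pore_size - 3) / 3, 0.05)
})

test_that("the full pipeline is deterministic and recovers a 2x rate contrast", {
  # pore sizes well above the pixel scale, so sub-pixel gap censoring is
  # negligible for both rates
  ph1 <- fiber_network_phantom(field_um = c(153.6, 153.6), pixel_size = 0.1,
                               gap_rate = 1 / 3, band_um = 5, seed = 5)
  img1 <- generate_fiber_image(ph1, "storm_render", noise = TRUE,
                               background = 0.05, photon_scale = 200, seed = 6)
  fit1 <- pore_size_pipeline(img1)
  fit1b <- pore_size_pipeline(img1)
  expect_identical(fit1$lambda, fit1b$lambda)   # same image, same config
  ph2 <- fiber_network_phantom(field_um = c(153.6, 153.6), pixel_size = 0.1,
                               gap_rate = 1 / 6, band_um = 5, seed = 5)
  img2 <- generate_fiber_image(ph2, "storm_render", noise = TRUE,
                               background = 0.05, photon_scale = 200, seed = 6)
  fit2 <- pore_size_pipeline(img2)
  expect_equal(fit2$pore_size / fit1$pore_size, 2, tolerance = 0.1)
  # batch mode pools gaps across images and keeps per-image fits
  pooled <- pore_size_pipeline(list(img1, img2))
  expect_equal(pooled$n_gaps, fit1$n_gaps + fit2$n_gaps)
  expect_length(pooled$per_image, 2)
})
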