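test_that("spheroid phantom honors its geometric invariants", {
  ph <- spheroid_slice_phantom(core_radius_um = 100, n_invasive_cells = 40,
                               seed = 2)
  r <- with(ph$cells, sqrt((x - ph$core_center_um[1])^2 +
                             (y - ph$core_center_um[2])^2))
  expect_true(all(r[ph$cells$invasive] > 100))
  expect_true(all(r[!ph$cells$invasive] <= 100))
  expect_identical(generate_spheroid_slices(ph, 1)[[1]]$data,
                   generate_spheroid_slices(ph, 1)[[1]]$data)
})

test_that("uniform staining gives a flat core profile, shallow penetration a rim", {
  # ideal uniform disk: flat normalized profile = 1 inside
  disk <- pixel_image(matrix(0, 250, 250), 2)
  disk$data <- spherosect:::circle_mask(disk, 250, 250, 200) * 3 + 0.01
  prof <- bisecting_profile(disk)
  inside <- abs(prof$position - max(prof$position) / 2) < 150
  expect_true(all(abs(prof$normalized[inside] - 1) < 1e-6))

  ph_pen <- spheroid_slice_phantom(field_um = c(500, 500), pixel_size = 2,
                                   core_radius_um = 200, n_core_cells = 3000,
                                   n_invasive_cells = 0, d_pen_um = 20, seed = 3)
  sl2 <- generate_spheroid_slices(ph_pen, 1, "in_3d", noise = FALSE)[[1]]
  nuc2 <- get_channel(sl2, "nuclei")
  # center intensity is far below the rim
  ctr <- nuc2$data[125, 125]
  rim <- max(nuc2$data)
  expect_lt(ctr, 0.1 * rim)
  # and all signal lies inside the core circle (no invasive cells)
  outside <- !spherosect:::circle_mask(nuc2, 250, 250, 215)
  expect_lt(max(nuc2$data[outside]), 0.05 * rim)
})

test_that("bisecting profiles are normalized to their own maximum", {
  ph <- spheroid_slice_phantom(seed = 5)
  img <- get_channel(generate_spheroid_slices(ph, 1)[[1]], "nuclei")
  prof <- bisecting_profile(img, angle_deg = 30)
  expect_equal(max(prof$normalized), 1)
  # scaling invariance
  img2 <- img; img2$data <- img2$data * 17
  prof2 <- bisecting_profile(img2, angle_deg = 30)
  expect_equal(prof2$normalized, prof$normalized)
  # all-zero line is flagged, not divided
  z <- pixel_image(matrix(0, 20, 20), 1)
  pz <- bisecting_profile(z)
  expect_true(attr(pz, "flagged"))
  expect_true(all(is.na(pz$normalized)))
})

test_that("per-slice summaries equal brute-force means and detect re-staining", {
  ph_in3d <- spheroid_slice_phantom(field_um = c(400, 400), pixel_size = 2,
                                    core_radius_um = 150, n_core_cells = 2000,
                                    n_invasive_cells = 0, d_pen_um = 15, seed = 4)
  ph_re <- spheroid_slice_phantom(field_um = c(400, 400), pixel_size = 2,
                                  core_radius_um = 150, n_core_cells = 2000,
                                  n_invasive_cells = 0, d_pen_um = 15, seed = 4)
  in3d <- generate_spheroid_slices(ph_in3d, 3, "in_3d")
  re <- generate_spheroid_slices(ph_re, 3, "restained")
  pr <- function(slices) lapply(slices, function(s)
    bisecting_profile(get_channel(s, "nuclei")))
  s_in <- per_slice_summary(pr(in3d), slices = 1:3)
  s_re <- per_slice_summary(pr(re), slices = 1:3)
  # uniform re-staining yields brighter normalized interiors
  expect_gt(mean(s_re$per_slice$mean_normalized),
            mean(s_in$per_slice$mean_normalized))
  # group means equal plain arithmetic means
  expect_equal(s_re$per_slice$mean_normalized[1],
               mean(s_re$values$mean_normalized[s_re$values$slice == 1]))
  # identical profiles give zero between-slice variance
  same <- per_slice_summary(rep(pr(re)[1], 4), slices = rep(1:2, 2))
  expect_equal(diff(same$per_slice$mean_normalized), 0)
})

test_that("signal-to-background is the ratio of region maxima", {
  m <- matrix(1, 50, 50)
  m[10:15, 10:15] <- 100   # cells
  m[40:45, 40:45] <- 10    # background structure
  img <- pixel_image(m, 1)
  sb <- signal_to_background(img,
                             data.frame(x = 12, y = 12, r = 6),
                             data.frame(x = 42, y = 42, r = 6))
  expect_equal(sb$ratio, 10)
  # signal below background gives ratio <= 1
  sb2 <- signal_to_background(img, data.frame(x = 42, y = 42, r = 5),
                              data.frame(x = 12, y = 12, r = 5))
  expect_lte(sb2$ratio, 1)
  expect_error(signal_to_background(img, data.frame(x = 12, y = 12, r = 6),
                                    data.frame(x = 13, y = 13, r = 6)),
               "disjoint")
  zero <- pixel_image(matrix(0, 20, 20), 1)
  expect_error(signal_to_background(zero, data.frame(x = 5, y = 5, r = 2),
                                    data.frame(x = 15, y = 15, r = 2)),
               "zero")
})

test_that("invasion measurement follows the 2 pi (r_front - r_core) definition", {
  m <- invasion_measurement(200, 400)
  expect_equal(m$invasive_distance_um, 2 * pi * 200)
  expect_identical(invasion_measurement(150, 150)$invasive_distance_um, 0)
  # percentile rule: ten cells at 300 um, one outlier at 1000 um
  r <- c(rep(300, 10), 1000)
  expect_equal(spherosect:::radial_percentile(r, 0.9), 300)
  # removing the farthest cell changes r_front only if it lay beyond the
  # 90th percentile
  set.seed(6)
  for (i in 1:20) {
    rr <- sort(runif(12, 100, 500))
    r90 <- spherosect:::radial_percentile(rr, 0.9)
    dropped <- spherosect:::radial_percentile(rr[-12], 0.9)
    if (max(rr) <= r90) expect_equal(dropped, r90)
  }
})

test_that("image-based invasive distance recovers constructed geometry", {
  img0 <- pixel_image(matrix(0, 200, 200), 2)
  img0$data <- spherosect:::circle_mask(img0, 200, 200, 100) + 0.01
  img1 <- img0
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  for (t in th)
    img1$data <- img1$data +
      spherosect:::circle_mask(img0, 200 + 180 * cos(t), 200 + 180 * sin(t), 6)
  inv <- invasive_distance(img0, img1)
  expect_equal(inv$invasive_distance_um, 2 * pi * (180 - 100), tolerance = 0.05)
  # identical images: nothing beyond the core, distance zero and flagged
  inv0 <- invasive_distance(img0, img0)
  expect_equal(inv0$invasive_distance_um, 0)
  expect_true(inv0$flagged)
  # rescaling pixel size scales the distance linearly
  img0b <- img0; img0b$pixel_size <- 4
  img1b <- img1; img1b$pixel_size <- 4
  inv2 <- invasive_distance(img0b, img1b)
  expect_equal(inv2$invasive_distance_um, 2 * inv$invasive_distance_um)
})

test_that("group comparisons annotate significance with the star convention", {
  expect_equal(significance_stars(c(0.03, 0.004, 2e-4, 0.2)),
               c("*", "**", "***", "†"))
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20, 10)  # 10 SD apart
  res <- compare_groups(c(a, b, a + 0.01),
                        rep(c("g1", "g2", "g3"), each = 20))
  expect_equal(nrow(res), choose(3, 2))
  expect_equal(res$annotation[res$group1 == "g1" & res$group2 == "g2"], "***")
  expect_equal(res$annotation[res$group1 == "g1" & res$group2 == "g3"], "†")
  # identical degenerate groups
  same <- compare_groups(rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(same$annotation, "†")
  expect_error(compare_groups(1:4, c("a", "a", "a", "b")), "at least 2 groups")
})
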