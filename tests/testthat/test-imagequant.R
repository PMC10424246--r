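test_that("line profiles interpolate correctly", {
  img <- matrix(3, 32, 32)
  prof <- extract_line_profile(img, c(2, 16), c(30, 16), 0.5)
  expect_true(all(prof$intensities == 3))

  # vertical stripes of period 10 px crossed perpendicularly
  img2 <- matrix(rep(rep(c(1, 0), each = 5), length.out = 40 * 40),
                 40, 40, byrow = TRUE)
  prof2 <- extract_line_profile(img2, c(1, 20), c(40, 20), 1)
  expect_equal(prof2$intensities, img2[20, ])

  expect_error(extract_line_profile(img, c(5, 5), c(5, 5), 0.5), "coincide")
  expect_error(extract_line_profile(img, c(0, 5), c(30, 5), 0.5), "outside")
})

test_that("impulse peak spacings scale with the pixel size", {
  y <- rep(0, 64)
  y[c(11, 31, 51)] <- 10   # impulses 20 px apart
  ps <- junction_spacings(y, um_per_pixel = 0.5, smooth_sigma_um = 0)
  expect_equal(ps$spacings, c(10, 10))
  ps2 <- junction_spacings(y, um_per_pixel = 1, smooth_sigma_um = 0)
  expect_equal(ps2$spacings, c(20, 20))
  # spacing equivariance under pixel-size rescaling
  expect_equal(ps2$spacings, 2 * ps$spacings)

  expect_error(junction_spacings(rep(0, 64), um_per_pixel = 1),
               "constant")
  y1 <- rep(0, 64); y1[30] <- 5
  expect_error(junction_spacings(y1, um_per_pixel = 1, smooth_sigma_um = 0),
               "insufficient peaks")
})

test_that("plateau peaks keep their leftmost sample", {
  y <- c(0, 0, 5, 5, 5, 0, 0, 0, 7, 0, 0)
  ps <- junction_spacings(y, um_per_pixel = 1, smooth_sigma_um = 0,
                          min_separation_um = 1)
  expect_equal(ps$peak_positions, c(2, 8))  # 0-based um positions of idx 3, 9
})

test_that("hexagonal boundary image yields spacings equal to the lattice diameter", {
  g <- gen_junction_image(mean_cell_diameter = 25, jitter = 0, snr = Inf,
                          seed = 1)
  # horizontal line through a row of cell centers
  row_um <- g$centers[which.min(abs(g$centers[, 2] - 64)), 2]
  row_px <- row_um / g$um_per_pixel
  prof <- extract_line_profile(g$image, c(2, row_px), c(255, row_px), 0.5)
  ps <- junction_spacings(prof)
  expect_true(all(abs(ps$spacings - 25) < 1))
})

test_that("mean cell diameter is recovered from random-line spacings", {
  g <- gen_junction_image(mean_cell_diameter = 25, jitter = 0.2, seed = 7)
  res <- sample_junction_spacings(g$image, g$um_per_pixel, n_lines = 20,
                                  seed = 107)
  expect_lt(abs(res$diameter_estimate - 25) / 25, 0.15)
  expect_gte(res$n_lines_used, 15)
})

test_that("area fractions follow the mask under both conventions", {
  img <- matrix(0, 40, 40); img[, 1:20] <- 1   # half bright
  af <- area_fraction(img)
  expect_equal(af$fraction_pct, 50)

  expect_equal(area_fraction(matrix(0, 20, 20))$fraction_pct, 0)

  af2 <- area_fraction(img, um_per_pixel = 2)
  # 800 positive px * 4 um2 = 3200 um2 of 6400 um2 -> 50000 per 1e5 um2
  expect_equal(af2$positive_area_um2, 3200)
  expect_equal(af2$area_per_reference, 5e4)

  expect_warning(af3 <- area_fraction(img, threshold = 5), "outside")
  expect_equal(af3$fraction_pct, 0)

  # gain invariance of the percentage under Otsu thresholding
  expect_equal(area_fraction(37 * img)$fraction_pct, 50)
})

test_that("blob coverage is recovered by Otsu-thresholded area fraction", {
  # disks of known total coverage on a dim background with mild noise
  set.seed(5)
  n <- 200
  img <- matrix(rnorm(n^2, 10, 1), n, n)
  xs <- rep(seq(20, 180, by = 40), times = 5)
  ys <- rep(seq(20, 180, by = 40), each = 5)
  r <- 8.74  # 25 disks of radius ~8.74 px cover ~12% of a 200x200 field
  for (i in seq_along(xs)) {
    cc <- which((row(img) - ys[i])^2 + (col(img) - xs[i])^2 <= r^2)
    img[cc] <- rnorm(length(cc), 100, 1)
  }
  truth <- 100 * sum(vapply(seq_along(xs), function(i)
    sum((row(img) - ys[i])^2 + (col(img) - xs[i])^2 <= r^2), numeric(1))) / n^2
  af <- area_fraction(img)
  expect_lt(abs(af$fraction_pct - truth), 1)
})

test_that("viability percentages follow the counts", {
  expect_equal(viability(90, 10), 90)
  expect_equal(viability(0, 25), 0)
  expect_error(viability(0, 0), "live \\+ dead")
  expect_error(viability(-1, 5), "live_count")
})

test_that("spot counting matches generated cell numbers", {
  expect_equal(count_cells(matrix(0, 64, 64)), 0)

  one <- matrix(0, 64, 64)
  one[20:28, 20:28] <- outer(dnorm(-4:4, sd = 2), dnorm(-4:4, sd = 2)) * 500
  expect_equal(count_cells(one), 1)

  g <- gen_livedead(n_cells = 200, viability_pct = 93, seed = 7)
  n_live <- count_cells(g$live)
  n_dead <- count_cells(g$dead)
  expect_lte(abs(n_live - g$n_live), 2)
  expect_lte(abs(n_dead - g$n_dead), 2)
  expect_lt(abs(viability(n_live, n_dead) - 93), 2)
})

test_that("histocytometry gating recovers the infected fraction", {
  g <- gen_infection_table(n_cells = 5000, infected_fraction = 0.106,
                           seed = 3)
  res <- histocytometry_gate(g$table)
  expect_lt(abs(res$pct_double_positive - 10.6), 1.5)

  g2 <- gen_infection_table(n_cells = 5000, infected_fraction = 0.028,
                            seed = 3)
  expect_lt(abs(histocytometry_gate(g2$table)$pct_double_positive - 2.8), 1)

  # no GFP-positive rows under a prohibitive fixed gate
  res0 <- histocytometry_gate(g$table, t_gfp = max(g$table$gfp_mean) + 1)
  expect_equal(res0$pct_double_positive, 0)
})

test_that("gated percentage is monotone non-increasing in the GFP threshold", {
  g <- gen_infection_table(n_cells = 2000, infected_fraction = 0.106,
                           seed = 12)
  cuts <- quantile(g$table$gfp_mean, seq(0.05, 0.95, by = 0.1))
  pct <- vapply(cuts, function(t)
    histocytometry_gate(g$table, t_gfp = t)$pct_double_positive, numeric(1))
  expect_true(all(diff(pct) <= 0))
  expect_error(histocytometry_gate(data.frame()), "nonempty")
})
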