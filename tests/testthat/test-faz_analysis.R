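pitch320 <- 4.5 / 320

test_that("centroid is the mean of foreground pixel centres", {
  b <- matrix(FALSE, 64, 64)
  b[11:20, 11:20] <- TRUE  # 0-based rows/cols 10..19
  expect_equal(unname(compute_centroid(b)), c(15, 15))
  s <- matrix(FALSE, 16, 16)
  s[8, 6] <- TRUE  # 0-based (x, y) = (5, 7)
  expect_equal(unname(compute_centroid(s)), c(5.5, 7.5))
  expect_error(compute_centroid(matrix(FALSE, 4, 4)), "empty")
})

test_that("analysis disc matches its physical radius and clips with warning", {
  img <- enface_angiogram(matrix(0.5, 320, 320) + diag(320) * 0.1)
  reg <- crop_analysis_disc(img, c(160, 160), diameter_mm = 3)
  r_px <- 1.5 / pitch320
  expect_equal(r_px, 106.666, tolerance = 1e-4)
  expect_lt(abs(sum(reg$disc_mask) - pi * r_px^2) / (pi * r_px^2), 0.005)
  expect_equal(reg$clipped_fraction, 0)
  # reflection symmetry of the disc mask (mirrored centroid, mirrored mask)
  rega <- crop_analysis_disc(img, c(100, 160), diameter_mm = 2)
  regb <- crop_analysis_disc(img, c(220, 160), diameter_mm = 2)
  expect_identical(rega$disc_mask, regb$disc_mask[, ncol(regb$disc_mask):1])
  # off-centre disc gets clipped and says so
  expect_warning(regc <- crop_analysis_disc(img, c(20, 160), diameter_mm = 3),
                 "clipped")
  expect_gt(regc$clipped_fraction, 0.2)
  expect_error(crop_analysis_disc(img, c(-5, 160)), "outside")
  expect_error(crop_analysis_disc(img, c(160, 160), diameter_mm = 0), "positive")
})

test_that("FAZ area is pixel count times squared pitch", {
  m <- matrix(FALSE, 320, 320)
  m[sample.int(320^2, 1000)] <- TRUE
  expect_equal(faz_area(m, pitch320), 1000 * pitch320^2)
  expect_equal(1000 * pitch320^2, 0.19775, tolerance = 1e-4)
  expect_equal(faz_area(matrix(TRUE, 320, 320), pitch320), 20.25)
  expect_warning(a0 <- faz_area(matrix(FALSE, 8, 8), 1), "empty")
  expect_equal(a0, 0)
})

test_that("boundary tracing gives the hand-traced chain length", {
  b <- matrix(FALSE, 32, 32)
  b[11:20, 11:20] <- TRUE
  # raw Moore chain of a 10x10 block: 4 sides x 9 steps
  expect_equal(faz_perimeter(b, 1, weights = "chain"), 36)
  # calibrated default shrinks by pi(1+sqrt2)/8
  expect_equal(faz_perimeter(b, 1), 36 * pi * (1 + sqrt(2)) / 8)
  # single pixel: documented 4 * pitch fallback
  s <- matrix(FALSE, 8, 8); s[4, 4] <- TRUE
  expect_equal(faz_perimeter(s, 0.5), 2)
  # disconnected mask: warn and use the largest blob
  two <- matrix(FALSE, 32, 32)
  two[5:6, 5:6] <- TRUE
  two[20:27, 20:27] <- TRUE
  expect_warning(p2 <- faz_perimeter(two, 1, weights = "chain"), "largest")
  expect_equal(p2, 28)  # 8x8 block: 4 x 7 steps
  expect_error(faz_perimeter(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("circularity behaves like 4 pi A / P^2", {
  expect_equal(circularity(4^2, 4 * 4), pi / 4)  # continuous square
  d <- make_disc(512, 150)
  circ <- circularity(faz_area(d, 1), faz_perimeter(d, 1))
  expect_gt(circ, 0.98); expect_lt(circ, 1.02)
  # elongation drives circularity down hard
  e <- matrix(FALSE, 220, 20); e[10:209, 10:11] <- TRUE
  expect_lt(circularity(faz_area(e, 1), faz_perimeter(e, 1)), 0.1)
  expect_error(circularity(1, 0), "positive")
})

test_that("disc circularity converges to 1 with radius", {
  errs <- sapply(c(10, 30, 100), function(r) {
    d <- make_disc(256 + 2 * r, r)
    abs(circularity(faz_area(d, 1), faz_perimeter(d, 1)) - 1)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("circularity is invariant under uniform shape rescaling", {
  # rasterize the same continuous shape at 1x, 2x, 4x scale
  base <- circularity(faz_area(make_disc(96, 30), 1),
                      faz_perimeter(make_disc(96, 30), 1))
  for (f in c(2, 4)) {
    up <- make_disc(96 * f, 30 * f)
    cu <- circularity(faz_area(up, 1), faz_perimeter(up, 1))
    expect_equal(cu, base, tolerance = 0.03)
  }
})

test_that("axial-length correction follows the Littmann-Bennett q ratio", {
  id <- axial_length_correction(24.39, 24.39)
  expect_equal(id$linear_factor, 1)
  expect_equal(id$area_factor, 1)
  c2 <- axial_length_correction(26.21, 24.39)
  expect_equal(c2$linear_factor, (26.21 - 1.82) / (24.39 - 1.82))
  expect_equal(c2$linear_factor, 1.0806, tolerance = 1e-4)
  expect_error(axial_length_correction(1.5, 24.39), "1.82")
  # circularity is invariant under the adjustment
  a <- 0.25; p <- 1.9
  expect_equal(circularity(a * c2$area_factor, p * c2$linear_factor),
               circularity(a, p))
})

test_that("delineate_faz assembles consistent morphometry", {
  img <- enface_angiogram(matrix(runif(320^2), 320, 320))
  theta <- seq(0, 2 * pi, length.out = 121)[-121]
  poly <- cbind(160 + 19 * cos(theta), 160 + 19 * sin(theta))
  faz <- delineate_faz(img, poly, axial_length_mm = 26.21)
  expect_equal(faz$circularity,
               circularity(faz$area_mm2, faz$perimeter_mm))
  expect_equal(faz$area_mm2, pi * (19 * pitch320)^2, tolerance = 0.02)
  lf <- (26.21 - 1.82) / (24.39 - 1.82)
  expect_equal(faz$area_adj_mm2, faz$area_mm2 * lf^2)
  expect_equal(faz$perimeter_adj_mm, faz$perimeter_mm * lf)
  expect_equal(unname(faz$centroid_px), c(160, 160), tolerance = 0.05)
})
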