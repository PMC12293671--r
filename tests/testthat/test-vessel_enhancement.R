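test_that("Hessian eigenvalues vanish on constants and track ridge curvature", {
  ev <- hessian_eigenvalues(matrix(0.7, 48, 48), sigma = 1.5)
  expect_equal(max(abs(ev$lambda1)), 0)
  expect_equal(max(abs(ev$lambda2)), 0)

  # sinusoid along x, flat along y: lambda along y ~ 0; at crests the
  # gamma-normalized dominant eigenvalue is -sigma^2 k^2 A exp(-sigma^2 k^2/2)
  n <- 128; period <- 16; k <- 2 * pi / period; A <- 0.5; sig <- 2
  img <- matrix(rep(A * sin(k * (seq_len(n) - 0.5)), each = n), n, n)
  ev <- hessian_eigenvalues(img, sigma = sig)
  crest_col <- which.max(img[1, ])
  mid <- n / 2
  analytic <- -sig^2 * k^2 * A * exp(-sig^2 * k^2 / 2)
  # sampled kernels approximate the continuous derivative to a few percent
  expect_equal(ev$lambda2[mid, crest_col], analytic, tolerance = 0.05)
  expect_lt(abs(ev$lambda1[mid, crest_col]), 0.05 * abs(analytic))
  # dominant eigenvalue negative at a bright crest
  expect_lt(ev$lambda2[mid, crest_col], 0)

  # 90-degree rotation of the input rotates the eigenvalue fields
  set.seed(5)
  rimg <- matrix(runif(32 * 32), 32, 32)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  a <- hessian_eigenvalues(rimg, 1.2)
  b <- hessian_eigenvalues(rot90(rimg), 1.2)
  expect_equal(b$lambda2, rot90(a$lambda2), tolerance = 1e-10)
})

test_that("Frangi vesselness prefers ridges, suppresses blobs and constants", {
  expect_equal(max(frangi_vesselness(matrix(0.3, 32, 32))), 0)
  expect_error(frangi_vesselness(matrix(0, 8, 8),
                                 vesselness_params(scales = numeric(0))),
               "non-empty")

  # bright Gaussian ridge of width ~ matched sigma
  n <- 96; sig0 <- 1.5
  ridge <- outer(seq_len(n), seq_len(n),
                 function(r, c) exp(-((r - n / 2)^2) / (2 * sig0^2)))
  v <- frangi_vesselness(ridge)
  centre <- v[n / 2, n / 2]
  bg <- median(v[c(1:30, 66:96), ])
  expect_gt(centre, 10 * max(bg, 1e-6))

  # response at the ridge centre agrees with direct formula evaluation
  ev <- hessian_eigenvalues(ridge, sig0)
  l1 <- ev$lambda1[n / 2, n / 2]; l2 <- ev$lambda2[n / 2, n / 2]
  S2 <- sqrt(ev$lambda1^2 + ev$lambda2^2)
  cc <- max(S2) / 2
  vref <- exp(-(l1 / l2)^2 / (2 * 0.5^2)) *
    (1 - exp(-(l1^2 + l2^2) / (2 * cc^2)))
  v_single <- frangi_vesselness(ridge, vesselness_params(scales = sig0))
  expect_equal(v_single[n / 2, n / 2], vref, tolerance = 0.05 * vref)

  # an isotropic blob of equal contrast scores below the ridge
  blob <- outer(seq_len(n), seq_len(n),
                function(r, c) exp(-((r - n / 2)^2 + (c - n / 2)^2) / (2 * sig0^2)))
  expect_gt(max(v), max(frangi_vesselness(blob)))
})

test_that("Frangi response is symmetric and monotone in the scale set", {
  set.seed(9)
  img <- matrix(0, 64, 64)
  img[30:32, 10:55] <- 1
  img[10:50, 20:22] <- 1
  img <- img + matrix(rnorm(64^2, 0, 0.02), 64, 64)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  v <- frangi_vesselness(img)
  vr <- frangi_vesselness(rot90(img))
  expect_lt(max(abs(vr - rot90(v))), 0.02 * max(v))
  vf <- frangi_vesselness(img[, ncol(img):1])
  expect_lt(max(abs(vf - v[, ncol(v):1])), 0.02 * max(v))

  # adding a scale never decreases any pixel's response (fixed c)
  p2 <- vesselness_params(scales = c(1, 2), c = 0.3)
  p3 <- vesselness_params(scales = c(1, 1.5, 2), c = 0.3)
  expect_true(all(frangi_vesselness(img, p3) >= frangi_vesselness(img, p2) - 1e-12))
})

test_that("vesselness inversion mirrors the map", {
  v <- matrix(runif(64), 8, 8)
  expect_equal(invert_vesselness(invert_vesselness(v)), v)
  expect_equal(invert_vesselness(matrix(0, 2, 2)), matrix(1, 2, 2))
  expect_equal(max(invert_vesselness(v)), 1 - min(v))
  expect_error(invert_vesselness(matrix(2, 2, 2)), "0, 1")
})

test_that("Phansalkar threshold follows its closed form on flat inputs", {
  # constant 0.5: T = 0.5 (1 + 2 e^-5 - 0.25) ~ 0.3817 < 0.5 -> all fg
  m <- phansalkar_threshold(matrix(0.5, 32, 32))
  expect_true(all(m))
  thr <- 0.5 * (1 + 2 * exp(-5) + 0.25 * ((0 / 0.5) - 1))
  expect_equal(thr, 0.38174, tolerance = 1e-4)
  # all-zero image: T = 0, strict > ties to background
  expect_false(any(phansalkar_threshold(matrix(0, 32, 32))))
  expect_error(phansalkar_threshold(matrix(0.5, 8, 8),
                                    threshold_params(window_radius = 10)),
               "larger")
  expect_error(phansalkar_threshold(matrix(1.5, 32, 32)), "normalized")
})

test_that("Phansalkar matches the brute-force windowed oracle bit for bit", {
  set.seed(21)
  for (rep in 1:10) {
    img <- matrix(runif(64 * 64), 64, 64)
    expect_identical(phansalkar_threshold(img), phansalkar_oracle(img))
  }
  # region argument zeroes outside pixels but keeps full-window statistics
  img <- matrix(runif(64 * 64), 64, 64)
  reg <- make_disc(64, 20)
  m <- phansalkar_threshold(img, region = reg)
  expect_false(any(m & !reg))
  expect_identical(m, phansalkar_oracle(img) & reg)
})
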