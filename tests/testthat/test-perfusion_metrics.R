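test_that("vessel density is the masked foreground fraction", {
  reg <- make_disc(64, 25)
  expect_equal(vessel_density(reg, reg), 1)
  chk <- outer(seq_len(64), seq_len(64), function(r, c) (r + c) %% 2 == 0)
  expect_equal(vessel_density(chk, reg), 0.5, tolerance = 1 / sum(reg) + 1e-9)
  expect_error(vessel_density(chk, matrix(FALSE, 64, 64)), "empty")
  # ground-truth identity on a phantom
  ph <- generate_vascular_phantom(small_phantom_spec(seed = 2))
  expect_equal(vessel_density(ph$truth$vessel_mask, ph$truth$effective_mask),
               ph$truth$true_density)
})

test_that("skeletonization thins to 1 px, preserves topology, is idempotent", {
  bar <- matrix(FALSE, 20, 60)
  bar[9:11, 6:55] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(bar[sk]))
  expect_no_2x2(sk)
  expect_gte(sum(sk), 46); expect_lte(sum(sk), 50)  # centreline, end effects
  expect_identical(skeletonize(sk), sk)

  # single pixel is its own skeleton
  s <- matrix(FALSE, 8, 8); s[4, 5] <- TRUE
  expect_identical(skeletonize(s), s)

  # phantom masks: containment, thinness, idempotence, component count
  for (seed in 1:3) {
    ph <- generate_vascular_phantom(small_phantom_spec(seed = seed))
    vm <- ph$truth$vessel_mask
    sk <- skeletonize(vm)
    expect_true(all(vm[sk]))
    expect_no_2x2(sk)
    expect_identical(skeletonize(sk), sk)
    expect_equal(max(octamorph:::label_components8(sk)),
                 max(octamorph:::label_components8(vm)))
  }
})

test_that("vessel length density counts skeleton pixels over the region", {
  # 100 skeleton px inside a 1000-px region -> 0.1
  reg2 <- matrix(FALSE, 50, 50); reg2[1:20, 1:50] <- TRUE
  l2 <- matrix(FALSE, 50, 50); l2[5, 1:50] <- TRUE; l2[9, 1:50] <- TRUE
  expect_equal(vessel_length_density(l2, reg2), 100 / 1000)
  expect_equal(vessel_length_density(matrix(FALSE, 50, 50), reg2), 0)
  # weighted chain length of a diagonal is sqrt 2 per step
  dg <- diag(10) > 0
  expect_equal(skeleton_length(dg, "weighted"), 9 * sqrt(2))
  expect_equal(skeleton_length(dg, "count"), 10)
})

test_that("VLD never exceeds VD on rendered phantoms", {
  for (seed in 1:3) {
    ph <- generate_vascular_phantom(small_phantom_spec(seed = seed + 10))
    eff <- ph$truth$effective_mask
    vd <- vessel_density(ph$truth$vessel_mask, eff)
    vld <- vessel_length_density(skeletonize(ph$truth$vessel_mask), eff)
    expect_lte(vld, vd)
  }
})

test_that("VD and VLD are exactly invariant under 90-degree rotation", {
  ph <- generate_vascular_phantom(small_phantom_spec(seed = 4))
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  eff <- ph$truth$effective_mask; vm <- ph$truth$vessel_mask
  sk <- ph$truth$true_skeleton
  expect_identical(vessel_density(vm, eff), vessel_density(rot90(vm), rot90(eff)))
  expect_identical(vessel_length_density(sk, eff),
                   vessel_length_density(rot90(sk), rot90(eff)))
})

test_that("box-counting recovers the dimension of reference objects", {
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  f1 <- suppressWarnings(box_counting_fd(line))
  expect_equal(f1$slope, 1, tolerance = 0.05)

  # a filled disc is 2-D; boxes must stay small relative to the object
  disc <- make_disc(512, 200)
  f2 <- suppressWarnings(box_counting_fd(disc, box_sizes = c(2, 4, 8, 16)))
  expect_equal(f2$slope, 2, tolerance = 0.05)

  sp <- make_sierpinski(6)
  f3 <- suppressWarnings(box_counting_fd(sp))
  expect_equal(f3$slope, log(3) / log(2), tolerance = 0.05)

  # counts non-increasing in box size, slope in [0, 2] + fit tolerance
  ph <- generate_vascular_phantom(small_phantom_spec(seed = 6))
  f4 <- box_counting_fd(ph$truth$true_skeleton)
  expect_true(all(diff(f4$box_counts) <= 0))
  expect_gte(f4$slope, 0); expect_lte(f4$slope, 2.05)

  expect_error(box_counting_fd(matrix(FALSE, 64, 64)), "empty")
  expect_error(box_counting_fd(diag(64) > 0, box_sizes = c(2, 4)), "at least 4")
})

test_that("random segment dropout degrades VD, VLD and usually FD", {
  n_dec_fd <- 0L; n <- 25L
  for (seed in seq_len(n)) {
    ph <- generate_vascular_phantom(small_phantom_spec(seed = 100 + seed))
    dg <- degrade_phantom(ph, dropout_fraction = 0.2, seed = 500 + seed)
    eff <- ph$truth$effective_mask
    expect_lt(dg$truth$true_density, ph$truth$true_density)
    expect_lt(sum(dg$truth$true_skeleton), sum(ph$truth$true_skeleton))
    fd0 <- box_counting_fd(ph$truth$true_skeleton & eff)$slope
    fd1 <- box_counting_fd(dg$truth$true_skeleton & dg$truth$effective_mask)$slope
    if (fd1 < fd0) n_dec_fd <- n_dec_fd + 1L
  }
  expect_gte(n_dec_fd, ceiling(0.9 * n))
})
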