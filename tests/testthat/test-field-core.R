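test_that("identity field is the exact zero element of the algebra", {
  f <- identity_field(8, 8)
  expect_equal(sum(abs(f$dx)) + sum(abs(f$dy)), 0)
  expect_equal(length(f$dx) + length(f$dy), 128)

  img <- rand_image(16, 12, seed = 3)
  expect_equal(max(abs(warp_image(img, identity_field(16, 12)) - img)), 0)

  expect_equal(corrupted_fraction(identity_field(64, 96)), 0)

  g <- rand_rbf_field(16, 20, seed = 5)
  expect_equal(max_abs_field_diff(compose_fields(identity_field(16, 20), g), g), 0)
  expect_equal(max_abs_field_diff(compose_fields(g, identity_field(16, 20)), g), 0)

  inv <- invert_field(identity_field(12, 10))
  expect_equal(max_abs_field_diff(inv, identity_field(12, 10)), 0)

  expect_error(identity_field(4, 30), "at least 8x8")
})

test_that("constant fields form a translation group under compose and invert", {
  a <- translation_field(12, 14, 3, -2)
  b <- translation_field(12, 14, -1.5, 4.25)
  ab <- compose_fields(a, b)
  expect_lt(max_abs_field_diff(ab, translation_field(12, 14, 1.5, 2.25)), 1e-6)

  inv <- invert_field(translation_field(16, 16, 3, -2))
  expect_lt(max_abs_field_diff(inv, translation_field(16, 16, -3, 2)), 1e-6)

  # inverse element: a composed with its inverse is the identity
  round <- compose_fields(a, invert_field(a))
  expect_lt(max_abs_field_diff(round, identity_field(12, 14)), 1e-6)
})

test_that("affine fields respect closed-form composition at interior pixels", {
  A <- affine_map(matrix(c(1.05, 0.04, -0.03, 0.97), 2, 2), c(2, -1))
  B <- affine_map(matrix(c(0.95, -0.02, 0.05, 1.08), 2, 2), c(-1.5, 0.5))
  h <- 24; w <- 30
  composed <- compose_fields(from_affine(A, h, w), from_affine(B, h, w))
  closed <- from_affine(affine_compose(A, B), h, w)
  interior <- function(m) m[4:(h - 3), 4:(w - 3)]
  expect_lt(max(abs(interior(composed$dx) - interior(closed$dx))), 1e-6)
  expect_lt(max(abs(interior(composed$dy) - interior(closed$dy))), 1e-6)

  # affine inversion against closed-form 2x3 algebra
  Ainv <- affine_invert(A)
  expect_lt(max(abs(affine_compose(A, Ainv)$linear - diag(2))), 1e-12)
})

test_that("from_affine reproduces translations and analytic Jacobians", {
  f <- from_affine(affine_map(diag(2), c(3, -2)), 10, 10)
  expect_equal(unique(as.vector(f$dx)), 3)
  expect_equal(unique(as.vector(f$dy)), -2)

  f0 <- from_affine(affine_map(diag(2), c(0, 0)), 12, 12)
  expect_equal(max_abs_field_diff(f0, identity_field(12, 12)), 0)

  # finite differences are exact for affine maps, borders included
  det4 <- jacobian_determinant(from_affine(affine_map(2 * diag(2)), 12, 16))
  expect_lt(max(abs(det4 - 4)), 1e-10)
  det25 <- jacobian_determinant(from_affine(affine_map(0.5 * diag(2)), 12, 16))
  expect_lt(max(abs(det25 - 0.25)), 1e-10)
  refl <- jacobian_determinant(
    from_affine(affine_map(matrix(c(-1, 0, 0, 1), 2, 2)), 12, 16))
  expect_lt(max(abs(refl + 1)), 1e-10)
})

test_that("corrupted_fraction separates orientation-preserving from reversing maps", {
  sizes <- list(c(8, 8), c(12, 20), c(33, 17))
  for (s in sizes) {
    keep <- from_affine(affine_map(matrix(c(1.1, 0.2, -0.1, 0.9), 2, 2), c(4, 1)),
                        s[1], s[2])
    expect_equal(corrupted_fraction(keep), 0)
    flip <- from_affine(affine_map(matrix(c(-1, 0, 0, 1), 2, 2)), s[1], s[2])
    expect_equal(corrupted_fraction(flip), 1)
  }
})

test_that("warp_image matches the scalar double-loop bilinear oracle", {
  img <- rand_image(8, 8, seed = 11)
  ramp <- image2d(matrix(rep((0:7) / 7, each = 8), 8, 8))
  shift <- translation_field(8, 8, 1, 0)
  out <- warp_image(ramp, shift)
  # each output column equals the next input column; last column is background
  expect_equal(unclass(out)[, 1:7], unclass(ramp)[, 2:8])
  expect_equal(unique(as.vector(out[, 8])), 0)

  set.seed(21)
  img2 <- rand_image(32, 32, seed = 22)
  fld <- rand_rbf_field(32, 32, n = 10, amp = 4, seed = 23)
  expect_lt(max(abs(warp_image(img2, fld) - brute_warp_bilinear(img2, fld))), 1e-6)

  expect_error(warp_image(img, identity_field(10, 10)), "mismatch")
})

test_that("warp_labels matches the nearest-neighbour oracle and is label-closed", {
  seg <- matrix(0L, 12, 12)
  seg[3:6, 3:8] <- 1L
  seg[8:10, 5:9] <- 2L
  expect_identical(warp_labels(seg, identity_field(12, 12)), seg)

  shifted <- warp_labels(seg, translation_field(12, 12, 2, 0))
  expect_identical(shifted[, 1:10], seg[, 3:12])
  expect_true(all(shifted[, 11:12] == 0L))

  fld <- rand_rbf_field(12, 12, n = 6, amp = 3, seed = 31)
  got <- warp_labels(seg, fld)
  expect_identical(got, brute_warp_nearest(seg, fld))
  expect_true(all(got %in% c(0L, unique(as.vector(seg)))))
})

test_that("landmark interpolation is exact at keypoints and smooth in between", {
  h <- 20; w <- 24
  corners <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
  f_id <- from_keypoints(keypoint_set(corners, corners), h, w)
  expect_lt(max_abs_field_diff(f_id, identity_field(h, w)), 1e-8)

  shifted <- corners
  shifted[, 1] <- shifted[, 1] + 5
  f_c <- from_keypoints(keypoint_set(corners, shifted), h, w)
  expect_lt(max(abs(f_c$dx - 5)), 1e-8)
  expect_lt(max(abs(f_c$dy)), 1e-8)

  expect_error(from_keypoints(keypoint_set(corners[1:2, ], corners[1:2, ]), h, w),
               "at least 3")
  dup <- rbind(corners, corners[1, ])
  expect_error(from_keypoints(keypoint_set(dup, dup), h, w), "singular|oincident")
})

test_that("a realistic landmark count interpolates to sub-millipixel residuals", {
  # 27 keypoints (the typical expert annotation count) on a 160x228 grid
  h <- 160; w <- 228
  set.seed(41)
  gx <- rep(seq(10, w - 11, length.out = 7), times = 4)[1:27]
  gy <- rep(seq(10, h - 11, length.out = 4), each = 7)[1:27]
  # annotation clicks land on pixel centres: integer reference coordinates
  ref <- cbind(round(gx + runif(27, -3, 3)), round(gy + runif(27, -3, 3)))
  mov <- ref + matrix(runif(54, -4, 4), ncol = 2)
  fld <- from_keypoints(keypoint_set(ref, mov), h, w)
  uu <- sample_field(fld, ref[, 1], ref[, 2])
  phix <- uu$dx + ref[, 1]
  phiy <- uu$dy + ref[, 2]
  resid <- sqrt((phix - mov[, 1])^2 + (phiy - mov[, 2])^2)
  expect_lt(max(resid), 1e-3)
})

test_that("SDI inversion round-trips smooth fields below half a pixel", {
  h <- 64; w <- 96
  for (seed in 1:5) {
    f <- rand_rbf_field(h, w, n = 9, amp = 0.08 * min(h, w), seed = 100 + seed)
    rt <- compose_fields(f, invert_field(f))
    m <- 11:(h - 10); n <- 11:(w - 10)
    resid <- mean(sqrt(rt$dx[m, n]^2 + rt$dy[m, n]^2))
    expect_lt(resid, 0.5)
  }
})

test_that("mean displacement norm pools fields and handles edge cases", {
  expect_equal(mean_displacement_norm(list(identity_field(8, 8))), 0)
  expect_equal(mean_displacement_norm(list(translation_field(8, 8, 3, 4))), 5)
  both <- list(translation_field(8, 8, 3, 4), identity_field(8, 8))
  expect_equal(mean_displacement_norm(both), 2.5)
  expect_error(mean_displacement_norm(list()), "at least one")
})
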