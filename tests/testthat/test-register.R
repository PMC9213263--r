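test_that("registering a volume to itself returns a near-zero field", {
  v <- textured_volume()
  f <- register_nonrigid(v, v)
  expect_lte(mean(sqrt(f$ux^2 + f$uy^2 + f$uz^2)), 0.05)
})

test_that("a two-voxel translation is recovered as a constant field", {
  v <- textured_volume()
  mv <- v[c(31:32, 1:30), , ]     # anatomy moved +2 voxels along FH
  f <- register_nonrigid(mv, v)
  expect_equal(mean(f$ux), 2, tolerance = 0.2)
  expect_lt(abs(mean(f$uy)), 0.2)
  expect_lt(abs(mean(f$uz)), 0.2)
})

test_that("a known smooth 8-voxel deformation is recovered within 1 voxel", {
  v <- textured_volume()
  s <- bench_field(dim(v), peak = 8)
  moving <- pmax(warp_image(v, scale_field(s, -1)), 0)
  f <- register_nonrigid(histogram_equalize(moving), histogram_equalize(v))
  expect_lte(mean(composition_epe(f, s)), 1.0)
})

test_that("registration is deterministic", {
  v <- textured_volume()
  s <- bench_field(dim(v), peak = 4)
  moving <- pmax(warp_image(v, scale_field(s, -1)), 0)
  f1 <- register_nonrigid(moving, v)
  f2 <- register_nonrigid(moving, v)
  expect_identical(f1$ux, f2$ux)
})

test_that("upsample_field follows the interpolation and scaling rules", {
  hs <- c(8L, 8L, 4L)
  z <- zero_field(hs, "half")
  up <- upsample_field(z, c(16L, 16L, 8L))
  expect_true(all(up$ux == 0) && all(up$uy == 0) && all(up$uz == 0))
  expect_equal(up$resolution_level, "full")
  # constant field c in half-grid voxels becomes 2c in full-grid voxels
  cfield <- deformation_field(array(1.5, hs), array(-0.5, hs),
                              array(0.25, hs), "half")
  upc <- upsample_field(cfield, c(16L, 16L, 8L))
  expect_true(all(abs(upc$ux - 3) < 1e-12))
  expect_true(all(abs(upc$uy + 1) < 1e-12))
  # a linear ramp is reproduced exactly in the interior (linear functions
  # are fixed points of trilinear interpolation)
  ramp <- array(rep((0:7) / 7, times = 32), hs)
  rf <- deformation_field(ramp, ramp * 0, ramp * 0, "half")
  upr <- upsample_field(rf, c(16L, 16L, 8L))
  expected <- 2 * (0:13) / 14   # interior corner-aligned ramp, scaled by 2
  expect_equal(upr$ux[1:14, 1, 1], expected, tolerance = 1e-9)
  # full-resolution input is rejected
  expect_error(upsample_field(zero_field(hs, "full"), c(16L, 16L, 8L)),
               "half-resolution")
})

test_that("deformation fields enforce their sanity limit", {
  hs <- c(8L, 8L, 4L)
  big <- array(40, hs)
  expect_error(deformation_field(big, big * 0, big * 0), "sanity limit")
  expect_error(deformation_field(array(NaN, hs), big * 0, big * 0),
               "non-finite")
})

test_that("warp and its adjoint are exact matrix transposes", {
  gs <- c(8L, 8L, 4L)
  f <- random_smooth_field(gs, 2, seed = 3)
  set.seed(4)
  a <- array(rnorm(prod(gs)), gs)
  b <- array(rnorm(prod(gs)), gs)
  expect_lt(abs(sum(warp_image(a, f) * b) - sum(a * warp_adjoint(b, f))),
            1e-10)
  # pure-translation warp by integer voxels matches indexing
  t2 <- deformation_field(array(-2, gs), array(0, gs), array(0, gs))
  w <- warp_image(a, t2)
  expect_equal(w[3:8, , ], a[1:6, , ])
})
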