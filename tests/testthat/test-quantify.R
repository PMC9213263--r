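test_that("contrast ratio of a constant image is one", {
  img <- array(3, c(8, 8, 4))
  roi_a <- array(FALSE, dim(img)); roi_a[1:2, 1:2, 1] <- TRUE
  roi_b <- array(FALSE, dim(img)); roi_b[5:6, 5:6, 2] <- TRUE
  expect_equal(contrast_ratio(img, roi_a, roi_b), 1.0)
})

test_that("piecewise-constant contrast ratio and scaling invariance", {
  img <- array(1, c(8, 8, 4))
  lge <- array(FALSE, dim(img)); lge[1:2, 1:2, 1] <- TRUE
  myo <- array(FALSE, dim(img)); myo[5:6, 5:6, 2] <- TRUE
  img[lge] <- 6
  expect_equal(contrast_ratio(img, lge, myo), 6.0)
  expect_equal(contrast_ratio(img * 17, lge, myo), 6.0)
  # pooled list-of-ROIs form
  expect_equal(contrast_ratio(img, list(which(lge)), list(which(myo))), 6.0)
  expect_error(contrast_ratio(img, array(FALSE, dim(img)), myo), "empty")
  expect_error(contrast_ratio(-img, lge, myo), "denominator")
})

test_that("FWHM mass on a binary shell recovers the scar set exactly", {
  img <- array(0, c(16, 16, 8))
  shell <- array(FALSE, dim(img)); shell[4:12, 4:12, 3:6] <- TRUE
  scar <- array(FALSE, dim(img)); scar[5:7, 5:7, 4:5] <- TRUE
  img[shell] <- 1
  img[scar] <- 10
  ct <- myocardial_contours(shell, voxel_volume_ml = 0.008)
  fw <- fwhm_mass(img, ct)
  expect_equal(fw$threshold, 5)
  expect_identical(fw$scar_mask, scar)
  expect_equal(fw$mass_g, sum(scar) * 0.008 * 1.05)
  # invariant to global intensity scaling
  fw2 <- fwhm_mass(img * 3.7, ct)
  expect_identical(fw2$scar_mask, scar)
  expect_equal(fw2$mass_g, fw$mass_g)
})

test_that("FWHM degenerate cases behave as documented", {
  shell <- array(FALSE, c(8, 8, 4)); shell[2:6, 2:6, 2:3] <- TRUE
  ct <- myocardial_contours(shell, 0.008)
  # uniform shell: every voxel is at half-max, so the whole shell counts
  fw_u <- fwhm_mass(array(2, c(8, 8, 4)), ct)
  expect_equal(sum(fw_u$scar_mask), sum(shell))
  # all-zero shell: zero mass, empty mask
  fw_0 <- fwhm_mass(array(0, c(8, 8, 4)), ct)
  expect_equal(fw_0$mass_g, 0)
  expect_equal(sum(fw_0$scar_mask), 0)
})

test_that("edge sharpness decreases under blur and rejects flat images", {
  set.seed(5)
  img <- array(0, c(24, 24, 12))
  img[1:12, , ] <- 1                        # ideal step edge
  band <- array(FALSE, dim(img)); band[11:14, , ] <- TRUE
  blurred <- mocolge:::gauss_smooth(img, 3)
  expect_gt(edge_sharpness(img, band), edge_sharpness(blurred, band))
  expect_error(edge_sharpness(array(1, dim(img)), band), "dynamic range")
})

test_that("rmse is zero on equality, scale-invariant, and noise-consistent", {
  set.seed(6)
  ref <- array(runif(64^2, 1, 2), c(64, 64, 1))
  expect_equal(rmse(ref, ref), 0)
  expect_lt(rmse(2 * ref, ref), 1e-12)
  sigma <- 0.05
  noisy <- ref + array(rnorm(length(ref), sd = sigma), dim(ref))
  expect_equal(rmse(noisy, ref), sigma, tolerance = 0.1)
})

test_that("copied contours are identical voxel-index sets", {
  shell <- array(FALSE, c(8, 8, 4)); shell[2:6, 2:6, 2:3] <- TRUE
  ct <- myocardial_contours(shell, 0.008)
  ct_copy <- ct   # ROIs copied between reconstructions
  expect_identical(which(ct$shell_mask), which(ct_copy$shell_mask))
})
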