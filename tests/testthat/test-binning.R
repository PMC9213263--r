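test_that("single bin contains every line with the median as centre", {
  fh <- c(3, 1, 4, 1, 5, 9, 2, 6)
  b <- assign_bins(fh, 1)
  expect_true(all(b$labels == 0))
  expect_equal(b$centers, median(fh))
  expect_equal(b$central_bin, 0L)
})

test_that("quantile binning of 0..9 gives five bins of two lines", {
  b <- assign_bins(0:9, 5)
  expect_equal(b$n_bins, 5L)
  expect_equal(as.integer(table(b$labels)), rep(2L, 5))
  # sort-and-split oracle: labels follow rank order
  expect_equal(b$labels, rep(0:4, each = 2))
  expect_equal(b$centers, c(0.5, 2.5, 4.5, 6.5, 8.5))
})

test_that("degenerate FH values merge bins with a warning", {
  expect_warning(b <- assign_bins(rep(c(0, 1), 10), 5), "merged")
  expect_lt(b$n_bins, 5)
})

test_that("binning partitions the acquired lines", {
  set.seed(3)
  fh <- rnorm(503)
  b <- assign_bins(fh, 5)
  expect_equal(sum(tabulate(b$labels + 1L, 5)), 503L)
  expect_true(all(b$labels >= 0 & b$labels < 5))
  # edges monotone, central bin nearest the overall median
  expect_true(all(diff(b$edges) > 0))
  expect_equal(b$central_bin,
               which.min(abs(b$centers - median(fh))) - 1L)
})

test_that("zero-shift correction is the identity", {
  scan <- small_scan()
  sh <- data.frame(fh_mm = rep(1.5, nrow(scan$lines)),
                   rl_mm = rep(-0.5, nrow(scan$lines)))
  out <- phase_shift_correct(scan$kspace, scan$lines, sh, sh,
                             c(2, 2, 2), 32)
  expect_identical(out, scan$kspace)
})

test_that("constant FH shift obeys the Fourier shift theorem", {
  ph <- small_phantom()
  params <- acquisition_params(fov_mm = 64, matrix = 32, n_slices = 32,
                               noise_sd = 0)
  mm <- motion_model(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0,
                     nonrigid_gain = 0, irregularity = 0, seed = 1)
  tr <- breathing_trace(mm, 4)
  traj <- generate_vdcaspr(32, 32, 1, n_beats = 4, lines_per_beat = 260)
  c1 <- coil_maps(c(32, 32, 32), 1)
  scan <- simulate_scan(ph, params, traj, tr, c1, seed = 1)
  n <- nrow(scan$lines)
  sh <- data.frame(fh_mm = rep(0, n), rl_mm = rep(0, n))
  tgt <- data.frame(fh_mm = 3 * 2, rl_mm = 0)   # +3 voxels at 2 mm voxels
  kc <- phase_shift_correct(scan$kspace, scan$lines, sh, tgt, c(2, 2, 2), 32)
  img0 <- kifft(grid_kspace(scan$kspace, scan$lines, rep(32, 3))$data[, , , 1])
  img1 <- kifft(grid_kspace(kc, scan$lines, rep(32, 3))$data[, , , 1])
  expect_lt(rel_err(img1, img0[c(30:32, 1:29), , ]), 1e-10)
  # unitarity: per-sample magnitudes unchanged
  expect_lt(max(abs(Mod(kc) - Mod(scan$kspace))), 1e-12)
})

test_that("shift_lines_vox translates selected lines only", {
  scan <- small_scan()
  rows <- 1:10
  out <- shift_lines_vox(scan$kspace, scan$lines, rows, c(1, 0.5, -0.25),
                         c(32, 32, 32))
  expect_identical(out[, , 11:dim(out)[3], ], scan$kspace[, , 11:dim(out)[3], ])
  expect_lt(max(abs(Mod(out[, , rows, ]) - Mod(scan$kspace[, , rows, ]))),
            1e-12)
  expect_false(identical(out[, , rows, ], scan$kspace[, , rows, ]))
})

test_that("histogram equalization is a monotone rank map", {
  set.seed(4)
  v <- array(runif(1000), c(10, 10, 10))
  h <- histogram_equalize(v)
  expect_equal(range(h), c(0, 1))
  o <- order(v)
  expect_true(all(diff(h[o]) >= 0))
  # invariant under a strictly monotone intensity warp
  expect_equal(histogram_equalize(v^3), h)
  # constant volume maps to zero
  expect_true(all(histogram_equalize(array(5, c(4, 4, 4))) == 0))
})

test_that("bin report summarizes the assignment", {
  b <- assign_bins(0:9, 5)
  rep <- bin_report(b)
  expect_equal(rep$counts, rep(2L, 5))
  expect_equal(rep$central_bin, b$central_bin)
})
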