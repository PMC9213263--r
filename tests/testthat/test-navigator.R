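# a smooth synthetic navigator frame (Gaussian blob off-centre)
nav_frame <- function(du = 24, dv = 16, cu = 12, cv = 8) {
  u <- matrix(seq_len(du), du, dv)
  v <- matrix(rep(seq_len(dv), each = du), du, dv)
  exp(-((u - cu)^2 / 18 + (v - cv)^2 / 10))
}

nav_stack <- function(frames, pixel_mm = 1) {
  arr <- array(0, c(length(frames), 2, dim(frames[[1]])))
  for (i in seq_along(frames)) {
    arr[i, 1, , ] <- frames[[i]]
    arr[i, 2, , ] <- frames[[i]]
  }
  inav_stack(arr, pixel_mm = pixel_mm)
}

test_that("identical frames track to zero shift", {
  st <- nav_stack(list(nav_frame(), nav_frame(), nav_frame()))
  tk <- track_template(st)
  # sub-pixel refinement is iterative; "zero" means well below 0.01 px
  expect_lt(max(abs(tk$fh_px)), 1e-3)
  expect_lt(max(abs(tk$rl_px)), 1e-3)
})

test_that("integer circular shifts are recovered exactly in sign and size", {
  f0 <- nav_frame()
  f1 <- f0[c(22:24, 1:21), ]                 # content moved +3 along FH
  f2 <- f0[, c(3:16, 1:2)]                   # content moved -2 along RL
  tk <- track_template(nav_stack(list(f0, f1, f2), pixel_mm = 2))
  expect_equal(tk$fh_px[2], 3, tolerance = 0.05)
  expect_equal(tk$rl_px[2], 0, tolerance = 0.05)
  expect_equal(tk$rl_px[3], -2, tolerance = 0.05)
  expect_equal(tk$fh_mm[2], 6, tolerance = 0.1)   # pixel_mm conversion
})

test_that("sub-pixel shifts are recovered within 0.1 px", {
  f0 <- nav_frame()
  f1 <- Re(fourier_shift(array(f0, c(dim(f0), 1)), c(1.25, -0.6, 0))[, , 1])
  tk <- track_template(nav_stack(list(f0, f1)))
  expect_equal(tk$fh_px[2], 1.25, tolerance = 0.1)
  expect_equal(tk$rl_px[2], -0.6, tolerance = 0.1)
})

test_that("shift consistency and antisymmetry hold", {
  f0 <- nav_frame()
  d <- c(2, 1)
  f1 <- f0[c((24 - d[1] + 1):24, 1:(24 - d[1])),
           c((16 - d[2] + 1):16, 1:(16 - d[2]))]
  # track(shift(I, d)) = track(I) + d
  tk <- track_template(nav_stack(list(f0, f1)))
  expect_equal(c(tk$fh_px[2], tk$rl_px[2]), d, tolerance = 0.1)
  # swapping reference and target negates the estimate
  st_rev <- nav_stack(list(f1, f0))
  tk_rev <- track_template(st_rev)
  expect_equal(c(tk_rev$fh_px[2], tk_rev$rl_px[2]), -d, tolerance = 0.1)
})

test_that("flat template is rejected and border peaks are flagged", {
  flat <- matrix(1, 24, 16)
  expect_error(track_template(nav_stack(list(flat, flat))), "flat")
  # shift beyond the search window: unreliable flag
  f0 <- nav_frame()
  f1 <- f0[c(14:24, 1:13), ]                 # +11 px, search radius is 4
  tk <- track_template(nav_stack(list(f0, f1)), search_px = 4)
  expect_false(tk$reliable[2])
})

test_that("tracking recovers the truth trace on simulated navigators", {
  scan <- small_scan()
  tr <- scan$truth$trace
  tk <- track_template(scan$inav)
  err_fh <- tk$fh_mm - (tr$fh_mm - tr$fh_mm[1])
  err_rl <- tk$rl_mm - (tr$rl_mm - tr$rl_mm[1])
  half_px <- 0.5 * scan$inav$pixel_mm
  expect_lt(max(abs(err_fh)), half_px)
  expect_lt(max(abs(err_rl)), half_px)
})
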