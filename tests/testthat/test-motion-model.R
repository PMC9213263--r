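test_that("noiseless breathing trace is bounded by the amplitude", {
  mm <- motion_model(fh_amp_mm = 10, irregularity = 0, seed = 1)
  tr <- breathing_trace(mm, 100, rr_s = 0.8)
  expect_gte(min(tr$fh_mm), 0)
  expect_lte(max(tr$fh_mm) - min(tr$fh_mm), 10 + 1e-9)
  # periodic samples: beats separated by exactly one period agree
  tr2 <- breathing_trace(mm, 50, rr_s = 1)   # period 4 s = 4 beats
  expect_equal(tr2$fh_mm[1:10], tr2$fh_mm[5:14], tolerance = 1e-12)
})

test_that("zero amplitude gives identically zero displacements", {
  mm <- motion_model(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0,
                     irregularity = 0.3, seed = 2)
  tr <- breathing_trace(mm, 50)
  expect_true(all(tr$fh_mm == 0) && all(tr$rl_mm == 0) && all(tr$ap_mm == 0))
})

test_that("per-cycle jitter has the configured spread and is reproducible", {
  mm <- motion_model(fh_amp_mm = 10, irregularity = 0.3, seed = 7)
  # dense sampling (rr << period) so cycle maxima estimate cycle amplitudes
  tr <- breathing_trace(mm, 4000, rr_s = 0.05)
  tr_b <- breathing_trace(mm, 4000, rr_s = 0.05)
  expect_identical(tr, tr_b)
  x <- tr$fh_mm
  peaks <- x[which(diff(sign(diff(x))) == -2) + 1]
  peaks <- peaks[peaks > 2]              # ignore spurious micro-peaks
  expect_gt(length(peaks), 30)
  expect_equal(sd(peaks) / 10, 0.3, tolerance = 0.35)
})

test_that("motion_to_field reduces to a constant translation at gain 0", {
  p <- small_phantom()
  mm <- motion_model(fh_amp_mm = 6, rl_amp_mm = 2, ap_amp_mm = 1,
                     nonrigid_gain = 0, irregularity = 0, seed = 1)
  tr <- breathing_trace(mm, 10)
  k <- which.max(tr$fh_mm)
  f <- motion_to_field(p, tr, k)
  expect_equal(max(f$ux) - min(f$ux), 0)
  expect_equal(unique(as.vector(f$ux)), tr$fh_mm[k] / p$voxel_mm[1])
  expect_equal(unique(as.vector(f$uz)), tr$rl_mm[k] / p$voxel_mm[3])
})

test_that("zero state gives the zero field", {
  p <- small_phantom()
  mm <- motion_model(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0, seed = 1)
  tr <- breathing_trace(mm, 2)
  f <- motion_to_field(p, tr, 1)
  expect_true(all(f$ux == 0) && all(f$uy == 0) && all(f$uz == 0))
})

test_that("FH taper matches its closed form at the diaphragm edge", {
  # 10 mm FH at 1.3 mm voxels, gain 0.5: the foot edge keeps the full
  # amplitude 10 / 1.3 = 7.69 voxels; the head edge has half of it
  p <- build_phantom(c(64, 64, 32), voxel_mm = 1.3)
  mm <- motion_model(fh_amp_mm = 10, rl_amp_mm = 0, ap_amp_mm = 0,
                     nonrigid_gain = 0.5, irregularity = 0, seed = 1)
  tr <- structure(list(beat_times_s = 0, fh_mm = 10, rl_mm = 0, ap_mm = 0,
                       nonrigid_state = 0.5),
                  class = "motion_trace", model = mm)
  f <- motion_to_field(p, tr, 1)
  expect_equal(max(abs(f$ux)), 10 / 1.3, tolerance = 1e-9)
  expect_equal(f$ux[1, 1, 1], 10 / 1.3)                 # diaphragm edge
  expect_equal(f$ux[64, 1, 1], 0.5 * 10 / 1.3)          # head edge
  # smoothness: bounded discrete gradient
  expect_lt(max(abs(diff(f$ux[, 1, 1]))), 0.1)
})
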