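test_that("static noiseless fully sampled scan reproduces the FFT exactly", {
  ph <- small_phantom()
  params <- acquisition_params(fov_mm = 64, matrix = 32, n_slices = 32,
                               noise_sd = 0)
  mm <- motion_model(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0,
                     nonrigid_gain = 0, irregularity = 0, seed = 1)
  tr <- breathing_trace(mm, 4)
  traj <- generate_vdcaspr(32, 32, 1, n_beats = 4, lines_per_beat = 260)
  c1 <- coil_maps(c(32, 32, 32), 1)
  scan <- simulate_scan(ph, params, traj, tr, c1, seed = 1)
  g <- grid_kspace(scan$kspace, scan$lines, c(32, 32, 32), echo = 1)
  truth <- reference_echo_images(ph, params)
  expect_true(all(g$mask == 1))
  expect_lt(rel_err(g$data[, , , 1], kfft(truth$e1)), 1e-10)
  # Parseval between the echo image and its sampled k-space
  expect_lt(abs(sum(Mod(g$data[, , , 1])^2) - sum(Mod(truth$e1)^2)) /
              sum(Mod(truth$e1)^2), 1e-9)
})

test_that("without fat the two echoes are identical", {
  ph <- build_phantom(c(32, 32, 32),
                      signal = list(fat_fat = 0, chest_fat = 0))
  params <- acquisition_params(fov_mm = 64, matrix = 32, n_slices = 32,
                               noise_sd = 0)
  mm <- motion_model(fh_amp_mm = 5, nonrigid_gain = 0, irregularity = 0,
                     seed = 1)
  tr <- breathing_trace(mm, 3)
  traj <- generate_vdcaspr(32, 32, 4, n_beats = 3, lines_per_beat = 30)
  c1 <- coil_maps(c(32, 32, 32), 2)
  scan <- simulate_scan(ph, params, traj, tr, c1, seed = 1)
  expect_lt(max(Mod(scan$kspace[1, , , ] - scan$kspace[2, , , ])), 1e-12)
})

test_that("default fat shift puts TE1 opposed and TE2 in phase", {
  params <- acquisition_params()
  ph1 <- exp(2i * pi * params$fat_shift_hz * params$te1_ms / 1000)
  ph2 <- exp(2i * pi * params$fat_shift_hz * params$te2_ms / 1000)
  expect_lt(Mod(ph1 + 1), 1e-12)   # exactly opposed
  expect_lt(Mod(ph2 - 1), 1e-12)   # exactly in phase
  # a pure-fat voxel's echo-1 signal is the negative of its echo-2 signal
  w <- 0; f <- 0.9
  e1 <- w + f * ph1; e2 <- w + f * ph2
  expect_lt(Mod(e1 + e2), 1e-12)
})

test_that("identical seeds give bit-identical raw data", {
  ph <- small_phantom()
  params <- acquisition_params(fov_mm = 64, matrix = 32, n_slices = 32,
                               noise_sd = 0.01)
  mm <- motion_model(fh_amp_mm = 8, irregularity = 0.2, seed = 3)
  tr <- breathing_trace(mm, 6)
  traj <- generate_vdcaspr(32, 32, 3, n_beats = 6, lines_per_beat = 20)
  c2 <- coil_maps(c(32, 32, 32), 2)
  a <- simulate_scan(ph, params, traj, tr, c2, seed = 9)
  b <- simulate_scan(ph, params, traj, tr, c2, seed = 9)
  expect_identical(a$kspace, b$kspace)
  expect_identical(a$inav$frames, b$inav$frames)
  d <- simulate_scan(ph, params, traj, tr, c2, seed = 10)
  expect_false(identical(a$kspace, d$kspace))
})

test_that("trajectory/trace beat mismatch is rejected", {
  ph <- small_phantom()
  params <- acquisition_params(fov_mm = 64, matrix = 32, n_slices = 32)
  mm <- motion_model(seed = 1)
  tr <- breathing_trace(mm, 3)
  traj <- generate_vdcaspr(32, 32, 3, n_beats = 10, lines_per_beat = 15)
  c1 <- coil_maps(c(32, 32, 32), 1)
  expect_error(simulate_scan(ph, params, traj, tr, c1),
               "more beats")
})
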