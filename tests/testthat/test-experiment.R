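test_that("a noiseless motion-free scan makes TC and NRC coincide", {
  cfg <- experiment_config(
    motion = list(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0,
                  nonrigid_gain = 0, irregularity = 0),
    acquisition = list(noise_sd = 0),
    trajectory = list(n_beats = 30),
    run_uncorrected = FALSE, seed = 1)
  # all navigator positions identical: the bins degenerate and merge
  ex <- suppressWarnings(run_experiment(cfg))
  expect_lt(rel_err(ex$images$nrc, ex$images$tc), 1e-3)
})

test_that("motion-free control: no correction needed, truth mass recovered", {
  ex <- static_experiment()
  m <- ex$metrics
  # the uncorrected reconstruction IS the motion-free reference here
  expect_lt(m$uncorrected$rmse, 1e-10)
  # paired deltas are small for every quality metric
  expect_lt(abs(m$nrc$sharpness - m$tc$sharpness), 0.02)
  expect_lt(abs(m$nrc$cr_lge_myo - m$tc$cr_lge_myo), 0.25)
  expect_lt(abs(m$nrc$mass_g - m$tc$mass_g), 0.2)
  # FWHM on the motion-free image recovers the ground-truth scar mass
  expect_equal(m$tc$mass_g, ex$truth$scar_mass_g, tolerance = 0.05)
})

test_that("reconstruction pipelines are deterministic", {
  scan <- small_scan()
  cg <- cg_params(8, 1e-6)
  a <- run_tc(scan, cg)
  b <- run_tc(scan, cg)
  expect_identical(a$echo1, b$echo1)
})

test_that("estimated inter-bin fields track the ground-truth bin motion", {
  ex <- nonrigid_experiment()
  scan <- ex$scan
  ph <- scan$truth$phantom
  tr <- scan$truth$trace
  nrc <- ex$recons$nrc
  bins <- nrc$bins
  cb <- bins$central_bin + 1
  sh <- mocolge:::line_shifts(nrc$shifts, scan$lines)
  target <- data.frame(fh_mm = bins$centers[bins$labels + 1],
                       rl_mm = bins$centers_rl[bins$labels + 1])
  # truth field of bin b relative to the central bin, after the per-line
  # bin-centre correction: line-weighted mean over the bin's beats
  mean_field <- function(rows) {
    beats <- scan$lines$beat[rows]
    ub <- table(beats)
    acc <- list(ux = 0, uy = 0, uz = 0); n <- 0
    for (k in as.integer(names(ub))) {
      w <- ub[as.character(k)]
      fk <- motion_to_field(ph, tr, k)
      j <- rows[match(k, beats)]
      acc$ux <- acc$ux + w * (fk$ux + (target$fh_mm[j] - sh$fh_mm[j]) / 2)
      acc$uy <- acc$uy + w * fk$uy
      acc$uz <- acc$uz + w * (fk$uz + (target$rl_mm[j] - sh$rl_mm[j]) / 2)
      n <- n + w
    }
    lapply(acc, function(a) a / n)
  }
  tcm <- mean_field(which(bins$labels == cb - 1))
  heart <- scan$truth$phantom$labels %in% 1:3
  heart <- array(heart, ph$grid_shape)
  epes <- c()
  for (b in seq_len(bins$n_bins)) {
    if (b == cb) next
    tb <- mean_field(which(bins$labels == b - 1))
    f <- nrc$fields_total[[b]]
    e <- sqrt((f$ux - (tb$ux - tcm$ux))^2 + (f$uy - (tb$uy - tcm$uy))^2 +
                (f$uz - (tb$uz - tcm$uz))^2)
    epes <- c(epes, mean(e[heart]))
  }
  expect_lt(mean(epes), 1.5)
})

test_that("experiment configuration merges nested overrides", {
  cfg <- experiment_config(motion = list(fh_amp_mm = 3), seed = 7)
  expect_equal(cfg$motion$fh_amp_mm, 3)
  expect_equal(cfg$motion$period_s, 4)    # untouched sibling default
  expect_equal(cfg$seed, 7)
})
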