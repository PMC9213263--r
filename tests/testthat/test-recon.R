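test_that("forward reduces to the plain FFT and is linear", {
  gs <- c(8L, 8L, 4L)
  spec <- encoding_spec(coil_maps(gs, 1), list(matrix(1, 8, 4)))
  set.seed(1)
  x <- array(complex(real = rnorm(256), imaginary = rnorm(256)), gs)
  y <- encode_forward(spec, x)
  expect_lt(rel_err(y[[1]][, , , 1], kfft(x)), 1e-12)
  expect_true(all(Mod(encode_forward(spec, x * 0)[[1]]) == 0))
})

test_that("forward and adjoint match the dense-matrix oracle", {
  gs <- c(8L, 8L, 4L)
  set.seed(42)
  coils <- coil_maps(gs, 2)
  masks <- list(matrix(rbinom(32, 1, 0.6), 8, 4),
                matrix(rbinom(32, 1, 0.6), 8, 4))
  fields <- list(NULL, random_smooth_field(gs, 1.5, seed = 5))
  spec <- encoding_spec(coils, masks, fields)
  E <- dense_E(spec)
  x <- array(complex(real = rnorm(256), imaginary = rnorm(256)), gs)
  fx <- unlist(lapply(encode_forward(spec, x), as.vector))
  expect_lt(max(Mod(fx - E %*% as.vector(x))), 1e-10)
  y <- complex(real = rnorm(nrow(E)), imaginary = rnorm(nrow(E)))
  ylist <- list(array(y[1:512], c(gs, 2)), array(y[513:1024], c(gs, 2)))
  ay <- encode_adjoint(spec, ylist)
  # masked rows of E are zero, so E^H y matches the adjoint exactly
  expect_lt(max(Mod(as.vector(ay) - Conj(t(E)) %*% y)), 1e-10)
})

test_that("randomized adjoint identity holds for all configurations", {
  for (cfg in specs_8x8x4()) {
    spec <- cfg$spec
    gs <- spec$grid_shape
    set.seed(99)
    x <- array(complex(real = rnorm(256), imaginary = rnorm(256)), gs)
    y <- lapply(seq_len(spec$n_bins), function(b)
      array(complex(real = rnorm(256 * spec$coils$n_coils),
                    imaginary = rnorm(256 * spec$coils$n_coils)),
            c(gs, spec$coils$n_coils)))
    fx <- encode_forward(spec, x)
    # fx is already masked, so unmasked entries of y cannot contribute
    ip1 <- sum(vapply(seq_along(y), function(b)
      sum(Conj(as.vector(fx[[b]])) * as.vector(y[[b]])), 0i))
    ip2 <- sum(Conj(as.vector(x)) * as.vector(encode_adjoint(spec, y)))
    ny <- sqrt(sum(vapply(fx, function(v) sum(Mod(v)^2), 0)))
    nyy <- sqrt(sum(vapply(y, function(v) sum(Mod(v)^2), 0)))
    expect_lt(Mod(ip1 - ip2) / (ny * nyy + 1e-30), 1e-6, label = cfg$tag)
  }
})

test_that("itsense solves the trivial full-mask problem in few iterations", {
  gs <- c(16L, 16L, 8L)
  set.seed(6)
  img <- array(rnorm(prod(gs)), gs)
  kd <- array(kfft(img), c(gs, 1))
  sol <- itsense(kd, coil_maps(gs, 1), matrix(1, 16, 8),
                 cg_params(5, 1e-12))
  expect_lt(rel_err(sol$image, img), 1e-8)
  expect_lte(length(sol$resids), 3)
})

test_that("multi-coil noiseless full sampling is recovered near-exactly", {
  ph <- small_phantom()
  gs <- ph$grid_shape
  coils <- coil_maps(gs, 8)
  img <- ph$water + 0.3i * ph$fat
  kd <- array(0i, c(gs, 8))
  for (c in 1:8) kd[, , , c] <- kfft(coils$maps[, , , c] * img)
  sol <- itsense(kd, coils, matrix(1, gs[2], gs[3]), cg_params(30, 1e-10))
  expect_lt(rel_err(sol$image, img), 1e-5)
})

test_that("undersampled static reconstruction meets the error budget", {
  ph <- desk_phantom()
  gs <- ph$grid_shape
  params <- desk_params(noise_sd = 0)
  mm <- motion_model(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0,
                     nonrigid_gain = 0, irregularity = 0, seed = 1)
  tr <- breathing_trace(mm, 40)
  traj <- generate_vdcaspr(gs[2], gs[3], 3.3, n_beats = 40)
  coils <- coil_maps(gs, 8)
  scan <- simulate_scan(ph, params, traj, tr, coils, seed = 1)
  g <- grid_kspace(scan$kspace, scan$lines, gs, echo = 1)
  sol <- itsense(g$data, coils, g$mask, cg_params(30, 1e-8))
  truth <- reference_echo_images(ph, params)$e1
  # unregularized and undersampling-limited: a fixed aliasing floor remains
  # (energy in phase-encode modes the coil geometry cannot disambiguate);
  # the solution is accurate to a fraction of the image norm and improves
  # with further iterations
  e30 <- rel_err(sol$image, truth)
  expect_lt(e30, 0.2)
  sol90 <- itsense(g$data, coils, g$mask, cg_params(90, 1e-10))
  expect_lt(rel_err(sol90$image, truth), e30)
  # normal-equation residuals trend strongly down (CG residual norms
  # oscillate; the least-squares objective itself is monotone)
  expect_true(all(sol$resids <= 2 * cummin(sol$resids)))
  expect_lt(tail(sol$resids, 1), 0.01 * sol$resids[1])
})

test_that("the reduction chain collapses NRC to TC to SENSE to the iFFT", {
  gs <- c(16L, 16L, 8L)
  coils <- coil_maps(gs, 2)
  set.seed(8)
  img <- array(complex(real = rnorm(prod(gs)),
                       imaginary = rnorm(prod(gs))), gs)
  mask <- matrix(rbinom(prod(gs[2:3]), 1, 0.6), gs[2], gs[3])
  kd <- array(0i, c(gs, 2))
  m3 <- mocolge:::expand_mask(mask, gs)
  for (c in 1:2) kd[, , , c] <- kfft(coils$maps[, , , c] * img) * m3
  cg <- cg_params(25, 1e-10)
  # NRC with identity fields and one bin is exactly itSENSE
  a <- itsense(kd, coils, mask, cg)
  b <- mc_itsense(list(kd), encoding_spec(coils, list(mask)), cg)
  expect_lt(rel_err(b$image, a$image), 1e-12)
  # two bins that partition the mask solve the pooled TC problem
  m1 <- mask; m1[, 5:8] <- 0
  m2 <- mask - m1
  y1 <- kd * array(rep(mocolge:::expand_mask(m1, gs), 2), c(gs, 2))
  y2 <- kd * array(rep(mocolge:::expand_mask(m2, gs), 2), c(gs, 2))
  d <- mc_itsense(list(y1, y2), encoding_spec(coils, list(m1, m2)), cg)
  expect_lt(rel_err(d$image, a$image), 1e-8)
  # uniform single coil + full mask: SENSE is the inverse FFT
  kf <- array(kfft(img), c(gs, 1))
  e <- itsense(kf, coil_maps(gs, 1), matrix(1, gs[2], gs[3]),
               cg_params(3, 1e-12))
  expect_lt(rel_err(e$image, img), 1e-8)
})
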