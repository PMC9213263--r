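# Shared fixtures.  Heavy end-to-end experiments are computed once per test
# session and cached; everything is generated in code under fixed seeds.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small phantom for unit tests
small_phantom <- function() cached("small_phantom", build_phantom(c(32, 32, 32)))

# default desk phantom
desk_phantom <- function() cached("desk_phantom", build_phantom())

# random smooth deformation field on a given grid, bounded magnitude
random_smooth_field <- function(gs, max_disp = 2, seed = 1) {
  set.seed(seed)
  mk <- function() {
    u <- mocolge:::gauss_smooth(array(rnorm(prod(gs)), gs), 2)
    u * max_disp / max(abs(u))
  }
  deformation_field(mk(), mk(), mk())
}

# pure-translation free-breathing experiment (10 mm FH), default elsewhere
translation_experiment <- function() cached("trans_exp", {
  run_experiment(experiment_config(
    motion = list(nonrigid_gain = 0, ap_amp_mm = 0), seed = 1))
})

# default non-rigid free-breathing experiment
nonrigid_experiment <- function() cached("nonrigid_exp", {
  run_experiment(experiment_config(seed = 1))
})

# motion-free control experiment
static_experiment <- function() cached("static_exp", {
  run_experiment(experiment_config(
    motion = list(fh_amp_mm = 0, rl_amp_mm = 0, ap_amp_mm = 0,
                  nonrigid_gain = 0, irregularity = 0), seed = 1))
})

# relative L2 error between volumes
rel_err <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}

# small simulated scan shared by navigator / container tests: 32^3 phantom,
# translation-only breathing, modest trajectory
small_scan <- function() cached("small_scan", {
  ph <- small_phantom()
  params <- acquisition_params(fov_mm = 64, matrix = 32, n_slices = 32,
                               noise_sd = 0.002)
  mm <- motion_model(fh_amp_mm = 8, rl_amp_mm = 2, ap_amp_mm = 0,
                     nonrigid_gain = 0, irregularity = 0.1, seed = 4)
  tr <- breathing_trace(mm, 30)
  traj <- generate_vdcaspr(32, 32, 2, n_beats = 30, lines_per_beat = 20)
  coils <- coil_maps(c(32, 32, 32), 4)
  simulate_scan(ph, params, traj, tr, coils, seed = 5)
})

# --- shared oracles and benchmarks -----------------------------------------

# dense-matrix brute-force oracle: build E column-by-column from the
# forward operator on unit vectors
dense_E <- function(spec) {
  n <- prod(spec$grid_shape)
  m <- n * spec$coils$n_coils * spec$n_bins
  E <- matrix(0i, m, n)
  for (i in seq_len(n)) {
    x <- array(0i, spec$grid_shape); x[i] <- 1
    E[, i] <- unlist(lapply(encode_forward(spec, x), as.vector))
  }
  E
}

# encoding configurations on an 8 x 8 x 4 grid: bins x coils x field types
specs_8x8x4 <- function() {
  gs <- c(8L, 8L, 4L)
  out <- list()
  for (nc in c(1, 2, 4)) {
    coils <- coil_maps(gs, nc)
    for (nb in 1:2) {
      set.seed(nb * 10 + nc)
      masks <- lapply(seq_len(nb), function(i)
        matrix(rbinom(32, 1, 0.7), 8, 4))
      for (ftype in c("identity", "smooth")) {
        fields <- if (ftype == "identity") NULL else
          lapply(seq_len(nb), function(i)
            random_smooth_field(gs, max_disp = 1.5, seed = i + nc))
        out[[length(out) + 1]] <-
          list(spec = encoding_spec(coils, masks, fields),
               tag = sprintf("%d coils, %d bins, %s fields", nc, nb, ftype))
      }
    }
  }
  out
}

# textured smooth volume: registration benchmark with gradient information
# everywhere (no aperture ambiguity)
textured_volume <- function(hs = c(32, 32, 16), seed = 11) {
  set.seed(seed)
  tex <- mocolge:::gauss_smooth(array(rnorm(prod(hs)), hs), 2)
  (tex - min(tex)) / (max(tex) - min(tex))
}

# smooth benchmark deformation: FH taper plus low-order sine components
bench_field <- function(hs, peak = 8) {
  nx <- hs[1]; ny <- hs[2]; nz <- hs[3]
  xg <- (seq_len(nx) - 1) / (nx - 1)
  yg <- (seq_len(ny) - 1) / (ny - 1)
  zg <- (seq_len(nz) - 1) / (nz - 1)
  ux <- peak * outer(outer(1 - xg, rep(1, ny)), rep(1, nz))
  uy <- 0.375 * peak * outer(outer(sin(pi * xg), cos(pi * yg / 2)),
                             rep(1, nz))
  uz <- 0.25 * peak * outer(outer(rep(1, nx), sin(pi * yg)), zg)
  deformation_field(array(ux, hs), array(uy, hs), array(uz, hs), "half")
}

# endpoint error of an estimate u against the generating field s under the
# composition convention u(r) = s(r + u(r))
composition_epe <- function(f, s) {
  hs <- f$grid_shape
  cx <- array(rep(seq_len(hs[1]), times = hs[2] * hs[3]), hs) + f$ux
  cy <- array(rep(rep(seq_len(hs[2]), each = hs[1]), times = hs[3]), hs) +
    f$uy
  cz <- array(rep(seq_len(hs[3]), each = hs[1] * hs[2]), hs) + f$uz
  sqrt((f$ux - mocolge:::interp3_at(s$ux, cx, cy, cz))^2 +
         (f$uy - mocolge:::interp3_at(s$uy, cx, cy, cz))^2 +
         (f$uz - mocolge:::interp3_at(s$uz, cx, cy, cz))^2)
}
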