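# Respiratory motion model: pseudo-periodic breathing trace and ground-truth
# deformation fields.

#' Respiratory motion model
#'
#' Pseudo-periodic free-breathing motion with dominant foot--head (FH)
#' translation, smaller right--left and anterior--posterior components and an
#' optional spatially varying (non-rigid) part.  `nonrigid_gain` converts a
#' fraction of the FH amplitude into a smooth deformation that tapers from
#' the diaphragm (foot end) toward the head and adds a mild AP chest
#' expansion; with `nonrigid_gain = 0` the model is a pure global
#' translation.  `irregularity` is the SD, as a fraction, of per-breath
#' amplitude and period jitter ("regular" vs "irregular" respiration).
#'
#' @param period_s respiratory period (s)
#' @param fh_amp_mm,rl_amp_mm,ap_amp_mm peak displacement amplitudes (mm)
#' @param nonrigid_gain fraction in `[0, 1]` of the FH amplitude converted
#'   into spatially varying deformation
#' @param irregularity per-cycle amplitude/period jitter SD (fraction, >= 0)
#' @param seed integer RNG seed for the jitter
#' @return object of class `motion_model`
#' @export
motion_model <- function(period_s = 4, fh_amp_mm = 10, rl_amp_mm = 2,
                         ap_amp_mm = 1, nonrigid_gain = 0.5,
                         irregularity = 0.1, seed = 1L) {
  stopifnot(period_s > 0, irregularity >= 0,
            nonrigid_gain >= 0, nonrigid_gain <= 1)
  structure(list(period_s = period_s, fh_amp_mm = fh_amp_mm,
                 rl_amp_mm = rl_amp_mm, ap_amp_mm = ap_amp_mm,
                 nonrigid_gain = nonrigid_gain, irregularity = irregularity,
                 seed = as.integer(seed)),
            class = "motion_model")
}

# evaluate expr with a private RNG stream, restoring the caller's stream
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a per-heartbeat breathing trace
#'
#' One motion state per heartbeat at beat times `0, rr_s, 2 rr_s, ...`:
#' `fh_mm[k] = A_c sin^2(pi (t_k - t0_c) / T_c)` within breath cycle `c`,
#' zero at the end-expiration baseline.  Per-cycle amplitude `A_c` and period
#' `T_c` are jittered around the model values by `irregularity` (Gaussian,
#' truncated so `T_c >= period_s / 5`).  RL and AP are scaled copies of the
#' same pattern.  Deterministic given the model seed.
#'
#' @param model `motion_model`
#' @param n_beats number of heartbeats (>= 1)
#' @param rr_s RR interval (s); default 60/69 s (heart rate 69 bpm)
#' @return object of class `motion_trace`: `beat_times_s`, `fh_mm`, `rl_mm`,
#'   `ap_mm`, `nonrigid_state` (per-beat scalars) with the model attached as
#'   attribute `model`
#' @export
breathing_trace <- function(model, n_beats, rr_s = 60 / 69) {
  stopifnot(inherits(model, "motion_model"), n_beats >= 1, rr_s > 0)
  t <- (seq_len(n_beats) - 1) * rr_s
  fh <- numeric(n_beats)
  norm_state <- numeric(n_beats)   # sin^2 envelope including amplitude jitter
  with_private_seed(model$seed, {
    t0 <- 0
    Tc <- model$period_s * max(0.2, 1 + model$irregularity * rnorm(1))
    Ac <- 1 + model$irregularity * rnorm(1)
    for (k in seq_len(n_beats)) {
      while (t[k] >= t0 + Tc) {
        t0 <- t0 + Tc
        Tc <- model$period_s * max(0.2, 1 + model$irregularity * rnorm(1))
        Ac <- 1 + model$irregularity * rnorm(1)
      }
      norm_state[k] <- Ac * sin(pi * (t[k] - t0) / Tc)^2
    }
  })
  fh <- model$fh_amp_mm * norm_state
  rl <- model$rl_amp_mm * norm_state
  ap <- model$ap_amp_mm * norm_state
  structure(list(beat_times_s = t, fh_mm = fh, rl_mm = rl, ap_mm = ap,
                 nonrigid_state = model$nonrigid_gain * norm_state),
            class = "motion_trace", model = model)
}

#' Ground-truth deformation field for one heartbeat
#'
#' Converts a beat's trace values into a dense displacement field in voxel
#' units: a global translation `(fh, ap, rl)` plus, weighted by the model's
#' `nonrigid_gain` g, a smooth spatially varying component.  The FH
#' displacement tapers linearly from the full amplitude at the foot
#' (diaphragm) edge to `(1 - g)` times the amplitude at the head edge; the AP
#' component gains a linear anterior--posterior gradient (chest expansion).
#' With `g = 0` the field is the constant translation.
#'
#' @param phantom `tissue_phantom` (supplies grid and voxel size)
#' @param trace `motion_trace`
#' @param beat_index beat number (1-based)
#' @return `deformation_field` (full resolution, voxel units); the anatomy at
#'   this beat is `warp_image(reference, scale_field(field, -1))`
#' @export
motion_to_field <- function(phantom, trace, beat_index) {
  stopifnot(inherits(trace, "motion_trace"),
            beat_index >= 1, beat_index <= length(trace$fh_mm))
  model <- attr(trace, "model")
  gs <- phantom$grid_shape; vx <- phantom$voxel_mm
  fh_vox <- trace$fh_mm[beat_index] / vx[1]
  ap_vox <- trace$ap_mm[beat_index] / vx[2]
  rl_vox <- trace$rl_mm[beat_index] / vx[3]
  g <- model$nonrigid_gain
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  # FH taper: 1 at the foot edge (x = 1), 1 - g at the head edge (x = nx)
  lam <- 1 - g * (seq_len(nx) - 1) / (nx - 1)
  ux <- array(rep(fh_vox * lam, times = ny * nz), gs)
  # AP: translation plus g-weighted chest-expansion gradient along AP
  mu <- (seq_len(ny) - 1) / (ny - 1) - 0.5
  uy <- array(rep(rep(ap_vox + g * 0.25 * fh_vox * mu, each = nx),
                  times = nz), gs)
  uz <- array(rl_vox, gs)
  deformation_field(ux, uy, uz, "full")
}
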