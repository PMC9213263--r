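# Dual-echo navigated acquisition simulator.

#' Simulate a dual-echo navigated free-breathing acquisition
#'
#' For every heartbeat with acquired lines, the phantom is deformed by that
#' beat's ground-truth field, the two echo images are formed as
#' `I_e = W + F exp(i 2 pi fat_shift TE_e)` (post-inversion contrast is baked
#' into the maps, so the steady-state scale factor is unity), multiplied by
#' each coil map, Fourier transformed (centered, unitary), and the beat's
#' trajectory lines are sampled for both echoes with complex Gaussian noise.
#' A low-resolution coronal dual-echo image navigator (iNAV) is rendered per
#' beat from the same deformed anatomy, honouring the acquisition's
#' "navigator immediately before the 3D shot" timing: iNAV and k-space lines
#' of a beat share one motion state.
#'
#' @param phantom `tissue_phantom`
#' @param params `acquisition_params` consistent with the phantom grid
#' @param trajectory `cartesian_trajectory` on the phantom's (AP, RL)
#'   phase-encode grid; beats must not exceed the trace
#' @param trace `motion_trace`
#' @param coils `coil_sensitivities` on the phantom grid
#' @param seed integer seed for the measurement noise
#' @param inav_downsample iNAV in-plane downsampling factor (default 4:
#'   quarter resolution)
#' @return list with `kspace` (complex array `[echo, coil, line, kx]`),
#'   `lines` (the trajectory line table with `time_s` added), `inav`
#'   (`inav_stack`), `trajectory`, `coils`, `params`, and `truth`
#'   (`phantom`, `trace`)
#' @export
simulate_scan <- function(phantom, params, trajectory, trace, coils,
                          seed = 1L, inav_downsample = 4) {
  gs <- phantom$grid_shape
  stopifnot(inherits(params, "acquisition_params"),
            inherits(trajectory, "cartesian_trajectory"),
            inherits(trace, "motion_trace"),
            inherits(coils, "coil_sensitivities"),
            identical(coils$grid_shape, gs),
            trajectory$ny == gs[2], trajectory$nz == gs[3])
  n_beats_traj <- max(trajectory$lines$beat)
  if (n_beats_traj > length(trace$fh_mm))
    stop("trajectory uses more beats than the motion trace provides")

  nx <- gs[1]; nc <- coils$n_coils
  lines <- trajectory$lines
  nl <- nrow(lines)
  ph1 <- exp(2i * pi * params$fat_shift_hz * params$te1_ms / 1000)
  ph2 <- exp(2i * pi * params$fat_shift_hz * params$te2_ms / 1000)

  ks <- array(0i, c(2, nc, nl, nx))
  du <- max(2L, gs[1] %/% inav_downsample)
  dv <- max(2L, gs[3] %/% inav_downsample)
  beats_used <- sort(unique(lines$beat))
  inav <- array(0, c(length(beats_used), 2, du, dv))
  hann_u <- 0.5 * (1 - cos(2 * pi * (seq_len(du) - 1) / (du - 1)))
  hann_v <- 0.5 * (1 - cos(2 * pi * (seq_len(dv) - 1) / (dv - 1)))
  apod <- outer(hann_u, hann_v)

  line_rows_of <- split(seq_len(nl), lines$beat)
  for (bi in seq_along(beats_used)) {
    beat <- beats_used[bi]
    field <- motion_to_field(phantom, trace, beat)
    moving <- scale_field(field, -1)   # anatomy displaced by +field
    wd <- warp_image(phantom$water, moving)
    fd <- warp_image(phantom$fat, moving)
    e1 <- wd + fd * ph1
    e2 <- wd + fd * ph2
    rows <- line_rows_of[[as.character(beat)]]
    kyi <- lines$ky[rows] + 1L; kzi <- lines$kz[rows] + 1L
    for (c in seq_len(nc)) {
      s <- coils$maps[, , , c]
      k1 <- kfft(e1 * s); k2 <- kfft(e2 * s)
      # one full readout column per phase-encode line
      for (j in seq_along(rows)) {
        ks[1, c, rows[j], ] <- k1[, kyi[j], kzi[j]]
        ks[2, c, rows[j], ] <- k2[, kyi[j], kzi[j]]
      }
    }
    # coronal projection iNAV (sum over AP), Fourier-cropped to low res
    for (e in 1:2) {
      proj <- apply(if (e == 1) e1 else e2, c(1, 3), sum)
      kproj <- kcrop(kfft(proj), c(du, dv)) * apod
      inav[bi, e, , ] <- abs(kifft(kproj))
    }
  }

  with_private_seed(seed, {
    if (params$noise_sd > 0) {
      n <- length(ks)
      ks <- ks + complex(real = rnorm(n, sd = params$noise_sd),
                         imaginary = rnorm(n, sd = params$noise_sd))
      ks <- array(ks, c(2, nc, nl, nx))
      ninav <- length(inav)
      inav <- inav + array(abs(rnorm(ninav, sd = params$noise_sd)),
                           dim(inav))
    }
  })

  lines$time_s <- trace$beat_times_s[lines$beat]
  pixel_mm <- phantom$voxel_mm[1] * gs[1] / du
  stack <- inav_stack(inav, beats = beats_used, pixel_mm = pixel_mm)
  list(kspace = ks, lines = lines, inav = stack, trajectory = trajectory,
       coils = coils, params = params,
       truth = list(phantom = phantom, trace = trace))
}

#' Construct an iNAV stack
#'
#' @param frames real array `[beat, echo, u (FH), v (RL)]`
#' @param beats beat numbers corresponding to the first dimension
#' @param pixel_mm iNAV pixel size (mm)
#' @param template_box integer `(u0, u1, v0, v1)` tracking template (1-based,
#'   inclusive); default: central half of the frame
#' @param reference_beat index (into `beats`) of the reference frame
#' @return object of class `inav_stack`
#' @export
inav_stack <- function(frames, beats = seq_len(dim(frames)[1]),
                       pixel_mm = 1, template_box = NULL,
                       reference_beat = 1L) {
  stopifnot(length(dim(frames)) == 4, all(is.finite(frames)))
  du <- dim(frames)[3]; dv <- dim(frames)[4]
  if (is.null(template_box))
    template_box <- c(floor(du / 4) + 1, du - floor(du / 4),
                      floor(dv / 4) + 1, dv - floor(dv / 4))
  stopifnot(template_box[1] >= 1, template_box[2] <= du,
            template_box[3] >= 1, template_box[4] <= dv,
            template_box[1] < template_box[2],
            template_box[3] < template_box[4])
  structure(list(frames = frames, beats = beats, pixel_mm = pixel_mm,
                 template_box = as.integer(template_box),
                 reference_beat = as.integer(reference_beat)),
            class = "inav_stack")
}

#' Echo images of the phantom at a fixed motion state
#'
#' Renders the coil-free dual-echo images of the phantom deformed to a given
#' motion state; used as the motion-free reference for image-error metrics.
#'
#' @param phantom `tissue_phantom`
#' @param params `acquisition_params`
#' @param trace optional `motion_trace`; if given, the state is the mean of
#'   the per-beat trace (the average breathing position), otherwise the rest
#'   position
#' @param state optional explicit list `(fh_mm, ap_mm, rl_mm)` overriding the
#'   trace average
#' @param model `motion_model` supplying the non-rigid geometry of the
#'   state; taken from the trace when one is given (required with
#'   `state` alone unless the state is purely translational)
#' @return list `e1`, `e2` (complex volumes), `field` (the state's
#'   deformation), `labels_warped` (integer volume of warped labels)
#' @export
reference_echo_images <- function(phantom, params, trace = NULL,
                                  state = NULL, model = NULL) {
  if (is.null(state)) {
    if (is.null(trace)) state <- list(fh_mm = 0, ap_mm = 0, rl_mm = 0)
    else state <- list(fh_mm = mean(trace$fh_mm), ap_mm = mean(trace$ap_mm),
                       rl_mm = mean(trace$rl_mm))
  }
  if (is.null(model))
    model <- if (is.null(trace)) motion_model(nonrigid_gain = 0, seed = 1)
             else attr(trace, "model")
  # one-beat trace at the requested state, reusing the field construction
  t1 <- structure(list(beat_times_s = 0, fh_mm = state$fh_mm,
                       rl_mm = state$rl_mm, ap_mm = state$ap_mm,
                       nonrigid_state = model$nonrigid_gain * state$fh_mm),
                  class = "motion_trace", model = model)
  field <- motion_to_field(phantom, t1, 1)
  moving <- scale_field(field, -1)
  wd <- warp_image(phantom$water, moving)
  fd <- warp_image(phantom$fat, moving)
  ph1 <- exp(2i * pi * params$fat_shift_hz * params$te1_ms / 1000)
  ph2 <- exp(2i * pi * params$fat_shift_hz * params$te2_ms / 1000)
  # warp per-label indicators and take the best-supported label, so that
  # interpolation cannot invent labels at tissue boundaries
  labs <- sort(unique(as.integer(phantom$labels)))
  best_w <- array(-Inf, phantom$grid_shape)
  labw <- array(labs[1], phantom$grid_shape)
  for (l in labs) {
    wl <- warp_image(array(as.double(phantom$labels == l),
                           phantom$grid_shape), moving)
    upd <- wl > best_w
    labw[upd] <- l
    best_w[upd] <- wl[upd]
  }
  list(e1 = wd + fd * ph1, e2 = wd + fd * ph2, field = field,
       labels_warped = labw, water = wd, fat = fd)
}
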