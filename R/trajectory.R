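# Variable-density golden-step Cartesian trajectory with spiral profile
# ordering (VD-CASPR).
#
# Construction (deterministic, no RNG):
#   1. Select the set of phase-encode points to acquire: every point inside
#      the fully sampled centre disk, plus outer points chosen by a
#      variable-density rule (radial density proportional to (1 - r)^p) using
#      a deterministic spatial hash as the selection key, so that the number
#      of unique acquired points is exactly round(ny * nz / accel).
#   2. Order the selected points into per-heartbeat spiral interleaves: each
#      point is assigned to the beat whose golden-step-rotated spiral arm is
#      angularly nearest to the point's spiral phase (theta - c * r), with
#      per-beat capacity enforced by spilling to the next arm; within a beat,
#      lines are sorted centre-out (centric in-out) and every beat starts by
#      (re-)acquiring the k-space centre, mirroring the centric-out-in /
#      centric-in-out adjacency of navigator and 3D acquisition.

#' Generate a VD-CASPR Cartesian trajectory
#'
#' @param ny,nz phase-encode grid size (AP, RL)
#' @param accel nominal undersampling factor (>= 1)
#' @param n_beats number of heartbeats available
#' @param lines_per_beat phase-encode lines acquired per heartbeat (including
#'   the centre line); `NULL` chooses the smallest capacity that covers the
#'   unique-line budget
#' @param golden_step_deg rotation between successive spiral interleaves
#'   (golden angle, 137.508 deg)
#' @param density_power exponent `p` of the radial density taper `(1 - r)^p`
#' @param center_frac radius of the fully sampled centre disk as a fraction
#'   of the maximum k-space radius
#' @param n_turns number of spiral turns from centre to edge of one interleaf
#' @return object of class `cartesian_trajectory`: `lines` data.frame with
#'   0-based `ky`, `kz` (DC at `floor(n/2)`), `beat`, `order_in_beat`;
#'   `ny`, `nz`, `accel_nominal`
#' @export
generate_vdcaspr <- function(ny, nz, accel, n_beats = 722,
                             lines_per_beat = NULL,
                             golden_step_deg = 137.508,
                             density_power = 1, center_frac = 0.1,
                             n_turns = 3) {
  stopifnot(ny >= 2, nz >= 2, accel >= 1, n_beats >= 1)
  n_total <- ny * nz
  n_target <- max(1L, round(n_total / accel))
  if (n_target > n_total) stop("acceleration below 1 is impossible")

  ky <- rep(0:(ny - 1), times = nz)
  kz <- rep(0:(nz - 1), each = ny)
  cy <- floor(ny / 2); cz <- floor(nz / 2)
  u <- (ky - cy) / (ny / 2); v <- (kz - cz) / (nz / 2)
  r <- sqrt(u^2 + v^2)
  rmax <- max(r)
  theta <- atan2(v, u)

  # deterministic spatial hash in [0, 1) as the selection key
  h <- (sin(ky * 12.9898 + kz * 78.233) * 43758.5453) %% 1
  w <- (1 - 0.95 * r / rmax)^density_power        # density weight, > 0
  key <- h / w
  key[r <= center_frac * rmax] <- -1              # centre disk always first
  sel <- order(key)[seq_len(n_target)]

  if (!is.null(lines_per_beat) && lines_per_beat > n_total)
    stop("lines_per_beat exceeds grid capacity")
  if (is.null(lines_per_beat))
    lines_per_beat <- ceiling(n_target / n_beats) + 1L
  capacity <- n_beats * (lines_per_beat - 1L)      # slot 0 is the centre
  if (capacity < n_target)
    warning("beat budget below the unique-line target; ",
            "coverage (and measured acceleration) will fall short")

  gamma <- golden_step_deg * pi / 180
  beat_angle <- ((seq_len(n_beats) - 1) * gamma) %% (2 * pi)
  # spiral phase of each selected point: the interleaf through it would have
  # offset theta - c_turn * r (Archimedean arm, angle growing with radius)
  c_turn <- 2 * pi * n_turns / rmax
  psi <- (theta[sel] - c_turn * r[sel]) %% (2 * pi)

  # nearest-arm assignment with capacity, via the sorted beat angles
  ord <- order(beat_angle)
  sorted_ang <- beat_angle[ord]
  pos <- findInterval(psi, sorted_ang)
  nb <- n_beats
  cand_lo <- ifelse(pos == 0, nb, pos)
  cand_hi <- ifelse(pos == nb, 1, pos + 1)
  d_lo <- pmin(abs(psi - sorted_ang[cand_lo]),
               2 * pi - abs(psi - sorted_ang[cand_lo]))
  d_hi <- pmin(abs(psi - sorted_ang[cand_hi]),
               2 * pi - abs(psi - sorted_ang[cand_hi]))
  pref <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)   # index into sorted order

  # fill beats centre-first so spilling pushes peripheral lines outward;
  # when the beat budget cannot hold every selected point the outermost
  # points are dropped (coverage shortfall already warned about above)
  counts <- integer(nb)
  assign_beat <- integer(length(sel))            # 0 = not acquired
  o_radial <- order(r[sel])
  filled <- 0L
  for (i in o_radial) {
    if (filled >= capacity) break
    j <- pref[i]
    while (counts[j] >= lines_per_beat - 1L) j <- (j %% nb) + 1L
    assign_beat[i] <- ord[j]                       # back to beat numbering
    counts[j] <- counts[j] + 1L
    filled <- filled + 1L
  }
  keep <- assign_beat > 0L
  sel <- sel[keep]
  assign_beat <- assign_beat[keep]

  # assemble per-beat line lists: centre line first, then centre-out
  sel_ky <- ky[sel]; sel_kz <- kz[sel]; sel_r <- r[sel]; sel_th <- theta[sel]
  o <- order(assign_beat, sel_r, sel_th)
  b <- assign_beat[o]
  beats_used <- sort(unique(b))
  n_lines <- length(o) + length(beats_used)
  out_ky <- integer(n_lines); out_kz <- integer(n_lines)
  out_beat <- integer(n_lines); out_ord <- integer(n_lines)
  ptr <- 1L
  idx_by_beat <- split(o, b)
  for (bb in beats_used) {
    ii <- idx_by_beat[[as.character(bb)]]
    # centre line first (re-acquired every beat; dedupe within the beat)
    kys <- c(cy, sel_ky[ii]); kzs <- c(cz, sel_kz[ii])
    dup <- duplicated(kys * nz + kzs)
    kys <- kys[!dup]; kzs <- kzs[!dup]
    m <- length(kys)
    out_ky[ptr:(ptr + m - 1)] <- kys
    out_kz[ptr:(ptr + m - 1)] <- kzs
    out_beat[ptr:(ptr + m - 1)] <- bb
    out_ord[ptr:(ptr + m - 1)] <- 0:(m - 1)
    ptr <- ptr + m
  }
  lines <- data.frame(ky = out_ky[seq_len(ptr - 1)],
                      kz = out_kz[seq_len(ptr - 1)],
                      beat = out_beat[seq_len(ptr - 1)],
                      order_in_beat = out_ord[seq_len(ptr - 1)])
  structure(list(lines = lines, ny = as.integer(ny), nz = as.integer(nz),
                 accel_nominal = accel),
            class = "cartesian_trajectory")
}

#' Binary sampling mask of a trajectory
#'
#' @param trajectory `cartesian_trajectory`
#' @param bins optional `bin_assignment` (see [assign_bins()]); if given,
#'   returns a list of per-bin masks instead of the pooled mask
#' @return `ny x nz` binary matrix (1 where some line acquired that
#'   location), or a list of such matrices per bin
#' @export
sampling_mask <- function(trajectory, bins = NULL) {
  stopifnot(inherits(trajectory, "cartesian_trajectory"))
  mk <- function(lines) {
    m <- matrix(0, trajectory$ny, trajectory$nz)
    if (nrow(lines)) m[cbind(lines$ky + 1, lines$kz + 1)] <- 1
    m
  }
  if (is.null(bins)) return(mk(trajectory$lines))
  stopifnot(length(bins$labels) == nrow(trajectory$lines))
  lapply(seq_len(bins$n_bins) - 1L,
         function(b) mk(trajectory$lines[bins$labels == b, , drop = FALSE]))
}

#' Measured acceleration of a trajectory
#'
#' Total phase-encode grid positions divided by unique acquired positions.
#' @param trajectory `cartesian_trajectory`
#' @return acceleration factor (1 = fully sampled)
#' @export
measured_acceleration <- function(trajectory) {
  stopifnot(inherits(trajectory, "cartesian_trajectory"))
  n_unique <- sum(sampling_mask(trajectory) > 0)
  if (n_unique == 0) stop("trajectory acquired no lines")
  trajectory$ny * trajectory$nz / n_unique
}
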