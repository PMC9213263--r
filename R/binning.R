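# Respiratory binning and k-space linear-phase translational correction.

#' Sort acquired lines into respiratory bins
#'
#' Equal-count (quantile) binning of the per-line foot--head position.  The
#' per-bin centre is the median FH of its lines; the central bin is the bin
#' whose centre is nearest the overall FH median (the average breathing
#' position).  Degenerate bins (fewer distinct FH values than bins) are
#' merged with a warning.
#'
#' @param fh_per_line numeric vector of per-line FH positions (mm)
#' @param n_bins number of bins (default 5)
#' @param rl_per_line optional per-line RL positions; if given, per-bin RL
#'   centres are returned alongside the FH centres
#' @return object of class `bin_assignment`: `n_bins`, `labels` (per-line
#'   bin index, 0-based), `edges` (length `n_bins + 1`), `centers`,
#'   `centers_rl` (or zeros), `central_bin` (0-based)
#' @export
assign_bins <- function(fh_per_line, n_bins = 5, rl_per_line = NULL) {
  stopifnot(n_bins >= 1, all(is.finite(fh_per_line)))
  n <- length(fh_per_line)
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- unname(quantile(fh_per_line, probs, type = 7))
  if (anyDuplicated(edges)) {
    edges <- unique(edges)
    if (length(edges) < 2) edges <- c(edges, edges + 1e-9)
    warning("fewer distinct FH values than bins; merged degenerate bins")
  }
  nb <- length(edges) - 1L
  labels <- findInterval(fh_per_line, edges, rightmost.closed = TRUE,
                         all.inside = TRUE) - 1L
  centers <- vapply(0:(nb - 1),
                    function(b) median(fh_per_line[labels == b]), 0)
  centers_rl <- if (is.null(rl_per_line)) rep(0, nb) else
    vapply(0:(nb - 1), function(b) median(rl_per_line[labels == b]), 0)
  central <- which.min(abs(centers - median(fh_per_line))) - 1L
  structure(list(n_bins = nb, labels = labels, edges = edges,
                 centers = centers, centers_rl = centers_rl,
                 central_bin = central,
                 fh = fh_per_line,
                 rl = if (is.null(rl_per_line)) rep(0, n) else rl_per_line),
            class = "bin_assignment")
}

#' k-space linear-phase translational correction
#'
#' Translates each line's content from its estimated position toward a
#' target position by modulating the line with a linear phase: a shift of
#' `d` voxels along an axis multiplies the centered-convention k-space by
#' `exp(-2i pi k d / n)`.  FH acts along the (fully sampled) readout, RL as
#' a constant phase per line through its kz index.  Sample magnitudes are
#' unchanged (unitary per line).
#'
#' @param kspace complex array `[echo, coil, line, kx]`
#' @param lines line table (`ky`, `kz`, `beat`, ...) matching dim 3
#' @param shifts per-line matrix/data.frame with columns `fh_mm`, `rl_mm`
#'   (estimated positions)
#' @param target per-line (or single-row) data.frame with columns `fh_mm`,
#'   `rl_mm`: the position each line is corrected toward
#' @param voxel_mm length-3 voxel size (mm)
#' @param nz RL grid size (for the kz phase)
#' @return corrected k-space array (same shape)
#' @export
phase_shift_correct <- function(kspace, lines, shifts, target, voxel_mm,
                                nz) {
  nl <- dim(kspace)[3]; nx <- dim(kspace)[4]
  stopifnot(nrow(lines) == nl, nrow(shifts) == nl)
  if (nrow(target) == 1) target <- target[rep(1, nl), , drop = FALSE]
  stopifnot(nrow(target) == nl)
  if (any(!is.finite(shifts$fh_mm)) || any(!is.finite(shifts$rl_mm)))
    stop("missing shift estimate for at least one line")
  d_fh <- (target$fh_mm - shifts$fh_mm) / voxel_mm[1]   # voxels along FH
  d_rl <- (target$rl_mm - shifts$rl_mm) / voxel_mm[3]   # voxels along RL
  kx <- kindex(nx)
  kz <- lines$kz - floor(nz / 2)                         # centered kz index
  out <- kspace
  for (l in seq_len(nl)) {
    if (d_fh[l] == 0 && d_rl[l] == 0) next
    phase <- exp(-2i * pi * (kx * d_fh[l] / nx + kz[l] * d_rl[l] / nz))
    out[, , l, ] <- sweep(array(kspace[, , l, ], dim(kspace)[c(1, 2, 4)]),
                          3, phase, `*`)
  }
  out
}

#' Grid corrected lines onto the Cartesian k-space raster
#'
#' Places the readout columns of the selected lines at their (ky, kz)
#' locations; repeated acquisitions of the same location are averaged.
#'
#' @param kspace complex array `[echo, coil, line, kx]`
#' @param lines line table matching dim 3
#' @param grid_shape length-3 image grid (nx, ny, nz)
#' @param echo echo to grid (1 or 2)
#' @param rows optional subset of line rows (e.g. one bin)
#' @return list `data` (complex array `[nx, ny, nz, coil]`), `mask`
#'   (`ny x nz` binary)
#' @export
grid_kspace <- function(kspace, lines, grid_shape, echo = 1,
                        rows = seq_len(nrow(lines))) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  nc <- dim(kspace)[2]
  data <- array(0i, c(nx, ny, nz, nc))
  counts <- matrix(0, ny, nz)
  for (l in rows) {
    iy <- lines$ky[l] + 1L; iz <- lines$kz[l] + 1L
    counts[iy, iz] <- counts[iy, iz] + 1
    for (c in seq_len(nc))
      data[, iy, iz, c] <- data[, iy, iz, c] + kspace[echo, c, l, ]
  }
  hit <- counts > 0
  for (iy in seq_len(ny)) for (iz in seq_len(nz)) {
    if (counts[iy, iz] > 1)
      data[, iy, iz, ] <- data[, iy, iz, ] / counts[iy, iz]
  }
  list(data = data, mask = (counts > 0) * 1)
}

#' Summarize a bin assignment
#'
#' @param bins `bin_assignment`
#' @return list with per-bin line counts, FH centres, edges and the central
#'   bin index (0-based); serializable to JSON
#' @export
bin_report <- function(bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  list(n_bins = bins$n_bins,
       counts = as.integer(tabulate(bins$labels + 1L, nbins = bins$n_bins)),
       centers_fh_mm = bins$centers,
       centers_rl_mm = bins$centers_rl,
       edges_mm = bins$edges,
       central_bin = bins$central_bin)
}

#' Shift selected lines' content by a constant voxel displacement
#'
#' Exact Fourier-domain translation of the content of the given lines by
#' `d_vox` voxels (FH, AP, RL): FH along the readout, AP and RL as constant
#' phases per line via the line's (ky, kz) indices.
#'
#' @param kspace complex array `[echo, coil, line, kx]`
#' @param lines line table matching dim 3
#' @param rows line rows to shift
#' @param d_vox length-3 displacement (voxels); positive moves content
#'   toward higher indices
#' @param grid_shape length-3 image grid
#' @return shifted k-space array
#' @export
shift_lines_vox <- function(kspace, lines, rows, d_vox, grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  stopifnot(dim(kspace)[4] == nx)
  kx <- kindex(nx)
  phx <- exp(-2i * pi * kx * d_vox[1] / nx)
  out <- kspace
  for (l in rows) {
    ky_c <- lines$ky[l] - floor(ny / 2)
    kz_c <- lines$kz[l] - floor(nz / 2)
    phase <- phx * exp(-2i * pi * (ky_c * d_vox[2] / ny +
                                     kz_c * d_vox[3] / nz))
    out[, , l, ] <- sweep(array(kspace[, , l, ], dim(kspace)[c(1, 2, 4)]),
                          3, phase, `*`)
  }
  out
}

#' Rank-based histogram equalization
#'
#' Monotone remap of the voxel intensities to a uniform `[0, 1]` histogram
#' (stable average ranks on ties); invariant under any strictly monotone
#' intensity warp of the input, which makes respiratory-bin images with
#' different signal scales comparable before registration.
#'
#' @param volume nonnegative real array
#' @return array of the same shape with values in `[0, 1]`
#' @export
histogram_equalize <- function(volume) {
  stopifnot(all(is.finite(volume)), all(volume >= 0))
  n <- length(volume)
  if (max(volume) == min(volume)) return(array(0, dim(volume)))
  r <- rank(volume, ties.method = "average")
  array((r - 1) / (n - 1), dim(volume))
}
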