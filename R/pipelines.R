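# End-to-end reconstruction pipelines: uncorrected, translational (TC) and
# non-rigid motion-compensated (NRC).

#' Half-resolution respiratory-bin reconstructions
#'
#' For each bin, takes the (already bin-centre-corrected) lines, crops to
#' the central half-size k-space region along all axes, and runs
#' [itsense()] on the half grid with block-averaged coil maps.  Only the
#' opposed-phase echo is reconstructed (the estimated fields are applied to
#' both echoes downstream).
#'
#' With `soft_sigma_mm` set (respiratory-weighted, "soft" binning), each
#' bin's image additionally borrows lines from neighbouring respiratory
#' positions with Gaussian weights in the FH distance to the bin centre;
#' borrowed lines are first translated to the target bin's centre by an
#' exact k-space phase shift.  This trades a small amount of residual
#' non-rigid blur for a large reduction in per-bin undersampling artifact,
#' which is what limits the bin-to-bin registration.
#'
#' @param kspace complex array `[echo, coil, line, kx]` (corrected)
#' @param lines line table matching dim 3
#' @param bins `bin_assignment` over the same lines
#' @param coils `coil_sensitivities` on the full grid
#' @param grid_shape full image grid (nx, ny, nz)
#' @param level `"half"` (default) or `"full"`
#' @param echo echo to reconstruct (default 1, opposed-phase)
#' @param cg `cg_params` for the per-bin solves
#' @param soft_sigma_mm Gaussian width (mm) of the respiratory weighting;
#'   `NULL` for hard binning (bin's own lines only)
#' @param voxel_mm length-3 voxel size (mm); required with `soft_sigma_mm`
#' @return list of per-bin complex volumes at the requested resolution
#' @export
reconstruct_bin_images <- function(kspace, lines, bins, coils, grid_shape,
                                   level = c("half", "full"), echo = 1,
                                   cg = cg_params(max_iter = 15),
                                   soft_sigma_mm = NULL, voxel_mm = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(bins, "bin_assignment"),
            length(bins$labels) == nrow(lines))
  counts <- tabulate(bins$labels + 1L, nbins = bins$n_bins)
  if (any(counts == 0)) stop("every bin must contain at least one line")
  if (any(counts < 0.01 * nrow(lines)))
    warning("bin with under 1% of lines; expect a poor bin image")
  if (!is.null(soft_sigma_mm)) stopifnot(!is.null(voxel_mm))
  gs <- as.integer(grid_shape)
  if (level == "full") {
    hs <- gs
    coils_h <- coils
    keep_kx <- seq_len(gs[1])
  } else {
    hs <- gs %/% 2L
    coils_h <- downsample_coils(coils, 2)
    c0 <- floor(gs[1] / 2) + 1
    keep_kx <- (c0 - floor(hs[1] / 2)):(c0 + ceiling(hs[1] / 2) - 1)
  }
  # centered phase-encode indices and the half-window test
  ky_c <- lines$ky - floor(gs[2] / 2)
  kz_c <- lines$kz - floor(gs[3] / 2)
  in_win <- ky_c >= -floor(hs[2] / 2) & ky_c <= ceiling(hs[2] / 2) - 1 &
            kz_c >= -floor(hs[3] / 2) & kz_c <= ceiling(hs[3] / 2) - 1
  scale <- sqrt(prod(hs) / prod(gs))   # keep image intensities comparable
  kx_h <- kindex(hs[1])
  out <- vector("list", bins$n_bins)
  eff_fh <- numeric(bins$n_bins)
  eff_rl <- numeric(bins$n_bins)
  for (b in seq_len(bins$n_bins) - 1L) {
    if (is.null(soft_sigma_mm)) {
      rows <- which(bins$labels == b & in_win)
      w <- rep(1, length(rows))
      d_fh <- rep(0, length(rows)); d_rl <- rep(0, length(rows))
    } else {
      ctr <- bins$centers[b + 1]; ctr_rl <- bins$centers_rl[b + 1]
      own_ctr <- bins$centers[bins$labels + 1L]
      own_rl <- bins$centers_rl[bins$labels + 1L]
      wall <- exp(-0.5 * ((own_ctr - ctr) / soft_sigma_mm)^2)
      rows <- which(in_win & wall > 0.05)
      w <- wall[rows]
      # translate borrowed lines from their own centre to this bin's centre
      d_fh <- (ctr - own_ctr[rows]) / voxel_mm[1] / (gs[1] / hs[1])
      d_rl <- (ctr_rl - own_rl[rows]) / voxel_mm[3] / (gs[3] / hs[3])
    }
    data <- array(0i, c(hs, coils_h$n_coils))
    wsum <- matrix(0, hs[2], hs[3])
    for (j in seq_along(rows)) {
      l <- rows[j]
      iy <- ky_c[l] + floor(hs[2] / 2) + 1L
      iz <- kz_c[l] + floor(hs[3] / 2) + 1L
      ph <- if (d_fh[j] != 0 || d_rl[j] != 0)
        exp(-2i * pi * (kx_h * d_fh[j] / hs[1] +
                          (iz - floor(hs[3] / 2) - 1) * d_rl[j] / hs[3]))
      else 1
      wsum[iy, iz] <- wsum[iy, iz] + w[j]
      for (c in seq_len(coils_h$n_coils))
        data[, iy, iz, c] <- data[, iy, iz, c] +
          w[j] * ph * kspace[echo, c, l, keep_kx] * scale
    }
    for (iy in seq_len(hs[2])) for (iz in seq_len(hs[3]))
      if (wsum[iy, iz] > 0) data[, iy, iz, ] <- data[, iy, iz, ] / wsum[iy, iz]
    sol <- itsense(data, coils_h, (wsum > 0) * 1, cg)
    out[[b + 1]] <- sol$image
    # effective respiratory state of the image: soft weighting mixes
    # anatomies, so the non-rigid content corresponds to the weighted mean
    # FH position, not the nominal bin centre
    eff_fh[b + 1] <- sum(w * bins$fh[rows]) / sum(w)
    eff_rl[b + 1] <- sum(w * bins$rl[rows]) / sum(w)
  }
  attr(out, "eff_fh") <- eff_fh
  attr(out, "eff_rl") <- eff_rl
  out
}

#' Downsample a volume by central k-space cropping
#'
#' Fourier-domain decimation consistent with the half-resolution bin
#' reconstructions (intensity-preserving scaling).
#' @param img real or complex 3D array
#' @param out_shape target grid
#' @export
kspace_downsample <- function(img, out_shape) {
  out <- kifft(kcrop(kfft(img), out_shape)) *
    sqrt(prod(out_shape) / length(img))
  if (is.complex(img)) out else Re(out)
}

# per-line shift table from per-beat tracking estimates
line_shifts <- function(track, lines) {
  i <- match(lines$beat, track$beat)
  if (any(is.na(i))) stop("missing navigator estimate for acquired beat")
  data.frame(fh_mm = track$fh_mm[i], rl_mm = track$rl_mm[i])
}

#' Uncorrected iterative SENSE reconstruction of a simulated scan
#'
#' @param scan output of [simulate_scan()] (or [load_container()])
#' @param cg `cg_params`
#' @return list `echo1`, `echo2` (complex volumes), `info`
#' @export
run_uncorrected <- function(scan, cg = cg_params()) {
  gs <- scan$truth$phantom$grid_shape
  out <- lapply(1:2, function(e) {
    g <- grid_kspace(scan$kspace, scan$lines, gs, echo = e)
    itsense(g$data, scan$coils, g$mask, cg)
  })
  list(echo1 = out[[1]]$image, echo2 = out[[2]]$image,
       info = list(resids = lapply(out, `[[`, "resids")))
}

#' Translational motion-corrected reconstruction (TC)
#'
#' Tracks the navigator template, modulates every line's k-space with a
#' linear phase shifting its content toward the average global breathing
#' position, and reconstructs each echo with [itsense()].
#'
#' @param scan output of [simulate_scan()] (or [load_container()])
#' @param cg `cg_params`
#' @return list `echo1`, `echo2`, `shifts` (per-beat table), `target`,
#'   `info`
#' @export
run_tc <- function(scan, cg = cg_params()) {
  gs <- scan$truth$phantom$grid_shape
  vx <- scan$truth$phantom$voxel_mm
  track <- track_template(scan$inav)
  sh <- line_shifts(track, scan$lines)
  target <- data.frame(fh_mm = mean(sh$fh_mm), rl_mm = mean(sh$rl_mm))
  kc <- phase_shift_correct(scan$kspace, scan$lines, sh, target, vx, gs[3])
  out <- lapply(1:2, function(e) {
    g <- grid_kspace(kc, scan$lines, gs, echo = e)
    itsense(g$data, scan$coils, g$mask, cg)
  })
  list(echo1 = out[[1]]$image, echo2 = out[[2]]$image, shifts = track,
       target = target,
       info = list(resids = lapply(out, `[[`, "resids")))
}

#' Non-rigid motion-compensated reconstruction (NRC)
#'
#' Full pipeline: navigator tracking, FH respiratory binning, per-bin
#' translational correction to the bin centres, half-resolution bin
#' reconstructions of the opposed-phase echo, histogram equalization and
#' B-spline registration to the central bin, field interpolation to full
#' resolution, and per-echo non-rigid motion-compensated iterative SENSE.
#'
#' @param scan output of [simulate_scan()] (or [load_container()])
#' @param n_bins respiratory bins (default from the scan parameters)
#' @param cg `cg_params` for the final solves
#' @param cg_bins `cg_params` for the half-resolution bin solves
#' @param reg settings from [register_settings()]
#' @param soft_sigma_mm width of the respiratory weighting for the bin
#'   images (see [reconstruct_bin_images()]); `NA` (default) uses the mean
#'   inter-bin-centre spacing, `NULL` disables soft weighting
#' @param pool_fields if `TRUE` (default), constrain the spatially varying
#'   parts of the per-bin fields to a single spatial profile scaled by each
#'   bin's respiratory amplitude offset (a rank-1 respiratory motion model):
#'   inter-bin deformation in free breathing scales with the FH excursion,
#'   and pooling the four registrations onto one profile averages down
#'   registration noise from the undersampled bin images
#' @return list `echo1`, `echo2`, `shifts`, `bins`, `fields` (full-res,
#'   per bin), `bin_images` (half-res, histogram-equalized), `info`
#' @export
run_nrc <- function(scan, n_bins = NULL, cg = cg_params(),
                    cg_bins = cg_params(max_iter = 20),
                    reg = register_settings(max_update = 0.2, lambda = 0.02,
                                            smooth_sigma = 1, max_iter = 60),
                    pool_fields = TRUE, soft_sigma_mm = NA) {
  gs <- scan$truth$phantom$grid_shape
  vx <- scan$truth$phantom$voxel_mm
  if (is.null(n_bins)) n_bins <- scan$params$n_bins
  track <- track_template(scan$inav)
  sh <- line_shifts(track, scan$lines)
  bins <- assign_bins(sh$fh_mm, n_bins, rl_per_line = sh$rl_mm)
  target <- data.frame(fh_mm = bins$centers[bins$labels + 1L],
                       rl_mm = bins$centers_rl[bins$labels + 1L])
  kc <- phase_shift_correct(scan$kspace, scan$lines, sh, target, vx, gs[3])

  # respiratory-weighted bin images (default width: the inter-bin spacing);
  # hard binning when there is a single (possibly merged) bin
  if (length(soft_sigma_mm) == 1 && is.na(soft_sigma_mm))
    soft_sigma_mm <- if (bins$n_bins > 1) mean(diff(sort(bins$centers)))
                     else NULL
  if (!is.null(soft_sigma_mm) &&
      (!is.finite(soft_sigma_mm) || soft_sigma_mm <= 0))
    soft_sigma_mm <- NULL
  bin_imgs <- reconstruct_bin_images(kc, scan$lines, bins, scan$coils, gs,
                                     level = "half", echo = 1, cg = cg_bins,
                                     soft_sigma_mm = soft_sigma_mm,
                                     voxel_mm = vx)
  eq <- lapply(bin_imgs, function(v) histogram_equalize(abs(v)))
  cb <- bins$central_bin + 1L
  hs <- dim(eq[[1]])
  fields <- vector("list", bins$n_bins)
  inits <- vector("list", bins$n_bins)
  for (b in seq_len(bins$n_bins)) {
    if (b == cb) {
      fields[b] <- list(NULL)   # identity warp for the central bin
    } else {
      # navigator-derived inter-bin translation (full-grid voxels): data in
      # bin b sit at their own centre after the per-bin correction
      inits[[b]] <- c((bins$centers[b] - bins$centers[cb]) / vx[1],
                      0,
                      (bins$centers_rl[b] - bins$centers_rl[cb]) / vx[3])
      fh <- register_nonrigid(eq[[b]], eq[[cb]], reg,
                              resolution_level = "half",
                              init = inits[[b]] * (hs / gs))
      fields[[b]] <- upsample_field(fh, gs)
    }
  }

  # rank-1 respiratory-motion-model pooling with empirical shrinkage:
  # model the registration output as u_b(x) = init_b + c_b * psi(x), where
  # c_b is the bin's FH centre offset and psi one shared deviation profile
  # (deformation plus any translation the navigator cannot see, e.g. AP).
  # psi is the least-squares fit over bins; the scatter of the per-bin
  # deviations around the fit estimates the registration noise, and psi is
  # shrunk by the fraction of its power that noise explains -- a scan with
  # purely translational motion therefore falls back to the navigator
  # solution.
  if (isTRUE(pool_fields)) {
    # regression abscissa: the bin images' effective FH states (soft
    # weighting attenuates the non-rigid content toward the centre, and the
    # effective states undo exactly that attenuation); the final fields are
    # evaluated at the true (hard) bin centres
    eff <- attr(bin_imgs, "eff_fh")
    if (is.null(eff)) eff <- bins$centers
    ce <- (eff - eff[cb]) / vx[1]
    cc <- (bins$centers - bins$centers[cb]) / vx[1]
    active <- which(!vapply(fields, is.null, TRUE))
    nb <- length(active)
    cbar <- mean(ce[active])
    Sc <- sum((ce[active] - cbar)^2)
    if (Sc > 0 && nb >= 4) {
      # per-voxel regression dev_b = m + ce_b * psi + eps across bins: the
      # intercept m absorbs errors common to every registration (they all
      # share the central-bin image) and is discarded -- physically the
      # inter-bin deviation vanishes at the central position
      devs <- lapply(active, function(b) {
        f <- fields[[b]]
        list(ux = f$ux - inits[[b]][1], uy = f$uy - inits[[b]][2],
             uz = f$uz - inits[[b]][3])
      })
      psi <- list(ux = array(0, gs), uy = array(0, gs), uz = array(0, gs))
      dbar <- list(ux = array(0, gs), uy = array(0, gs), uz = array(0, gs))
      for (i in seq_len(nb)) for (cm in c("ux", "uy", "uz"))
        dbar[[cm]] <- dbar[[cm]] + devs[[i]][[cm]] / nb
      for (i in seq_len(nb)) {
        wgt <- (ce[active[i]] - cbar) / Sc
        for (cm in c("ux", "uy", "uz"))
          psi[[cm]] <- psi[[cm]] + wgt * (devs[[i]][[cm]] - dbar[[cm]])
      }
      s2 <- 0
      for (i in seq_len(nb)) {
        d <- ce[active[i]] - cbar
        s2 <- s2 +
          mean((devs[[i]]$ux - dbar$ux - d * psi$ux)^2 +
                 (devs[[i]]$uy - dbar$uy - d * psi$uy)^2 +
                 (devs[[i]]$uz - dbar$uz - d * psi$uz)^2)
      }
      s2 <- s2 / (nb - 2)                  # residual noise per bin
      var_psi <- s2 / Sc                   # sampling variance of psi-hat
      p2 <- mean(psi$ux^2 + psi$uy^2 + psi$uz^2)
      kappa <- max(0, 1 - var_psi / max(p2, .Machine$double.eps))
      attr(fields, "kappa") <- kappa
      for (b in active) {
        fields[[b]] <- deformation_field(
          inits[[b]][1] + cc[b] * kappa * psi$ux,
          inits[[b]][2] + cc[b] * kappa * psi$uy,
          inits[[b]][3] + cc[b] * kappa * psi$uz, "full")
      }
    }
  }

  # split each estimated field into its mean translation, applied exactly as
  # a k-space linear phase shift of the bin's lines (as for TC), and the
  # spatially varying residual, which enters the warp operator; the warp
  # then never has to represent a plain translation by interpolation
  fields_total <- fields
  for (b in seq_len(bins$n_bins)) {
    f <- fields[[b]]
    if (is.null(f)) next
    t_b <- c(mean(f$ux), mean(f$uy), mean(f$uz))
    rows <- which(bins$labels == b - 1L)
    kc <- shift_lines_vox(kc, scan$lines, rows, -t_b, gs)
    fields[[b]] <- deformation_field(f$ux - t_b[1], f$uy - t_b[2],
                                     f$uz - t_b[3], "full")
  }

  # normalize the per-bin weighting so that every acquired (ky,kz) location
  # carries unit total weight across bins: the densely re-acquired centre
  # would otherwise be counted once per bin, over-weighting low frequencies
  # relative to the pooled TC problem
  masks <- sampling_mask(scan$trajectory, bins)
  mult <- Reduce(`+`, masks)
  fac <- ifelse(mult > 0, 1 / sqrt(mult), 0)
  masks <- lapply(masks, function(m) m * fac)
  out <- lapply(1:2, function(e) {
    bk <- lapply(seq_len(bins$n_bins) - 1L, function(b) {
      y <- grid_kspace(kc, scan$lines, gs, echo = e,
                      rows = which(bins$labels == b))$data
      sweep(y, 2:3, fac, `*`)
    })
    spec <- encoding_spec(scan$coils, masks, fields)
    mc_itsense(bk, spec, cg)
  })
  # present the result at the average global breathing position (the same
  # reference position as TC), by an exact sub-voxel Fourier shift from the
  # central-bin centre
  d_out <- c((mean(sh$fh_mm) - bins$centers[cb]) / vx[1], 0,
             (mean(sh$rl_mm) - bins$centers_rl[cb]) / vx[3])
  e1 <- fourier_shift(out[[1]]$image, d_out)
  e2 <- fourier_shift(out[[2]]$image, d_out)
  list(echo1 = e1, echo2 = e2, shifts = track,
       bins = bins, fields = fields, fields_total = fields_total,
       bin_images = eq,
       info = list(resids = lapply(out, `[[`, "resids"),
                   kappa = attr(fields, "kappa"),
                   output_shift_vox = d_out))
}
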