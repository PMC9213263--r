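# Contrast ratios, FWHM scar mass, and objective image-quality surrogates.

#' Contrast ratio between pooled regions of interest
#'
#' Mean signal intensity over the pooled numerator ROIs divided by the mean
#' over the pooled denominator ROIs (e.g. LGE-to-myocardium with three ROIs
#' each, or blood-to-myocardium with a luminal blood ROI).  Invariant to
#' global intensity scaling.
#'
#' @param image real volume
#' @param numerator_rois,denominator_rois a logical mask, an integer index
#'   vector, or a list of either (pooled)
#' @return scalar ratio
#' @export
contrast_ratio <- function(image, numerator_rois, denominator_rois) {
  pool <- function(rois) {
    if (!is.list(rois)) rois <- list(rois)
    unlist(lapply(rois, function(r) {
      if (is.logical(r)) which(r) else as.integer(r)
    }))
  }
  ni <- pool(numerator_rois); di <- pool(denominator_rois)
  if (!length(ni) || !length(di)) stop("empty ROI")
  if (max(ni, di) > length(image) || min(ni, di) < 1)
    stop("ROI outside the image grid")
  den <- mean(image[di])
  if (den <= 0) stop("non-positive denominator ROI mean")
  mean(image[ni]) / den
}

#' Myocardial contours
#'
#' @param shell_mask logical volume: myocardial shell (epicardium minus
#'   endocardium); the same (copied) mask must be used for every
#'   reconstruction being compared
#' @param voxel_volume_ml voxel volume in mL
#' @return object of class `myocardial_contours`
#' @export
myocardial_contours <- function(shell_mask, voxel_volume_ml) {
  stopifnot(is.logical(shell_mask), any(shell_mask), voxel_volume_ml > 0)
  structure(list(shell_mask = shell_mask,
                 voxel_volume_ml = voxel_volume_ml),
            class = "myocardial_contours")
}

#' FWHM scar mass
#'
#' Thresholds the myocardial shell at half of the maximal signal intensity
#' within it (full-width-at-half-maximum rule): voxels at or above the
#' threshold are scar; mass is voxel count times voxel volume times tissue
#' density.  Invariant to global intensity scaling.  On an all-zero shell
#' the mass is 0 with an empty mask; on a uniform shell every voxel meets
#' the half-max threshold (documented degenerate plateau).
#'
#' @param image real volume (signal intensities)
#' @param contours `myocardial_contours`
#' @param density_g_per_ml tissue density (default 1.05 g/mL)
#' @return list `mass_g`, `scar_mask` (logical volume), `threshold`
#' @export
fwhm_mass <- function(image, contours, density_g_per_ml = 1.05) {
  stopifnot(inherits(contours, "myocardial_contours"),
            identical(dim(image), dim(contours$shell_mask)))
  shell_vals <- image[contours$shell_mask]
  mx <- max(shell_vals)
  if (mx <= 0)
    return(list(mass_g = 0,
                scar_mask = array(FALSE, dim(image)), threshold = 0))
  thr <- 0.5 * mx
  scar <- contours$shell_mask & image >= thr
  list(mass_g = sum(scar) * contours$voxel_volume_ml * density_g_per_ml,
       scar_mask = scar, threshold = thr)
}

#' Edge sharpness surrogate
#'
#' Mean gradient magnitude within a boundary band, normalized by the
#' image's dynamic range; higher means sharper.  An objective stand-in for
#' visual border-sharpness scoring (e.g. the myocardium--blood-pool
#' interface).
#'
#' @param image real volume
#' @param boundary_band_mask logical volume selecting the boundary band
#' @return scalar sharpness
#' @export
edge_sharpness <- function(image, boundary_band_mask) {
  stopifnot(identical(dim(image), dim(boundary_band_mask)),
            any(boundary_band_mask))
  rng <- max(image) - min(image)
  if (rng == 0) stop("zero dynamic range")
  gm <- sqrt(grad_axis(image, 1)^2 + grad_axis(image, 2)^2 +
               grad_axis(image, 3)^2)
  mean(gm[boundary_band_mask]) / rng
}

#' Root-mean-square error after global intensity matching
#'
#' Least-squares global scale of the image onto the reference, then RMS
#' magnitude difference over the mask; invariant to global scaling of
#' either input.
#'
#' @param image,reference real or complex volumes on one grid
#' @param mask logical volume (default: everywhere)
#' @return scalar RMSE (in reference intensity units)
#' @export
rmse <- function(image, reference, mask = NULL) {
  stopifnot(identical(dim(image), dim(reference)))
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  stopifnot(identical(dim(mask), dim(image)), any(mask))
  a <- Mod(image[mask]); b <- Mod(reference[mask])
  s <- sum(a * b) / sum(a * a)
  sqrt(mean((s * a - b)^2))
}

#' Boundary band between two label regions
#'
#' Voxels within `width` voxels (Chebyshev distance) of the interface
#' between two masks; used to build the myocardium--blood sharpness band
#' from phantom truth labels.
#'
#' @param mask_a,mask_b logical volumes
#' @param width band half-width in voxels
#' @return logical volume
#' @export
boundary_band <- function(mask_a, mask_b, width = 1) {
  dil <- function(m, k) {
    out <- m
    for (i in seq_len(k)) {
      d <- dim(out)
      sh <- function(ax, by) {
        idx <- lapply(d, seq_len)
        idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
        do.call(`[`, c(list(out), idx, list(drop = FALSE)))
      }
      out <- out | sh(1, 1) | sh(1, -1) | sh(2, 1) | sh(2, -1) |
        sh(3, 1) | sh(3, -1)
    }
    out
  }
  dil(mask_a, width) & dil(mask_b, width)
}
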