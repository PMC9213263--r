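# Digital water/fat cardiac phantom and acquisition parameters.

#' Acquisition parameters
#'
#' Sequence parameters of the free-breathing dual-echo inversion-recovery
#' spoiled gradient-echo 3D LGE acquisition.  Defaults are the published
#' protocol: TR 7.2 ms, TE1/TE2 = 2.38/4.76 ms, flip 20 deg, FOV 312 mm,
#' matrix 240, 3.3-fold undersampling, five respiratory bins, TI around
#' 245 ms.  The fat chemical shift defaults to `1/(2 TE1)` = 210.084 Hz so
#' that TE1 is exactly opposed-phase and TE2 exactly in-phase, which makes
#' two-point Dixon separation exact in the noiseless limit (a 1.5 T scanner
#' value of about -220 Hz can be set for realism).
#'
#' @param tr_ms repetition time (ms)
#' @param te1_ms,te2_ms echo times (ms), `te2_ms > te1_ms > 0`
#' @param flip_deg excitation flip angle (degrees)
#' @param fov_mm in-plane field of view (mm)
#' @param matrix in-plane matrix size (per axis, even)
#' @param n_slices number of slices (RL extent of the 3D slab)
#' @param accel nominal undersampling factor (>= 1)
#' @param n_bins number of respiratory bins (>= 1)
#' @param ti_ms inversion time (ms)
#' @param fat_shift_hz fat--water chemical shift (Hz)
#' @param noise_sd complex Gaussian noise SD per k-space sample (image-scale
#'   units under the unitary FFT convention)
#' @return object of class `acquisition_params`; `voxel_mm` is derived as
#'   `fov_mm / matrix` (isotropic)
#' @export
acquisition_params <- function(tr_ms = 7.2, te1_ms = 2.38, te2_ms = 4.76,
                               flip_deg = 20, fov_mm = 312, matrix = 240,
                               n_slices = 96, accel = 3.3, n_bins = 5,
                               ti_ms = 245,
                               fat_shift_hz = 1000 / (2 * te1_ms),
                               noise_sd = 0.005) {
  stopifnot(te1_ms > 0, te2_ms > te1_ms, accel >= 1, n_bins >= 1,
            matrix %% 2 == 0, noise_sd >= 0, fov_mm > 0, n_slices >= 1)
  structure(list(tr_ms = tr_ms, te1_ms = te1_ms, te2_ms = te2_ms,
                 flip_deg = flip_deg, fov_mm = fov_mm, matrix = matrix,
                 n_slices = n_slices, accel = accel, n_bins = n_bins,
                 ti_ms = ti_ms, fat_shift_hz = fat_shift_hz,
                 noise_sd = noise_sd,
                 voxel_mm = fov_mm / matrix),
            class = "acquisition_params")
}

#' Desk-scale acquisition parameters
#'
#' Same sequence timing as [acquisition_params()] on a 64 x 64 x 32 grid
#' with 2 mm isotropic voxels, sized for fast simulation experiments.
#' @param ... overrides passed to [acquisition_params()]
#' @export
desk_params <- function(...) {
  acquisition_params(fov_mm = 128, matrix = 64, n_slices = 32, ...)
}

# label codes for the phantom tissue map
PHANTOM_LABELS <- c(background = 0L, myocardium = 1L, blood = 2L, scar = 3L,
                    fat = 4L, chest_wall = 5L)

#' Build the digital water/fat cardiac phantom
#'
#' Constructs a left-ventricle-like anatomy on a named 3D grid: an
#' ellipsoidal-shell myocardium with interior blood pool, a subendocardial
#' scar sector, an epicardial fat rim and an anterior chest-wall slab.
#' Post-inversion LGE contrast is baked into the water map as effective
#' magnetizations (no Bloch simulation): blood > scar > fat-voxel water
#' component > remote myocardium (near-nulled).  The fat map is nonzero only
#' in fat and chest-wall labels.
#'
#' @param grid_shape integer length-3 (FH, AP, RL), each >= 32 and even
#' @param voxel_mm voxel size (scalar isotropic or length-3, mm)
#' @param scar_spec list with `theta0`, `theta1` (start/end angle of the scar
#'   sector in radians, measured in the FH-AP plane), `z_extent` (fraction of
#'   the RL semi-axis covered, in (0,1]) and `transmural` (fraction of the wall
#'   thickness from the endocardium, in (0,1]); set `z_extent = 0` or
#'   `theta0 == theta1` for a scar-free phantom
#' @param signal named numeric overrides of the effective magnetizations
#' @return object of class `tissue_phantom`: `water`, `fat` (real 3D maps),
#'   `labels` (integer 3D map), `grid_shape`, `voxel_mm`
#' @export
build_phantom <- function(grid_shape = c(64, 64, 32),
                          voxel_mm = c(2, 2, 2),
                          scar_spec = list(theta0 = -0.5, theta1 = 0.7,
                                           z_extent = 0.6, transmural = 0.55),
                          signal = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (any(grid_shape < 32) || any(grid_shape %% 2 != 0))
    stop("grid_shape must be even and at least 32 per axis")
  sig <- list(blood = 1.0, scar = 0.8, myocardium = 0.12,
              fat_water = 0.35, fat_fat = 0.8,
              chest_water = 0.3, chest_fat = 0.5)
  if (!is.null(signal)) sig[names(signal)] <- signal

  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  # normalized coordinates relative to the LV centre (slightly posterior)
  cx <- nx / 2 + 1; cy <- ny / 2 + 4; cz <- nz / 2 + 1
  x <- array(rep(seq_len(nx), times = ny * nz), grid_shape) - cx
  y <- array(rep(rep(seq_len(ny), each = nx), times = nz), grid_shape) - cy
  z <- array(rep(seq_len(nz), each = nx * ny), grid_shape) - cz

  # epicardial / endocardial ellipsoids (voxel semi-axes scale with the grid)
  ae <- 0.28 * nx; be <- 0.24 * ny; ce <- 0.30 * nz     # epicardium
  wall <- max(3, round(0.07 * nx))                       # wall thickness (vox)
  re2 <- (x / ae)^2 + (y / be)^2 + (z / ce)^2
  # inner ellipsoid scaled down by the wall thickness along each axis
  ai <- ae - wall; bi <- be - wall; ci <- ce - wall * ce / ae
  ri2 <- (x / ai)^2 + (y / bi)^2 + (z / ci)^2

  labels <- array(PHANTOM_LABELS[["background"]], grid_shape)
  labels[re2 <= 1] <- PHANTOM_LABELS[["myocardium"]]
  labels[ri2 <= 1] <- PHANTOM_LABELS[["blood"]]

  # subendocardial scar sector within the shell
  if (!is.null(scar_spec) && isTRUE(scar_spec$z_extent > 0) &&
      scar_spec$theta1 > scar_spec$theta0) {
    if (scar_spec$transmural > 1 || scar_spec$z_extent > 1)
      stop("scar_spec extends outside the myocardial shell")
    theta <- atan2(y, x)
    shell <- re2 <= 1 & ri2 > 1
    # transmural coordinate s: 0 at the endocardial surface (ri2 = 1),
    # 1 at the epicardial surface (re2 = 1), interpolated along the ray
    rho_i <- sqrt(pmax(ri2, 1e-12)); rho_e <- sqrt(pmax(re2, 1e-12))
    s <- (rho_i - 1) / pmax(rho_i - rho_e, 1e-12)
    in_sector <- theta >= scar_spec$theta0 & theta <= scar_spec$theta1
    in_z <- abs(z) <= scar_spec$z_extent * ce
    subendo <- shell & s <= scar_spec$transmural
    scar <- shell & in_sector & in_z & subendo
    labels[scar] <- PHANTOM_LABELS[["scar"]]
  }

  # epicardial fat rim: thin layer just outside the epicardium, lateral side
  rim <- re2 > 1 & (x / (ae + 2))^2 + (y / (be + 2))^2 + (z / (ce + 2))^2 <= 1
  labels[rim & labels == PHANTOM_LABELS[["background"]]] <- PHANTOM_LABELS[["fat"]]

  # anterior chest-wall slab (low y = anterior)
  slab <- y + cy <= max(4, round(0.1 * ny))
  labels[slab & labels == PHANTOM_LABELS[["background"]]] <- PHANTOM_LABELS[["chest_wall"]]

  water <- array(0, grid_shape); fat <- array(0, grid_shape)
  water[labels == PHANTOM_LABELS[["myocardium"]]] <- sig$myocardium
  water[labels == PHANTOM_LABELS[["blood"]]] <- sig$blood
  water[labels == PHANTOM_LABELS[["scar"]]] <- sig$scar
  water[labels == PHANTOM_LABELS[["fat"]]] <- sig$fat_water
  water[labels == PHANTOM_LABELS[["chest_wall"]]] <- sig$chest_water
  fat[labels == PHANTOM_LABELS[["fat"]]] <- sig$fat_fat
  fat[labels == PHANTOM_LABELS[["chest_wall"]]] <- sig$chest_fat

  structure(list(water = water, fat = fat, labels = labels,
                 grid_shape = grid_shape, voxel_mm = voxel_mm),
            class = "tissue_phantom")
}

#' Ground-truth scar mass of a phantom
#'
#' Scar voxel count times voxel volume times tissue density.
#' @param phantom `tissue_phantom`
#' @param density_g_per_ml myocardial density (g/mL), default 1.05
#' @return mass in grams
#' @export
phantom_scar_mass <- function(phantom, density_g_per_ml = 1.05) {
  n <- sum(phantom$labels == PHANTOM_LABELS[["scar"]])
  vox_ml <- prod(phantom$voxel_mm) / 1000
  n * vox_ml * density_g_per_ml
}

#' Label mask helper
#' @param phantom `tissue_phantom`
#' @param label one of `"myocardium"`, `"blood"`, `"scar"`, `"fat"`,
#'   `"chest_wall"`, `"background"`
#' @return logical 3D array
#' @export
phantom_mask <- function(phantom, label) {
  phantom$labels == PHANTOM_LABELS[[label]]
}
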