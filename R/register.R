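# Multi-resolution B-spline free-form-deformation registration with a
# mean-squares metric, used to estimate bin-to-bin non-rigid respiratory
# motion from histogram-equalized half-resolution bin images.

# cubic B-spline FFD basis matrix for one axis: n voxel positions,
# control-point spacing `delta` (voxels); returns n x K dense matrix
bspline_basis <- function(n, delta) {
  t <- (seq_len(n) - 1) / delta
  i <- floor(t)
  s <- t - i
  w <- cbind((1 - s)^3 / 6,
             (3 * s^3 - 6 * s^2 + 4) / 6,
             (-3 * s^3 + 3 * s^2 + 3 * s + 1) / 6,
             s^3 / 6)
  K <- max(i) + 4
  B <- matrix(0, n, K)
  for (k in 0:3) B[cbind(seq_len(n), i + k + 1)] <- w[, k + 1]
  B
}

# apply matrix A (m x d[dim]) along dimension `dim` of a 3D array
apply_along <- function(A, arr, dim) {
  d <- dim(arr)
  perm <- c(dim, setdiff(1:3, dim))
  m <- matrix(aperm(arr, perm), d[dim], prod(d[-dim]))
  out <- A %*% m
  out <- array(out, c(nrow(A), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

# evaluate the FFD: control array (Kx,Ky,Kz) -> dense field component
ffd_eval <- function(ctrl, Bx, By, Bz) {
  apply_along(Bz, apply_along(By, apply_along(Bx, ctrl, 1), 2), 3)
}

# transpose FFD: dense voxel gradient -> control-point gradient
ffd_backproject <- function(dense, Bx, By, Bz) {
  apply_along(t(Bz), apply_along(t(By), apply_along(t(Bx), dense, 1), 2), 3)
}

# smooth + decimate a volume by integer factor per axis
pyr_down <- function(vol, f) {
  if (all(f == 1)) return(vol)
  sm <- gauss_smooth(vol, 0.5 * f)
  d <- dim(vol)
  idx <- lapply(1:3, function(i) seq(1, d[i], by = f[i]))
  sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# resample a dense field (list ux,uy,uz in source-grid voxels) onto a new
# grid, scaling displacements by the grid ratio
field_resample <- function(ux, uy, uz, new_shape) {
  old <- dim(ux)
  scale <- new_shape / old
  coords <- lapply(1:3, function(i) (seq_len(new_shape[i]) - 1) / scale[i] + 1)
  cx <- array(rep(coords[[1]], times = new_shape[2] * new_shape[3]), new_shape)
  cy <- array(rep(rep(coords[[2]], each = new_shape[1]), times = new_shape[3]),
              new_shape)
  cz <- array(rep(coords[[3]], each = new_shape[1] * new_shape[2]), new_shape)
  list(ux = interp3_at(ux, cx, cy, cz) * scale[1],
       uy = interp3_at(uy, cx, cy, cz) * scale[2],
       uz = interp3_at(uz, cx, cy, cz) * scale[3])
}

# central-difference gradient of a volume along one axis
grad_axis <- function(vol, axis) {
  d <- dim(vol)
  n <- d[axis]
  hi <- pmin(seq_len(n) + 1, n); lo <- pmax(seq_len(n) - 1, 1)
  g <- switch(axis,
              (vol[hi, , , drop = FALSE] - vol[lo, , , drop = FALSE]),
              (vol[, hi, , drop = FALSE] - vol[, lo, , drop = FALSE]),
              (vol[, , hi, drop = FALSE] - vol[, , lo, drop = FALSE]))
  g / 2
}

#' Default registration settings
#'
#' @param control_spacing B-spline control-point spacing (voxels at the
#'   registration resolution)
#' @param n_levels pyramid levels (downsampling factors `2^(n_levels-1) ... 1`)
#' @param max_iter gradient-descent iterations per level
#' @param tol relative loss-improvement stopping tolerance
#' @param step0 initial maximum control-point update (voxels)
#' @param mask_quantile the mean-squares metric is restricted to voxels
#'   where the fixed image exceeds this intensity quantile (its tissue
#'   support), so that background and residual undersampling ghosts do not
#'   drive the deformation; set to 0 to use the whole volume
#' @param smooth_sigma additional Gaussian pre-smoothing (voxels) of both
#'   images at every pyramid level
#' @param lambda weight of the quadratic penalty pulling the displacement
#'   toward its initialization (per squared voxel, relative to the
#'   mean-squares metric); stabilizes the global modes of the deformation
#'   when the images carry undersampling ghosts
#' @param max_update trust region: per-level cap on the control-point
#'   update magnitude (voxels at that level); caps the additional
#'   deformation any one level may introduce beyond its initialization
#' @export
register_settings <- function(control_spacing = 6, n_levels = 3,
                              max_iter = 150, tol = 1e-6, step0 = 1,
                              mask_quantile = 0.5, smooth_sigma = 0.5,
                              lambda = 0.001, max_update = 2) {
  list(control_spacing = control_spacing, n_levels = n_levels,
       max_iter = max_iter, tol = tol, step0 = step0,
       mask_quantile = mask_quantile, smooth_sigma = smooth_sigma,
       lambda = lambda, max_update = max_update)
}

#' Non-rigid registration of two volumes
#'
#' Estimates the displacement field `u` (voxel units on the fixed grid) that
#' maps fixed-grid coordinates into the moving image,
#' `moving(r + u(r)) ~ fixed(r)`, by multi-resolution gradient descent on a
#' mean-squares metric over a cubic B-spline free-form deformation.  Inputs
#' are expected to be comparably scaled (e.g. [histogram_equalize()]d).
#'
#' For anatomy displaced by `+s` relative to the fixed image (i.e.
#' `moving = warp_image(fixed, scale_field(s, -1))` for smooth `s`), the
#' recovered field is `u ~ +s`.
#'
#' @param moving,fixed real 3D arrays on the same grid
#' @param settings list from [register_settings()]
#' @param resolution_level tag stored on the returned field (`"half"` for
#'   bin-image registration)
#' @param init optional initialization: length-3 numeric translation
#'   (voxels, input grid) or a `deformation_field` on the input grid;
#'   e.g. the navigator-derived inter-bin translation.  The `lambda`
#'   penalty shrinks each level's update toward zero, i.e. the total field
#'   toward this initialization plus coarser-level corrections.
#' @return `deformation_field`; attribute `converged` is `FALSE` when the
#'   metric could not be improved (best-so-far field returned)
#' @export
register_nonrigid <- function(moving, fixed,
                              settings = register_settings(),
                              resolution_level = "half", init = NULL) {
  stopifnot(identical(dim(moving), dim(fixed)), length(dim(moving)) == 3)
  d_full <- dim(moving)
  factors <- 2^((settings$n_levels - 1):0)
  ux <- uy <- uz <- NULL
  init_full <- NULL
  if (!is.null(init)) {
    if (inherits(init, "deformation_field")) {
      stopifnot(identical(init$grid_shape, as.integer(d_full)))
      init_full <- list(ux = init$ux, uy = init$uy, uz = init$uz)
    } else {
      stopifnot(is.numeric(init), length(init) == 3)
      init_full <- list(ux = array(init[1], d_full),
                        uy = array(init[2], d_full),
                        uz = array(init[3], d_full))
    }
  }
  converged <- TRUE
  for (f in factors) {
    fv <- pmin(c(f, f, f), pmax(1, d_full %/% 8))  # keep levels >= ~8 voxels
    M <- pyr_down(moving, fv); F <- pyr_down(fixed, fv)
    if (settings$smooth_sigma > 0) {
      M <- gauss_smooth(M, settings$smooth_sigma)
      F <- gauss_smooth(F, settings$smooth_sigma)
    }
    d <- dim(M)
    # metric support: tissue region of the fixed image, softly dilated
    if (settings$mask_quantile > 0) {
      msk <- (F >= quantile(F, settings$mask_quantile)) * 1
      msk <- (gauss_smooth(msk, 2) > 0.25) * 1
    } else msk <- array(1, d)
    nmask <- max(sum(msk), 1)
    if (is.null(ux)) {
      if (is.null(init_full)) {
        ux <- array(0, d); uy <- array(0, d); uz <- array(0, d)
      } else {
        r <- field_resample(init_full$ux, init_full$uy, init_full$uz, d)
        ux <- r$ux; uy <- r$uy; uz <- r$uz
      }
    } else if (!identical(dim(ux), d)) {
      r <- field_resample(ux, uy, uz, d)
      ux <- r$ux; uy <- r$uy; uz <- r$uz
    }
    delta <- max(2, settings$control_spacing)
    Bx <- bspline_basis(d[1], delta)
    By <- bspline_basis(d[2], delta)
    Bz <- bspline_basis(d[3], delta)
    K <- c(ncol(Bx), ncol(By), ncol(Bz))
    cx <- array(0, K); cy <- array(0, K); cz <- array(0, K)
    gx <- grad_axis(M, 1); gy <- grad_axis(M, 2); gz <- grad_axis(M, 3)
    dims_i <- as.integer(d)
    lam <- settings$lambda
    nvox <- length(M)
    loss_of <- function(wx, wy, wz) {
      Mw <- array(warp3_gather(M, dims_i, wx, wy, wz), d)
      sum(msk * (Mw - F)^2) / nmask +
        lam * sum((wx - ux)^2 + (wy - uy)^2 + (wz - uz)^2) / nvox
    }
    wx <- ux; wy <- uy; wz <- uz
    cur <- loss_of(wx, wy, wz)
    step <- settings$step0
    improved_any <- FALSE
    for (it in seq_len(settings$max_iter)) {
      Mw <- array(warp3_gather(M, dims_i, wx, wy, wz), d)
      resid <- 2 * msk * (Mw - F) / nmask
      gwx <- array(warp3_gather(gx, dims_i, wx, wy, wz), d)
      gwy <- array(warp3_gather(gy, dims_i, wx, wy, wz), d)
      gwz <- array(warp3_gather(gz, dims_i, wx, wy, wz), d)
      Gx <- ffd_backproject(resid * gwx + 2 * lam * (wx - ux) / nvox,
                            Bx, By, Bz)
      Gy <- ffd_backproject(resid * gwy + 2 * lam * (wy - uy) / nvox,
                            Bx, By, Bz)
      Gz <- ffd_backproject(resid * gwz + 2 * lam * (wz - uz) / nvox,
                            Bx, By, Bz)
      gmax <- max(abs(Gx), abs(Gy), abs(Gz))
      if (gmax == 0) break
      cap <- settings$max_update
      ok <- FALSE
      for (try in 1:12) {
        a <- step / gmax
        nx_ <- pmin(pmax(cx - a * Gx, -cap), cap)
        ny_ <- pmin(pmax(cy - a * Gy, -cap), cap)
        nz_ <- pmin(pmax(cz - a * Gz, -cap), cap)
        twx <- ux + ffd_eval(nx_, Bx, By, Bz)
        twy <- uy + ffd_eval(ny_, Bx, By, Bz)
        twz <- uz + ffd_eval(nz_, Bx, By, Bz)
        new <- loss_of(twx, twy, twz)
        if (new < cur) { ok <- TRUE; break }
        step <- step / 2
      }
      if (!ok) break
      rel <- (cur - new) / max(cur, .Machine$double.eps)
      cx <- nx_; cy <- ny_; cz <- nz_
      wx <- twx; wy <- twy; wz <- twz
      cur <- new
      improved_any <- TRUE
      step <- min(step * 1.5, 4 * settings$step0)
      if (rel < settings$tol) break
    }
    if (!improved_any && f == 1) converged <- FALSE
    ux <- wx; uy <- wy; uz <- wz
  }
  if (!identical(dim(ux), d_full)) {
    r <- field_resample(ux, uy, uz, d_full)
    ux <- r$ux; uy <- r$uy; uz <- r$uz
  }
  out <- deformation_field(ux, uy, uz, resolution_level)
  attr(out, "converged") <- converged
  out
}
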