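# Iterative SENSE solvers: plain itSENSE and non-rigid motion-compensated
# itSENSE via a generalized encoding operator solved with conjugate
# gradients on the normal equations.
#
# Encoding model, per respiratory bin b:
#   E_b x = M_b F S_c W_b x
# where W_b warps the reconstruction-grid image into bin-b anatomy
# (pull-back with the negated bin field, consistent with the simulator and
# the registration convention), S_c are the coil maps, F the centered
# unitary FFT and M_b the bin's sampling mask.  The adjoint uses the exact
# interpolation transpose of W_b (scatter), not the inverse warp.

#' Construct an encoding specification
#'
#' @param coils `coil_sensitivities` on the reconstruction grid
#' @param masks list of `ny x nz` binary per-bin masks (length = n bins)
#' @param fields list of per-bin `deformation_field`s (full resolution) or
#'   `NULL` entries for identity warps; `NULL` for all-identity
#' @param grid_shape length-3 image grid
#' @return object of class `encoding_spec`
#' @export
encoding_spec <- function(coils, masks, fields = NULL, grid_shape = NULL) {
  stopifnot(inherits(coils, "coil_sensitivities"), is.list(masks))
  if (is.null(grid_shape)) grid_shape <- coils$grid_shape
  stopifnot(identical(as.integer(coils$grid_shape),
                      as.integer(grid_shape)))
  nb <- length(masks)
  if (is.null(fields)) fields <- vector("list", nb)
  stopifnot(length(fields) == nb)
  for (f in fields)
    if (!is.null(f)) {
      stopifnot(inherits(f, "deformation_field"),
                identical(as.integer(f$grid_shape), as.integer(grid_shape)))
      if (f$resolution_level != "full")
        stop("encoding fields must be full resolution")
    }
  for (m in masks)
    stopifnot(nrow(m) == grid_shape[2], ncol(m) == grid_shape[3])
  structure(list(coils = coils, masks = masks, fields = fields,
                 grid_shape = as.integer(grid_shape), n_bins = nb),
            class = "encoding_spec")
}

#' Conjugate-gradient parameters
#'
#' @param max_iter maximum CG iterations (default 30)
#' @param tol relative residual stopping tolerance (default 1e-6)
#' @param verbose print per-iteration residuals
#' @export
cg_params <- function(max_iter = 30, tol = 1e-6, verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 verbose = isTRUE(verbose)),
            class = "cg_params")
}

# warp the image into bin anatomy: anatomy displaced by +u is rendered by
# pull-back with -u
bin_warp <- function(x, field) {
  if (is.null(field)) x else warp_image(x, scale_field(field, -1))
}

bin_warp_adjoint <- function(x, field) {
  if (is.null(field)) x else warp_adjoint(x, scale_field(field, -1))
}

# expand a ny x nz phase-encode mask over the readout axis
expand_mask <- function(mask, grid_shape) {
  array(rep(as.vector(mask), each = grid_shape[1]), grid_shape)
}

#' Forward encoding operator
#'
#' @param spec `encoding_spec`
#' @param x complex image on the reconstruction grid
#' @return list of per-bin complex arrays `[nx, ny, nz, coil]` (zero at
#'   unsampled locations)
#' @export
encode_forward <- function(spec, x) {
  stopifnot(identical(as.integer(dim(x)), spec$grid_shape))
  gs <- spec$grid_shape; nc <- spec$coils$n_coils
  out <- vector("list", spec$n_bins)
  for (b in seq_len(spec$n_bins)) {
    xb <- bin_warp(x, spec$fields[[b]])
    m3 <- expand_mask(spec$masks[[b]], gs)
    yb <- array(0i, c(gs, nc))
    for (c in seq_len(nc))
      yb[, , , c] <- kfft(spec$coils$maps[, , , c] * xb) * m3
    out[[b]] <- yb
  }
  out
}

#' Adjoint encoding operator
#'
#' @param spec `encoding_spec`
#' @param y list of per-bin arrays as produced by [encode_forward()]
#' @return complex image
#' @export
encode_adjoint <- function(spec, y) {
  stopifnot(length(y) == spec$n_bins)
  gs <- spec$grid_shape; nc <- spec$coils$n_coils
  x <- array(0i, gs)
  for (b in seq_len(spec$n_bins)) {
    stopifnot(identical(as.integer(dim(y[[b]])), as.integer(c(gs, nc))))
    m3 <- expand_mask(spec$masks[[b]], gs)
    acc <- array(0i, gs)
    for (c in seq_len(nc))
      acc <- acc + Conj(spec$coils$maps[, , , c]) * kifft(y[[b]][, , , c] * m3)
    x <- x + bin_warp_adjoint(acc, spec$fields[[b]])
  }
  x
}

# normal operator E^H E applied without materializing the data side twice
encode_normal <- function(spec, x) {
  gs <- spec$grid_shape; nc <- spec$coils$n_coils
  out <- array(0i, gs)
  for (b in seq_len(spec$n_bins)) {
    xb <- bin_warp(x, spec$fields[[b]])
    m3 <- expand_mask(spec$masks[[b]], gs)^2   # M^H M (masks may be weights)
    acc <- array(0i, gs)
    for (c in seq_len(nc)) {
      s <- spec$coils$maps[, , , c]
      acc <- acc + Conj(s) * kifft(kfft(s * xb) * m3)
    }
    out <- out + bin_warp_adjoint(acc, spec$fields[[b]])
  }
  out
}

# conjugate gradients on E^H E x = rhs
cg_solve <- function(spec, rhs, cg) {
  x <- array(0i, dim(rhs))
  r <- rhs
  p <- r
  rs <- sum(Mod(r)^2)
  rs0 <- rs
  resids <- numeric(0)
  n_up <- 0L
  flag <- "converged"
  for (it in seq_len(cg$max_iter)) {
    ap <- encode_normal(spec, p)
    alpha <- rs / Re(sum(Conj(p) * ap))
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(Mod(r)^2)
    resids <- c(resids, sqrt(rs_new / rs0))
    if (cg$verbose)
      message(sprintf("cg iter %d: rel resid %.3e", it, sqrt(rs_new / rs0)))
    if (rs_new > rs) n_up <- n_up + 1L else n_up <- 0L
    if (n_up >= 5) {
      warning("CG residual increased for 5 consecutive iterations; aborting")
      flag <- "diverged"
      break
    }
    if (sqrt(rs_new / rs0) < cg$tol) { rs <- rs_new; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (flag == "converged" && length(resids) == cg$max_iter &&
      resids[length(resids)] >= cg$tol) flag <- "max_iter"
  list(x = x, resids = resids, flag = flag)
}

#' Iterative SENSE reconstruction (single motion state)
#'
#' Solves `E^H E x = E^H y` by conjugate gradients with `E = M F S`
#' (sampling mask, unitary centered FFT, coil maps; identity warp).
#'
#' @param kspace complex array `[nx, ny, nz, coil]` gridded onto the mask
#' @param coils `coil_sensitivities`
#' @param mask `ny x nz` binary sampling mask
#' @param cg `cg_params`
#' @return list `image` (complex volume), `resids`, `flag`
#' @export
itsense <- function(kspace, coils, mask, cg = cg_params()) {
  spec <- encoding_spec(coils, list(mask))
  mc_itsense(list(kspace), spec, cg)
}

#' Non-rigid motion-compensated iterative SENSE
#'
#' Solves the multi-bin normal equations
#' `sum_b E_b^H E_b x = sum_b E_b^H y_b` with per-bin warps; with identity
#' fields and a single bin this reduces to [itsense()].  Bin data must
#' already be translationally corrected to their bin centres
#' ([phase_shift_correct()]); the solution lives on the central-bin
#' (average breathing position) anatomy.
#'
#' @param bin_kspace list of per-bin complex arrays `[nx, ny, nz, coil]`
#' @param spec `encoding_spec`
#' @param cg `cg_params`
#' @return list `image`, `resids`, `flag`
#' @export
mc_itsense <- function(bin_kspace, spec, cg = cg_params()) {
  stopifnot(inherits(spec, "encoding_spec"),
            length(bin_kspace) == spec$n_bins)
  rhs <- encode_adjoint(spec, bin_kspace)
  sol <- cg_solve(spec, rhs, cg)
  list(image = sol$x, resids = sol$resids, flag = sol$flag)
}
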