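# Deformation fields and image warping.

#' Construct a deformation field object
#'
#' Dense per-voxel displacement in voxel units on a 3D grid, components
#' ordered (FH, AP, RL).  Applied by pull-back resampling: see
#' [warp_image()].
#'
#' @param ux,uy,uz real 3D arrays of identical shape (displacement along FH,
#'   AP, RL in voxels)
#' @param resolution_level `"full"` or `"half"`
#' @param sanity_limit maximum admissible |displacement| per component
#'   (voxels); exceeding it is an error (guards against runaway registration)
#' @return object of class `deformation_field` with elements `ux, uy, uz`,
#'   `grid_shape`, `resolution_level`
#' @export
deformation_field <- function(ux, uy, uz, resolution_level = "full",
                              sanity_limit = 30) {
  stopifnot(identical(dim(ux), dim(uy)), identical(dim(ux), dim(uz)),
            length(dim(ux)) == 3)
  if (!all(is.finite(ux)) || !all(is.finite(uy)) || !all(is.finite(uz)))
    stop("deformation field contains non-finite displacements")
  m <- max(abs(ux), abs(uy), abs(uz))
  if (m > sanity_limit)
    stop(sprintf("deformation field exceeds sanity limit (%.1f > %d voxels)",
                 m, sanity_limit))
  resolution_level <- match.arg(resolution_level, c("full", "half"))
  structure(list(ux = ux, uy = uy, uz = uz,
                 grid_shape = dim(ux),
                 resolution_level = resolution_level),
            class = "deformation_field")
}

#' Zero deformation field
#' @param grid_shape integer length-3 vector
#' @param resolution_level `"full"` or `"half"`
#' @export
zero_field <- function(grid_shape, resolution_level = "full") {
  z <- array(0, grid_shape)
  deformation_field(z, z, z, resolution_level)
}

#' Warp a volume by a deformation field (pull-back resampling)
#'
#' `out(r) = img(r + u(r))` with trilinear interpolation and edge clamping.
#' Anatomy displaced by `+s` voxels is rendered as `warp_image(ref, scale_field(s, -1))`.
#'
#' @param img real or complex 3D array
#' @param field `deformation_field` on the same grid
#' @return warped array (same mode as input)
#' @export
warp_image <- function(img, field) {
  stopifnot(inherits(field, "deformation_field"),
            identical(dim(img), field$grid_shape))
  d <- dim(img)
  if (is.complex(img)) {
    re <- warp3_gather(Re(img), as.integer(d), field$ux, field$uy, field$uz)
    im <- warp3_gather(Im(img), as.integer(d), field$ux, field$uy, field$uz)
    out <- complex(real = re, imaginary = im)
  } else {
    out <- warp3_gather(as.double(img), as.integer(d),
                        field$ux, field$uy, field$uz)
  }
  array(out, d)
}

#' Adjoint (transpose) of [warp_image()]
#'
#' Scatters each voxel's value to the interpolation stencil of `r + u(r)`
#' with the same trilinear weights, i.e. the exact matrix transpose of the
#' gather warp (not the inverse warp).
#'
#' @param img real or complex 3D array
#' @param field `deformation_field` on the same grid
#' @return array of the same shape
#' @export
warp_adjoint <- function(img, field) {
  stopifnot(inherits(field, "deformation_field"),
            identical(dim(img), field$grid_shape))
  d <- dim(img)
  if (is.complex(img)) {
    re <- warp3_scatter(Re(img), as.integer(d), field$ux, field$uy, field$uz)
    im <- warp3_scatter(Im(img), as.integer(d), field$ux, field$uy, field$uz)
    out <- complex(real = re, imaginary = im)
  } else {
    out <- warp3_scatter(as.double(img), as.integer(d),
                         field$ux, field$uy, field$uz)
  }
  array(out, d)
}

#' Multiply a deformation field by a scalar
#' @param field `deformation_field`
#' @param s scalar
#' @export
scale_field <- function(field, s) {
  deformation_field(field$ux * s, field$uy * s, field$uz * s,
                    field$resolution_level)
}

#' Interpolate a half-resolution field to the full grid
#'
#' Trilinear interpolation of each displacement component onto a grid whose
#' axes are `scale` times larger, with displacements multiplied by the same
#' grid-size ratio (half-grid voxels become full-grid voxels).
#'
#' @param field `deformation_field` with `resolution_level = "half"`
#' @param full_shape integer length-3 vector of the full grid
#' @return `deformation_field` with `resolution_level = "full"`
#' @export
upsample_field <- function(field, full_shape) {
  stopifnot(inherits(field, "deformation_field"))
  if (field$resolution_level != "half")
    stop("upsample_field expects a half-resolution field")
  hs <- field$grid_shape
  scale <- full_shape / hs
  up <- function(comp, s_disp) {
    # evaluate the half-grid component at half-grid coordinates of each full
    # voxel via the gather kernel applied on the half grid
    coords <- lapply(1:3, function(i) {
      # corner-aligned: full voxel 1 maps onto half voxel 1; the top
      # half-voxel of each axis is clamped (documented edge behaviour)
      (seq_len(full_shape[i]) - 1) / scale[i] + 1
    })
    cx <- array(rep(coords[[1]], times = full_shape[2] * full_shape[3]), full_shape)
    cy <- array(rep(rep(coords[[2]], each = full_shape[1]), times = full_shape[3]), full_shape)
    cz <- array(rep(coords[[3]], each = full_shape[1] * full_shape[2]), full_shape)
    vals <- interp3_at(comp, cx, cy, cz)
    vals * s_disp
  }
  deformation_field(up(field$ux, scale[1]), up(field$uy, scale[2]),
                    up(field$uz, scale[3]), "full")
}

#' Trilinear interpolation of a volume at arbitrary continuous coordinates
#'
#' Coordinates are 1-based voxel indices (clamped to the volume bounds).
#' @param vol real 3D array
#' @param cx,cy,cz arrays of coordinates (same shape as the desired output)
#' @keywords internal
interp3_at <- function(vol, cx, cy, cz) {
  d <- dim(vol)
  out_shape <- dim(cx)
  n <- length(cx)
  # reuse the gather kernel: displacements relative to a same-size identity
  # grid would need matching shapes, so do it directly in R for generality
  px <- pmin(pmax(as.double(cx), 1), d[1])
  py <- pmin(pmax(as.double(cy), 1), d[2])
  pz <- pmin(pmax(as.double(cz), 1), d[3])
  x0 <- pmin(floor(px), d[1] - if (d[1] > 1) 1 else 0)
  y0 <- pmin(floor(py), d[2] - if (d[2] > 1) 1 else 0)
  z0 <- pmin(floor(pz), d[3] - if (d[3] > 1) 1 else 0)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(ix, iy, iz) vol[cbind(as.vector(ix), as.vector(iy), as.vector(iz))]
  v <- at(x0, y0, z0) * as.vector((1 - fx) * (1 - fy) * (1 - fz)) +
       at(x1, y0, z0) * as.vector(fx * (1 - fy) * (1 - fz)) +
       at(x0, y1, z0) * as.vector((1 - fx) * fy * (1 - fz)) +
       at(x1, y1, z0) * as.vector(fx * fy * (1 - fz)) +
       at(x0, y0, z1) * as.vector((1 - fx) * (1 - fy) * fz) +
       at(x1, y0, z1) * as.vector(fx * (1 - fy) * fz) +
       at(x0, y1, z1) * as.vector((1 - fx) * fy * fz) +
       at(x1, y1, z1) * as.vector(fx * fy * fz)
  array(v, out_shape)
}
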