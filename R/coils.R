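# Analytic coil sensitivity maps.

#' Analytic smooth coil sensitivity maps
#'
#' Gaussian-magnitude lobes centred at `n_coils` equispaced positions on a
#' circle in the AP--RL plane just outside the volume (surface-coil layout),
#' each with a small linear phase ramp pointing away from its centre.  With
#' `n_coils = 1` the map is uniform `1 + 0i` (body-coil limit).  The
#' root-sum-of-squares magnitude is strictly positive everywhere.
#'
#' @param grid_shape integer length-3 (FH, AP, RL)
#' @param n_coils number of coils (>= 1)
#' @param sigma_frac Gaussian lobe width as a fraction of the grid diagonal
#' @return object of class `coil_sensitivities`: `maps` complex 4D array
#'   `[x, y, z, coil]`, `n_coils`
#' @export
coil_maps <- function(grid_shape, n_coils = 8, sigma_frac = 0.6) {
  stopifnot(n_coils >= 1, length(grid_shape) == 3)
  gs <- as.integer(grid_shape)
  maps <- array(0i, c(gs, n_coils))
  if (n_coils == 1) {
    maps[, , , 1] <- 1 + 0i
  } else {
    nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
    x <- array(rep(seq_len(nx), times = ny * nz), gs)
    y <- array(rep(rep(seq_len(ny), each = nx), times = nz), gs)
    z <- array(rep(seq_len(nz), each = nx * ny), gs)
    sigma <- sigma_frac * sqrt(sum(gs^2)) / 2
    r_ring <- 0.65 * sqrt((ny / 2)^2 + (nz / 2)^2)
    for (c in seq_len(n_coils)) {
      ang <- 2 * pi * (c - 1) / n_coils
      cyc <- ny / 2 + 0.5 + r_ring * cos(ang)
      czc <- nz / 2 + 0.5 + r_ring * sin(ang)
      cxc <- nx / 2 + 0.5
      mag <- 0.15 + exp(-((x - cxc)^2 + (y - cyc)^2 + (z - czc)^2) /
                          (2 * sigma^2))
      ph <- 0.5 * pi * ((y - cyc) / ny + (z - czc) / nz) + ang / 3
      maps[, , , c] <- mag * exp(1i * ph)
    }
  }
  structure(list(maps = maps, n_coils = n_coils, grid_shape = gs),
            class = "coil_sensitivities")
}

#' Downsample coil maps to a coarser grid by block averaging
#'
#' Used for half-resolution respiratory-bin reconstructions; valid because
#' the analytic maps are smooth on the voxel scale.
#' @param coils `coil_sensitivities`
#' @param factor integer downsampling factor per axis (default 2)
#' @export
downsample_coils <- function(coils, factor = 2) {
  gs <- coils$grid_shape
  stopifnot(all(gs %% factor == 0))
  hs <- gs %/% factor
  out <- array(0i, c(hs, coils$n_coils))
  for (c in seq_len(coils$n_coils)) {
    m <- coils$maps[, , , c]
    a <- array(m, c(factor, hs[1], factor, hs[2], factor, hs[3]))
    out[, , , c] <- apply(a, c(2, 4, 6), mean)
  }
  structure(list(maps = out, n_coils = coils$n_coils, grid_shape = hs),
            class = "coil_sensitivities")
}

#' Root-sum-of-squares magnitude of coil maps
#' @param coils `coil_sensitivities`
#' @return real 3D array
#' @export
coil_rss <- function(coils) {
  sqrt(apply(abs(coils$maps)^2, 1:3, sum))
}
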