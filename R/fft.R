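# Centered orthonormal FFT helpers.  Convention (fixed package-wide): the DC
# sample sits at 0-based index floor(n/2), i.e. R index floor(n/2) + 1, on
# every transformed axis; transforms are unitary (1/sqrt(N) both ways).

#' Circularly shift an array along every dimension
#'
#' @param x array
#' @param shifts integer vector, one entry per dimension; positive values move
#'   content toward higher indices (wrapping around).
#' @return shifted array
#' @keywords internal
circshift <- function(x, shifts) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  stopifnot(length(shifts) == length(d))
  idx <- lapply(seq_along(d), function(i) {
    s <- shifts[i] %% d[i]
    if (s == 0) seq_len(d[i]) else c((d[i] - s + 1):d[i], 1:(d[i] - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @keywords internal
fftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  circshift(x, floor(d / 2))
}

#' @keywords internal
ifftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  circshift(x, ceiling(d / 2))
}

#' Centered orthonormal N-dimensional FFT
#'
#' Forward transform image -> k-space with the DC sample at R index
#' `floor(n/2) + 1` on every axis and unitary scaling.
#'
#' @param x numeric or complex array
#' @return complex array of the same shape
#' @export
kfft <- function(x) {
  fftshift(fft(ifftshift(x))) / sqrt(length(x))
}

#' Centered orthonormal N-dimensional inverse FFT
#'
#' @param x complex array (k-space, centered convention)
#' @return complex array of the same shape
#' @export
kifft <- function(x) {
  fftshift(fft(ifftshift(x), inverse = TRUE)) / sqrt(length(x))
}

#' Centered k-space index vector
#'
#' Integer frequencies for an axis of length `n` under the centered
#' convention: `-floor(n/2) ... n - floor(n/2) - 1`, DC at 0.
#' @param n axis length
#' @keywords internal
kindex <- function(n) seq_len(n) - (floor(n / 2) + 1)

#' Gaussian low-pass smoothing via the centered FFT
#'
#' Gaussian smoothing of each volume; used for coil-map downsampling, B0
#' phasor smoothing and registration pyramids.  Boundaries are periodic by
#' default (adequate when the support is interior); `pad = "replicate"`
#' edge-extends each axis by 3 sigma before smoothing, which avoids
#' wrap-around bias for fields that do not vanish at the volume edge (e.g.
#' a B0 ramp).
#'
#' @param x real or complex array
#' @param sigma standard deviation in voxels (scalar or per-axis)
#' @param pad `"periodic"` or `"replicate"`
#' @return smoothed array (real if input real)
#' @keywords internal
gauss_smooth <- function(x, sigma, pad = c("periodic", "replicate")) {
  pad <- match.arg(pad)
  d <- dim(x)
  if (length(sigma) == 1) sigma <- rep(sigma, length(d))
  if (pad == "replicate") {
    p <- pmin(ceiling(3 * sigma), d)
    idx <- lapply(seq_along(d), function(i)
      c(rep(1, p[i]), seq_len(d[i]), rep(d[i], p[i])))
    xe <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    se <- gauss_smooth(xe, sigma, pad = "periodic")
    idx2 <- lapply(seq_along(d), function(i) p[i] + seq_len(d[i]))
    return(do.call(`[`, c(list(se), idx2, list(drop = FALSE))))
  }
  kern <- lapply(seq_along(d), function(i) {
    k <- kindex(d[i]) / d[i]
    exp(-2 * pi^2 * sigma[i]^2 * k^2)
  })
  w <- Reduce(function(a, b) outer(a, b), kern)   # separable tensor kernel
  dim(w) <- d
  out <- kifft(kfft(x) * w)
  if (is.complex(x)) out else Re(out)
}

#' Translate a volume by a sub-voxel displacement (Fourier shift)
#'
#' Exact periodic translation of the content by `d_vox` voxels per axis.
#' @param img real or complex 3D array
#' @param d_vox length-3 displacement (voxels); positive moves content
#'   toward higher indices
#' @return shifted array (same mode as input)
#' @export
fourier_shift <- function(img, d_vox) {
  d <- dim(img)
  stopifnot(length(d_vox) == length(d))
  k <- kfft(img)
  for (i in seq_along(d)) {
    if (d_vox[i] == 0) next
    ph <- exp(-2i * pi * kindex(d[i]) * d_vox[i] / d[i])
    k <- sweep(k, i, ph, `*`)
  }
  out <- kifft(k)
  if (is.complex(img)) out else Re(out)
}

#' Crop the central region of a centered k-space array
#'
#' Keeps the central `dim_out` samples on each axis (DC-preserving under the
#' centered convention).
#' @param k complex array
#' @param dim_out integer vector of output dims (each <= dim(k))
#' @keywords internal
kcrop <- function(k, dim_out) {
  d <- dim(k)
  stopifnot(all(dim_out <= d))
  idx <- lapply(seq_along(d), function(i) {
    c0 <- floor(d[i] / 2) + 1            # DC (R index)
    lo <- c0 - floor(dim_out[i] / 2)
    lo:(lo + dim_out[i] - 1)
  })
  do.call(`[`, c(list(k), idx, list(drop = FALSE)))
}
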