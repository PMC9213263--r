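# Beat-to-beat translational motion estimation from 2D image navigators.

# normalized cross-correlation between a template and a same-size patch
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# bilinear sample of matrix `m` at continuous (1-based) coordinates
bilin_patch <- function(m, u0, v0, nu, nv) {
  du <- dim(m)[1]; dv <- dim(m)[2]
  uu <- pmin(pmax(u0 + seq_len(nu) - 1, 1), du)
  vv <- pmin(pmax(v0 + seq_len(nv) - 1, 1), dv)
  iu0 <- pmin(floor(uu), du - 1); iv0 <- pmin(floor(vv), dv - 1)
  fu <- uu - iu0; fv <- vv - iv0
  m00 <- m[cbind(rep(iu0, nv), rep(iv0, each = nu))]
  m10 <- m[cbind(rep(iu0 + 1, nv), rep(iv0, each = nu))]
  m01 <- m[cbind(rep(iu0, nv), rep(iv0 + 1, each = nu))]
  m11 <- m[cbind(rep(iu0 + 1, nv), rep(iv0 + 1, each = nu))]
  wu <- rep(fu, nv); wv <- rep(fv, each = nu)
  matrix(m00 * (1 - wu) * (1 - wv) + m10 * wu * (1 - wv) +
           m01 * (1 - wu) * wv + m11 * wu * wv, nu, nv)
}

#' Track the navigator template across beats
#'
#' Estimates per-beat (FH, RL) translations of the heart relative to the
#' reference frame by maximizing the normalized cross-correlation (NCC) of
#' the reference-frame template over an integer search window, refined to
#' sub-pixel precision by continuous NCC optimization on the bilinearly
#' interpolated frame (Nelder--Mead started from the quadratic fit of the
#' integer NCC peak).  The opposed-phase echo navigator (echo 1) is used.
#'
#' Sign convention: a positive FH estimate means the heart moved toward the
#' head (positive axis-1 direction) relative to the reference; the k-space
#' correction in [phase_shift_correct()] consumes the same convention.
#'
#' @param stack `inav_stack` with at least 2 beats
#' @param search_px integer search radius (low-res pixels)
#' @param echo navigator echo used for tracking (default 1, opposed-phase)
#' @return data.frame with one row per beat: `beat`, `fh_mm`, `rl_mm`,
#'   `fh_px`, `rl_px`, `reliable` (FALSE when the correlation peak sits on
#'   the search-window border)
#' @export
track_template <- function(stack, search_px = NULL, echo = 1) {
  stopifnot(inherits(stack, "inav_stack"))
  nb <- dim(stack$frames)[1]
  if (nb < 2) stop("need at least 2 navigator frames")
  tb <- stack$template_box
  ref <- stack$frames[stack$reference_beat, echo, , ]
  tmpl <- ref[tb[1]:tb[2], tb[3]:tb[4]]
  if (sd(tmpl) == 0) stop("flat (zero-variance) navigator template")
  nu <- nrow(tmpl); nv <- ncol(tmpl)
  du <- dim(stack$frames)[3]; dv <- dim(stack$frames)[4]
  if (is.null(search_px))
    search_px <- max(3L, floor(min(du, dv) / 4))

  est <- matrix(0, nb, 2)
  reliable <- rep(TRUE, nb)
  for (k in seq_len(nb)) {
    if (k == stack$reference_beat) next
    frame <- stack$frames[k, echo, , ]
    best <- -Inf; bu <- 0L; bv <- 0L
    sc <- matrix(NA_real_, 2 * search_px + 1, 2 * search_px + 1)
    for (duu in -search_px:search_px) {
      for (dvv in -search_px:search_px) {
        u0 <- tb[1] + duu; v0 <- tb[3] + dvv
        if (u0 < 1 || v0 < 1 || u0 + nu - 1 > du || v0 + nv - 1 > dv) next
        s <- ncc(tmpl, frame[u0:(u0 + nu - 1), v0:(v0 + nv - 1)])
        sc[duu + search_px + 1, dvv + search_px + 1] <- s
        if (s > best) { best <- s; bu <- duu; bv <- dvv }
      }
    }
    if (abs(bu) == search_px || abs(bv) == search_px) reliable[k] <- FALSE
    # quadratic sub-pixel start from the 3x3 neighbourhood of the peak
    qoff <- c(0, 0)
    iu <- bu + search_px + 1; iv <- bv + search_px + 1
    if (iu > 1 && iu < nrow(sc) && iv > 1 && iv < ncol(sc) &&
        all(is.finite(sc[(iu - 1):(iu + 1), (iv - 1):(iv + 1)]))) {
      d1 <- (sc[iu + 1, iv] - sc[iu - 1, iv]) / 2
      d2 <- sc[iu + 1, iv] - 2 * sc[iu, iv] + sc[iu - 1, iv]
      if (d2 < 0) qoff[1] <- max(-0.5, min(0.5, -d1 / d2))
      e1 <- (sc[iu, iv + 1] - sc[iu, iv - 1]) / 2
      e2 <- sc[iu, iv + 1] - 2 * sc[iu, iv] + sc[iu, iv - 1]
      if (e2 < 0) qoff[2] <- max(-0.5, min(0.5, -e1 / e2))
    }
    # continuous refinement on the bilinearly interpolated frame
    obj <- function(p) {
      -ncc(tmpl, bilin_patch(frame, tb[1] + p[1], tb[3] + p[2], nu, nv))
    }
    opt <- optim(c(bu + qoff[1], bv + qoff[2]), obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10))
    est[k, ] <- opt$par
  }
  # template found at offset +d means the anatomy moved by +d
  data.frame(beat = stack$beats,
             fh_mm = est[, 1] * stack$pixel_mm,
             rl_mm = est[, 2] * stack$pixel_mm,
             fh_px = est[, 1], rl_px = est[, 2],
             reliable = reliable)
}
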