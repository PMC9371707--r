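# FFT cross-correlation engine shared by image registration, bead
# displacement tracking and PIV. Image convention: matrices indexed
# [row = y, col = x], origin lower-left after IO flipping.

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular cross-correlation of two equally sized images (b relative to a);
# returns the correlation matrix with zero lag at [1, 1].
cross_correlate <- function(a, b) {
  Re(ifft2(Conj(fft2(a)) * fft2(b)))
}

# 3-point Gaussian subpixel interpolation along one axis given the peak
# value and its two neighbours (all positive); falls back to parabolic.
subpixel_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den < 0) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm + cp - 2 * c0)
  if (den == 0) 0 else (cm - cp) / den
}

# Translation of `b` relative to `a` by phase correlation with local
# upsampled-DFT refinement. Returns c(dx, dy) in pixels (x = columns).
phase_shift <- function(a, b, upsample = 20L) {
  ny <- nrow(a); nx <- ncol(a)
  Fa <- fft2(a); Fb <- fft2(b)
  Q <- Conj(Fa) * Fb
  mag <- Mod(Q)
  Qn <- Q / ifelse(mag > 0, mag, 1)
  r <- Re(ifft2(Qn))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  iy <- pk[1] - 1L; ix <- pk[2] - 1L
  dy0 <- if (iy > ny / 2) iy - ny else iy
  dx0 <- if (ix > nx / 2) ix - nx else ix
  # refine on a fine grid around (dx0, dy0) by direct DFT evaluation
  ky <- c(0:(floor(ny / 2)), -(ceiling(ny / 2) - 1):-1)[1:ny]
  kx <- c(0:(floor(nx / 2)), -(ceiling(nx / 2) - 1):-1)[1:nx]
  gy <- dy0 + seq(-1, 1, length.out = 2L * upsample + 1L)
  gx <- dx0 + seq(-1, 1, length.out = 2L * upsample + 1L)
  Wy <- exp(2i * pi * outer(gy, ky) / ny)   # (G x ny), inverse-DFT evaluation
  Wx <- exp(2i * pi * outer(kx, gx) / nx)   # (nx x G)
  rf <- Re(Wy %*% Qn %*% Wx) / (nx * ny)
  pk2 <- which(rf == max(rf), arr.ind = TRUE)[1, ]
  c(dx = gx[pk2[2]], dy = gy[pk2[1]])
}

# Windowed cross-correlation displacement field: displacement of
# `deformed` relative to `reference` per interrogation window.
# Returns list(x, y, dx, dy, mask) in pixel units; window centres in
# pixel coordinates (x right, y up). Featureless windows are masked.
window_displacements <- function(reference, deformed, window, overlap) {
  stopifnot(all(dim(reference) == dim(deformed)), window >= 8)
  step <- max(1L, round(window * (1 - overlap)))
  ny <- nrow(reference); nx <- ncol(reference)
  ys <- seq(1L, ny - window + 1L, by = step)
  xs <- seq(1L, nx - window + 1L, by = step)
  dx <- dy <- matrix(NA_real_, length(ys), length(xs))
  mask <- matrix(FALSE, length(ys), length(xs))
  maxdisp <- window / 3
  # linear (zero-padded) correlation avoids wraparound bias; lags are
  # normalized by the overlap area before peak search
  W2 <- 2L * window
  lag <- c(0:(window - 1L), -window:-1L)     # lag value per padded index
  ovl <- window - abs(lag)
  norm2 <- outer(ovl, ovl)
  sel <- abs(lag) <= maxdisp
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    aw <- reference[ys[i]:(ys[i] + window - 1L), xs[j]:(xs[j] + window - 1L)]
    bw <- deformed[ys[i]:(ys[i] + window - 1L), xs[j]:(xs[j] + window - 1L)]
    if (stats::sd(aw) < 1e-12 || stats::sd(bw) < 1e-12) next
    pa <- matrix(0, W2, W2); pb <- matrix(0, W2, W2)
    pa[1:window, 1:window] <- aw - mean(aw)
    pb[1:window, 1:window] <- bw - mean(bw)
    r <- cross_correlate(pa, pb) / norm2
    rs <- r
    rs[!sel, ] <- -Inf; rs[, !sel] <- -Inf
    pk <- which(rs == max(rs), arr.ind = TRUE)[1, ]
    sy <- lag[pk[1]]; sx <- lag[pk[2]]
    wrap <- function(k) ((k - 1L) %% W2) + 1L
    py <- pk[1]; px <- pk[2]
    ddx <- subpixel_offset(r[py, wrap(px - 1L)], r[py, px], r[py, wrap(px + 1L)])
    ddy <- subpixel_offset(r[wrap(py - 1L), px], r[py, px], r[wrap(py + 1L), px])
    dx[i, j] <- sx + ddx
    dy[i, j] <- sy + ddy
    mask[i, j] <- TRUE
  }
  list(x = xs + (window - 1) / 2, y = ys + (window - 1) / 2,
       dx = dx, dy = dy, mask = mask, step = step)
}
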