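# Internal helpers shared across modules.

# Translate a matrix by integer (dy, dx), filling exposed pixels with `fill`.
# Positive dy moves content down (towards larger row indices).
shiftIntInternal <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Spectral (Fourier-shift-theorem) translation by real (dy, dx); periodic
# boundary. Used for the fractional part of subpixel alignment so intensities
# are not smoothed by interpolation.
shiftSpectralInternal <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  fy <- fftFreq(h); fx <- fftFreq(w)
  phase <- exp(-2i * pi * (outer(fy * dy, rep(1, w)) + outer(rep(1, h), fx * dx)))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (h * w)
}

# DFT sample frequencies in cycles/pixel, matching numpy.fft.fftfreq.
fftFreq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / n
  if (n == 1L) k <- 0
  k
}

# Translate by real-valued (dy, dx): integer part by zero-filled shift,
# fractional remainder (if any) spectrally. Returns list(image, valid) where
# valid marks pixels whose value originated inside the frame.
translateImage <- function(img, dy, dx, fill = 0) {
  iy <- round(dy); ix <- round(dx)
  ry <- dy - iy; rx <- dx - ix
  out <- img
  if (abs(ry) > 1e-9 || abs(rx) > 1e-9)
    out <- shiftSpectralInternal(out, ry, rx)
  out <- shiftIntInternal(out, iy, ix, fill = fill)
  valid <- shiftIntInternal(matrix(TRUE, nrow(img), ncol(img)), iy, ix,
                            fill = FALSE)
  # fractional wrap contaminates a 1-px border on the moved-from side
  if (abs(ry) > 1e-9 || abs(rx) > 1e-9) {
    my <- iy + sign(ry); mx <- ix + sign(rx)
    valid <- valid & shiftIntInternal(matrix(TRUE, nrow(img), ncol(img)),
                                      my, mx, fill = FALSE)
  }
  list(image = out, valid = valid)
}

# Median absolute deviation scaled to the normal (sigma-consistent), guarded
# against zero for quantised backgrounds.
robustScale <- function(x) {
  s <- stats::mad(x, constant = 1.4826)
  if (s <= 0) s <- stats::sd(x)
  if (!is.finite(s)) s <- 0
  s
}

# Crofton-style perimeter estimate (in pixels) of a binary mask: mean of the
# boundary-crossing counts in the 0/90-degree and 45/135-degree direction
# pairs, the diagonal pair weighted by 1/sqrt(2). Stated once here; estimators
# differ by several percent and cross-magnification matching relies on this
# one being used everywhere.
croftonPerimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  n0 <- sum(abs(m[, -1] - m[, -ncol(m)]))        # vertical edges (crossings along rows)
  n90 <- sum(abs(m[-1, ] - m[-nrow(m), ]))       # horizontal edges
  h <- nrow(m); w <- ncol(m)
  d1 <- sum(abs(m[-1, -1] - m[-h, -w]))          # "\" diagonal crossings
  d2 <- sum(abs(m[-1, -w] - m[-h, -1]))          # "/" diagonal crossings
  (pi / 4) * ((n0 + n90) / 2 + (d1 + d2) / (2 * sqrt(2)))
}

# Greedy local-maxima selection: candidates at or above `threshold` that are
# maxima of their 3x3 neighbourhood, then enforced pairwise euclidean
# separation >= min_distance, preferring higher values and, on plateaus, the
# smallest (row, col). The footprint is fixed at 3x3 (independent of
# min_distance) so that peaks separated by just over min_distance are still
# individually detectable.
selectPeaks <- function(img, min_distance, threshold, mask = NULL) {
  mx <- maxFilter(img, 1L)
  cand <- which(img >= threshold & img >= mx - 1e-12, arr.ind = TRUE)
  if (!is.null(mask) && nrow(cand))
    cand <- cand[mask[cand], , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  v <- img[cand]
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; v <- v[ord]
  keep_r <- numeric(0); keep_c <- numeric(0); keep_v <- numeric(0)
  md2 <- min_distance^2
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, 1]; ci <- cand[i, 2]
    if (!length(keep_r) ||
        all((keep_r - ri)^2 + (keep_c - ci)^2 >= md2)) {
      keep_r <- c(keep_r, ri); keep_c <- c(keep_c, ci); keep_v <- c(keep_v, v[i])
    }
  }
  data.frame(row = as.integer(keep_r), col = as.integer(keep_c),
             value = keep_v)
}

# Separable running-maximum filter over a (2r+1)^2 square window.
maxFilter <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (k in seq_len(r)) {   # row direction
    up <- rbind(out[-1, , drop = FALSE], out[h, , drop = FALSE])
    dn <- rbind(out[1, , drop = FALSE], out[-h, , drop = FALSE])
    out <- pmax(out, up, dn)
  }
  res <- out
  for (k in seq_len(r)) {   # col direction
    lf <- cbind(res[, -1, drop = FALSE], res[, w, drop = FALSE])
    rt <- cbind(res[, 1, drop = FALSE], res[, -w, drop = FALSE])
    res <- pmax(res, lf, rt)
  }
  res
}

# Max / mean over the square aperture of side 2a+1 centred at (row, col),
# clipped at the image border. Returns list(value, clipped).
apertureStat <- function(img, row, col, a, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, row - a); r1 <- min(h, row + a)
  c0 <- max(1L, col - a); c1 <- min(w, col + a)
  block <- img[r0:r1, c0:c1]
  list(value = if (stat == "max") max(block) else mean(block),
       clipped = (r1 - r0 + 1L != 2L * a + 1L) || (c1 - c0 + 1L != 2L * a + 1L))
}

# Rasterise a filled, rotated ellipse into a logical mask on an h x w grid.
# Centre in pixel units (row, col), semi-axes in pixels, theta in radians.
ellipseMask <- function(h, w, row, col, a, b, theta = 0) {
  rr <- matrix(seq_len(h), h, w) - row
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - col
  u <- cc * cos(theta) + rr * sin(theta)
  v <- -cc * sin(theta) + rr * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

stopWithPath <- function(path, msg) {
  stop(sprintf("%s [%s]", msg, path), call. = FALSE)
}

# Grayscale morphological white top-hat with a (2r+1)^2 square structuring
# element: image minus its opening (min filter then max filter). Removes
# structures wider than the window, leaving compact peaks on a flat residual.
grayTopHat <- function(img, r) {
  er <- -maxFilter(-img, r)
  img - maxFilter(er, r)
}
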