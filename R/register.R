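#' Estimate the translation between two images by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and locates
#' its inverse-transform peak. The returned shift `(dy, dx)` is the
#' translation that superimposes `moving` onto `reference`: shifting the
#' moving image down by `dy` rows and right by `dx` columns reproduces the
#' reference. Integer shifts of cyclically shifted images are recovered
#' exactly at `upsample = 1`; with `upsample > 1` the correlation peak is
#' refined on a local grid of spacing `1/upsample` pixels using an upsampled
#' discrete Fourier transform, giving subpixel estimates.
#'
#' @param reference,moving Numeric matrices of identical dimensions.
#' @param upsample Integer subpixel refinement factor (1 = integer shifts).
#' @param smooth_sigma Gaussian low-pass sigma (px) applied to both images
#'   before whitening; suppresses the noise-dominated high frequencies that
#'   otherwise swamp the phase spectrum of smooth biological content. 0
#'   disables. Smoothing commutes with translation, so shifts are unbiased.
#' @return A list with elements `dy`, `dx` (pixels) and `peak` (normalized
#'   correlation peak height, in (0, 1] for noise-free translations).
#' @seealso [alignStack()]
#' @export
estimateShift <- function(reference, moving, upsample = 1L,
                          smooth_sigma = 1.5) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            all(dim(reference) == dim(moving)))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("no structure to register: constant image")
  if (smooth_sigma > 0) {
    reference <- EBImage::gblur(reference, sigma = smooth_sigma)
    moving <- EBImage::gblur(moving, sigma = smooth_sigma)
  }
  h <- nrow(reference); w <- ncol(reference)
  F1 <- stats::fft(reference)
  F2 <- stats::fft(moving)
  R <- F1 * Conj(F2)
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (h * w)
  pk <- which.max(cc)
  pr <- (pk - 1L) %% h
  pc <- (pk - 1L) %/% h
  dy <- if (pr > h / 2) pr - h else pr
  dx <- if (pc > w / 2) pc - w else pc
  peak <- cc[pk]
  if (upsample > 1L) {
    step <- 1 / upsample
    yseq <- dy + seq(-1.5, 1.5, by = step)
    xseq <- dx + seq(-1.5, 1.5, by = step)
    Ky <- exp(2i * pi * outer(yseq, fftFreq(h) * 1))
    Kx <- exp(2i * pi * outer(fftFreq(w) * 1, xseq))
    up <- Re(Ky %*% R %*% Kx) / (h * w)
    ij <- which(up == max(up), arr.ind = TRUE)[1, ]
    dy <- yseq[ij[1]]; dx <- xseq[ij[2]]
    peak <- max(up)
  }
  list(dy = dy, dx = dx, peak = peak)
}

#' Register all cycles of an SBS stack to a reference cycle
#'
#' Estimates, for every cycle, the DAPI-channel shift relative to the
#' reference cycle by [estimateShift()], then translates every channel of
#' that cycle by the estimated shift. Integer parts are applied as
#' zero-filled shifts; fractional parts spectrally via the Fourier shift
#' theorem (no interpolation smoothing). Pixels that fell outside the frame
#' in any cycle are recorded in the stack's validity mask and excluded from
#' downstream spot detection. Cycles whose estimated shift magnitude exceeds
#' `max_shift` are flagged failed and left untranslated; spots on such FOVs
#' cannot receive a full-length call.
#'
#' @param stack An [SBSImageStack-class].
#' @param reference_cycle 1-based cycle to align onto (default 1).
#' @param upsample Subpixel factor passed to [estimateShift()].
#' @param max_shift Maximum credible shift in pixels (default 50).
#' @param smooth_sigma Pre-filter passed to [estimateShift()].
#' @return A list with `stack` (aligned [SBSImageStack-class]) and `shifts`
#'   (data.frame: cycle, dy_px, dx_px, peak_correlation, failed). The
#'   reference cycle's shift is exactly (0, 0).
#' @export
alignStack <- function(stack, reference_cycle = 1L, upsample = 1L,
                       max_shift = 50, smooth_sigma = 1.5) {
  stopifnot(is(stack, "SBSImageStack"))
  nc <- nCycles(stack)
  px <- stack@pixels
  h <- dim(px)[3]; w <- dim(px)[4]
  ref <- px[reference_cycle, 1L, , ]
  shifts <- data.frame(cycle = seq_len(nc), dy_px = 0, dx_px = 0,
                       peak_correlation = 1, failed = FALSE)
  valid <- matrix(TRUE, h, w)
  out <- px
  for (ci in seq_len(nc)) {
    if (ci == reference_cycle) next
    est <- estimateShift(ref, px[ci, 1L, , ], upsample = upsample,
                         smooth_sigma = smooth_sigma)
    shifts$dy_px[ci] <- est$dy
    shifts$dx_px[ci] <- est$dx
    shifts$peak_correlation[ci] <- est$peak
    if (max(abs(est$dy), abs(est$dx)) > max_shift) {
      shifts$failed[ci] <- TRUE
      next
    }
    if (est$dy == 0 && est$dx == 0) next
    for (ki in seq_len(dim(px)[2])) {
      tr <- translateImage(px[ci, ki, , ], est$dy, est$dx)
      out[ci, ki, , ] <- pmax(tr$image, 0)
      if (ki == 1L) valid <- valid & tr$valid
    }
  }
  aligned <- SBSImageStack(out, fov = stack@fov, aligned = TRUE,
                           valid_mask = valid)
  list(stack = aligned, shifts = shifts)
}
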