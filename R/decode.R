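#' Cross-cycle standard-deviation image
#'
#' For each of the four SBS channels, computes the per-pixel population
#' standard deviation (denominator = number of cycles) of the intensity
#' across all cycles, then averages the four per-channel SD maps. Pixels
#' with large cycle-to-cycle fluorescence changes — the signature of an ISS
#' spot switching dye channels between cycles — score high; static
#' structures (nuclei, background) score near zero.
#'
#' @param stack An aligned [SBSImageStack-class] with at least 2 cycles.
#' @return Numeric matrix (height x width).
#' @seealso [detectSpots()]
#' @export
computeSDImage <- function(stack) {
  stopifnot(is(stack, "SBSImageStack"))
  nc <- nCycles(stack)
  if (nc < 2L) stop("compute_sd_image requires at least 2 cycles")
  d <- dim(stack@pixels)
  acc <- matrix(0, d[3], d[4])
  for (ch in 2:5) {
    x <- stack@pixels[, ch, , ]              # cycles x rows x cols
    mu <- colMeans(x)                        # rows x cols
    m2 <- colMeans(x^2)
    acc <- acc + sqrt(pmax(m2 - mu^2, 0))
  }
  acc / 4
}

#' Detect candidate ISS spots in the SD image
#'
#' Local maxima of the SD image with pairwise euclidean separation of at
#' least `min_distance_px` and value at or above the detection threshold.
#' The threshold is either absolute (`threshold_abs`) or robust:
#' `median(sd_image) + k_mad * MAD(sd_image)`. Plateau ties resolve to the
#' smallest (row, col). Pixels outside the stack's validity mask (lost to
#' registration) are excluded.
#'
#' @param sd_image Matrix from [computeSDImage()].
#' @param min_distance_px Minimum peak separation (px).
#' @param threshold_abs Absolute threshold; overrides the robust rule.
#' @param k_mad Robust threshold multiplier (default 5).
#' @param mask Optional logical matrix of valid pixels.
#' @param fov_id FOV identifier stamped into the table.
#' @return SpotTable data.frame: spot_id, fov_id, row, col, sd_score,
#'   consistent (NA until [consistencyFilter()]), cell_label (0).
#' @export
detectSpots <- function(sd_image, min_distance_px = 2, threshold_abs = NULL,
                        k_mad = 5, mask = NULL, fov_id = "fov") {
  stopifnot(is.matrix(sd_image), all(is.finite(sd_image)))
  med <- stats::median(sd_image)
  if (diff(range(sd_image)) == 0) {
    pk <- data.frame(row = integer(), col = integer(), value = numeric())
  } else {
    thr <- if (!is.null(threshold_abs)) threshold_abs else
      med + k_mad * robustScale(sd_image)
    pk <- selectPeaks(sd_image, min_distance_px, thr, mask = mask)
    if (is.null(threshold_abs)) pk <- pk[pk$value > med, , drop = FALSE]
  }
  data.frame(
    spot_id = if (nrow(pk)) paste0(fov_id, "_s", seq_len(nrow(pk))) else character(),
    fov_id = rep(fov_id, nrow(pk)),
    row = pk$row, col = pk$col, sd_score = pk$value,
    consistent = rep(NA, nrow(pk)), cell_label = rep(0L, nrow(pk))
  )
}

#' Keep only spots detected consistently in every cycle
#'
#' A spot is consistent when, in every non-failed cycle, the maximum over
#' the four SBS channels of its windowed peak intensity reaches the cycle's
#' background plus `k_sigma` robust noise scales (background and scale are
#' the per-frame median and normal-consistent MAD). Only consistent spots
#' proceed to base calling; if any cycle failed registration the spot can
#' never yield a full-length read and is marked ineligible.
#'
#' @param stack Aligned [SBSImageStack-class].
#' @param spots SpotTable from [detectSpots()].
#' @param k_sigma Noise multiplier (default 3).
#' @param window_px Half-width of the peak search window (default 1).
#' @param shifts Optional ShiftTable from [alignStack()]; rows with
#'   `failed = TRUE` are excluded from the consistency denominator.
#' @return The SpotTable with `consistent` filled in and an `eligible`
#'   column (consistent and no failed cycles).
#' @export
consistencyFilter <- function(stack, spots, k_sigma = 3, window_px = 1L,
                              shifts = NULL) {
  stopifnot(is(stack, "SBSImageStack"))
  nc <- nCycles(stack)
  failed <- rep(FALSE, nc)
  if (!is.null(shifts)) failed[shifts$cycle[shifts$failed]] <- TRUE
  cycles <- which(!failed)
  if (!nrow(spots)) {
    spots$consistent <- logical(0); spots$eligible <- logical(0)
    return(spots)
  }
  ok <- matrix(FALSE, nrow(spots), length(cycles))
  for (j in seq_along(cycles)) {
    cyc <- cycles[j]
    # per-channel frame statistics for this cycle
    thr <- numeric(4)
    frames <- vector("list", 4)
    for (b in 1:4) {
      f <- stack@pixels[cyc, b + 1L, , ]
      frames[[b]] <- f
      thr[b] <- stats::median(f) + k_sigma * robustScale(f)
    }
    for (i in seq_len(nrow(spots))) {
      best <- -Inf
      for (b in 1:4) {
        v <- apertureStat(frames[[b]], spots$row[i], spots$col[i],
                          window_px, "max")$value - thr[b]
        if (v > best) best <- v
      }
      ok[i, j] <- best > 0
    }
  }
  spots$consistent <- rowSums(ok) == length(cycles)
  spots$eligible <- spots$consistent & !any(failed)
  spots
}

#' Extract per-spot, per-cycle channel intensities
#'
#' For every spot, cycle and SBS channel, takes the mean (default) or
#' maximum over a square aperture of side `2 * aperture_px + 1` centred on
#' the spot. The mean is the default because it adds no channel-common bias
#' to the extracted vectors, which the multiplicative crosstalk correction
#' would otherwise turn into channel-specific distortion. By default the per-frame median (the cycle's background level in
#' that channel) is subtracted, so the extracted vectors live on the
#' crosstalk-mixed signal scale. Apertures clipped at the image border are
#' flagged.
#'
#' @param stack Aligned [SBSImageStack-class].
#' @param spots SpotTable (typically the consistent subset).
#' @param aperture_px Aperture half-width (0 = centre pixel only).
#' @param stat `"mean"` or `"max"`.
#' @param subtract_background Subtract the per-frame median.
#' @return List: `values` (array spot x cycle x 4, base order G,T,A,C,
#'   non-negative), `clipped` (logical per spot), `source = "raw"`.
#' @export
extractIntensities <- function(stack, spots, aperture_px = 1L,
                               stat = c("mean", "max"),
                               subtract_background = TRUE) {
  stat <- match.arg(stat)
  stopifnot(is(stack, "SBSImageStack"))
  nc <- nCycles(stack)
  ns <- nrow(spots)
  vals <- array(0, dim = c(ns, nc, 4),
                dimnames = list(spots$spot_id, NULL, SBS_BASES))
  clipped <- rep(FALSE, ns)
  for (cyc in seq_len(nc)) {
    for (b in 1:4) {
      f <- stack@pixels[cyc, b + 1L, , ]
      bg <- if (subtract_background) stats::median(f) else 0
      for (i in seq_len(ns)) {
        ap <- apertureStat(f, spots$row[i], spots$col[i], aperture_px, stat)
        vals[i, cyc, b] <- max(ap$value - bg, 0)
        if (ap$clipped) clipped[i] <- TRUE
      }
    }
  }
  list(values = vals, clipped = clipped, source = "raw")
}

#' Estimate the median crosstalk-correction matrix for one cycle
#'
#' Two-pass scheme: spots are provisionally classed by the argmax of their
#' raw intensity vector in this cycle; column j of the matrix is the
#' channel-wise median of the raw vectors in class j, scaled to unit
#' maximum. When any base class holds fewer than `min_spots_per_base` spots,
#' or the matrix condition number exceeds `max_condition`, the conservative
#' fallback is used: a diagonal matrix of per-channel global medians
#' (degraded mode, flagged).
#'
#' @param raw Intensity list from [extractIntensities()].
#' @param cycle 1-based cycle index.
#' @param min_spots_per_base Minimum class occupancy (default 5).
#' @param max_condition Condition-number bound (default 1e6).
#' @return list(cycle, M (4x4), fallback_used).
#' @seealso [correctIntensities()]
#' @export
estimateCorrectionMatrix <- function(raw, cycle, min_spots_per_base = 5L,
                                     max_condition = 1e6) {
  v <- raw$values[, cycle, , drop = FALSE]
  dim(v) <- c(dim(raw$values)[1], 4)
  if (!nrow(v)) stop("cannot estimate a correction matrix from zero spots")
  cls <- max.col(v, ties.method = "first")
  M <- matrix(0, 4, 4, dimnames = list(SBS_BASES, SBS_BASES))
  counts <- tabulate(cls, nbins = 4)
  fallback <- any(counts < min_spots_per_base)
  if (!fallback) {
    for (j in 1:4) {
      med <- apply(v[cls == j, , drop = FALSE], 2, stats::median)
      if (max(med) <= 0) { fallback <- TRUE; break }
      M[, j] <- med / max(med)
    }
  }
  if (!fallback && kappa(M, exact = TRUE) > max_condition) fallback <- TRUE
  if (fallback) {
    g <- apply(v, 2, stats::median)
    g[g <= 0] <- 1
    M <- diag(g / max(g))
    dimnames(M) <- list(SBS_BASES, SBS_BASES)
  }
  list(cycle = cycle, M = M, fallback_used = fallback)
}

#' Apply per-cycle median correction to raw intensities
#'
#' Corrected vector = M^-1 times the raw vector, per cycle. Components may
#' be negative; base calling uses the pre-clamp argmax while quality scores
#' are computed on the clamped (non-negative) values.
#'
#' @param raw Intensity list from [extractIntensities()].
#' @param matrices List of per-cycle results from
#'   [estimateCorrectionMatrix()]; `NULL` estimates them for every cycle.
#' @param ... Passed to [estimateCorrectionMatrix()] when estimating.
#' @return Intensity list with `source = "corrected"` and the `matrices`
#'   attached.
#' @export
correctIntensities <- function(raw, matrices = NULL, ...) {
  nc <- dim(raw$values)[2]
  if (is.null(matrices))
    matrices <- lapply(seq_len(nc), function(cyc)
      estimateCorrectionMatrix(raw, cyc, ...))
  out <- raw$values
  for (cyc in seq_len(nc)) {
    M <- matrices[[cyc]]$M
    Minv <- tryCatch(solve(M), error = function(e)
      stop("singular correction matrix in cycle ", cyc))
    v <- raw$values[, cyc, , drop = FALSE]
    dim(v) <- c(dim(raw$values)[1], 4)
    out[, cyc, ] <- v %*% t(Minv)
  }
  list(values = out, clipped = raw$clipped, source = "corrected",
       matrices = matrices)
}

#' Call bases and quality scores from an intensity tensor
#'
#' Per spot and cycle the called base is the channel with the highest
#' intensity (ties broken in the order G, T, A, C and flagged). The cycle
#' quality is `1 - second/first` on the clamped intensities (0 when the top
#' intensity is 0); the spot quality is the minimum cycle quality, i.e. the
#' weakest link of the read.
#'
#' @param intens Intensity list (raw or corrected).
#' @param spot_ids Optional spot identifiers (default from the tensor).
#' @return ReadTable data.frame: spot_id, barcode, per-cycle quality columns
#'   `q1..qN`, spot_quality, tie flag.
#' @export
callBases <- function(intens, spot_ids = NULL) {
  v <- intens$values
  ns <- dim(v)[1]; nc <- dim(v)[2]
  if (is.null(spot_ids)) spot_ids <- dimnames(v)[[1]]
  if (is.null(spot_ids)) spot_ids <- paste0("s", seq_len(ns), recycle0 = TRUE)
  barcode <- character(ns)
  qual <- matrix(0, ns, nc)
  tie <- rep(FALSE, ns)
  for (i in seq_len(ns)) {
    bases <- character(nc)
    for (cyc in seq_len(nc)) {
      x <- v[i, cyc, ]
      b <- which.max(x)              # first max = G,T,A,C tie order
      if (sum(x == x[b]) > 1L) tie[i] <- TRUE
      bases[cyc] <- SBS_BASES[b]
      xc <- sort(pmax(x, 0), decreasing = TRUE)
      qual[i, cyc] <- if (xc[1] <= 0) 0 else 1 - xc[2] / xc[1]
    }
    barcode[i] <- paste(bases, collapse = "")
  }
  out <- data.frame(spot_id = spot_ids, barcode = barcode,
                    stringsAsFactors = FALSE)
  for (cyc in seq_len(nc)) out[[paste0("q", cyc)]] <- qual[, cyc]
  out$spot_quality <- if (ns) apply(qual, 1, min) else numeric(0)
  out$tie <- tie
  out
}

#' Assign spots to cell bodies
#'
#' Sets each spot's `cell_label` to the cell label at its exact pixel
#' (no majority vote); 0 means unassigned background.
#'
#' @param spots SpotTable.
#' @param cells Integer cell label matrix from [segmentCells()].
#' @return SpotTable with `cell_label` filled.
#' @export
assignReadsToCells <- function(spots, cells) {
  stopifnot(is.matrix(cells))
  if (!nrow(spots)) { spots$cell_label <- integer(0); return(spots) }
  spots$cell_label <- cells[cbind(spots$row, spots$col)]
  spots
}

#' Decode one FOV end to end
#'
#' Convenience wrapper running alignment, SD-image spot detection, the
#' 12-cycle consistency filter, intensity extraction, median correction and
#' base calling on one stack. Used by the pipeline runner and by tests.
#'
#' @param stack A raw [SBSImageStack-class].
#' @param cells Optional cell label matrix for read assignment.
#' @param params Named list overriding defaults: reference_cycle, upsample,
#'   max_shift, min_distance_px, k_mad, threshold_abs, k_sigma, window_px,
#'   aperture_px, stat, subtract_background, correct (logical),
#'   min_spots_per_base.
#' @return list(spots, reads, shifts, sd_image, matrices); `reads` covers
#'   eligible (consistent, fully registered) spots only.
#' @export
decodeFov <- function(stack, cells = NULL, params = list()) {
  p <- utils::modifyList(list(
    reference_cycle = 1L, upsample = 1L, max_shift = 50,
    min_distance_px = 2, k_mad = 5, threshold_abs = NULL,
    k_sigma = 3, window_px = 1L, aperture_px = 1L, stat = "mean",
    subtract_background = TRUE, correct = TRUE, min_spots_per_base = 5L
  ), params)
  al <- alignStack(stack, p$reference_cycle, p$upsample, p$max_shift)
  sd_img <- computeSDImage(al$stack)
  spots <- detectSpots(sd_img, p$min_distance_px, p$threshold_abs, p$k_mad,
                       mask = al$stack@valid_mask,
                       fov_id = al$stack@fov@fov_id)
  spots <- consistencyFilter(al$stack, spots, p$k_sigma, p$window_px,
                             shifts = al$shifts)
  if (!is.null(cells)) spots <- assignReadsToCells(spots, cells)
  keep <- spots[spots$eligible, , drop = FALSE]
  reads <- NULL
  matrices <- NULL
  if (nrow(keep)) {
    raw <- extractIntensities(al$stack, keep, p$aperture_px, p$stat,
                              p$subtract_background)
    intens <- if (p$correct) {
      corr <- correctIntensities(raw,
        matrices = lapply(seq_len(nCycles(stack)), function(cyc)
          estimateCorrectionMatrix(raw, cyc, p$min_spots_per_base)))
      matrices <- corr$matrices
      corr
    } else raw
    reads <- callBases(intens, spot_ids = keep$spot_id)
    reads$cell_label <- keep$cell_label
    reads$row <- keep$row
    reads$col <- keep$col
  } else {
    reads <- data.frame(spot_id = character(), barcode = character(),
                        spot_quality = numeric(), tie = logical(),
                        cell_label = integer(), row = integer(),
                        col = integer())
  }
  list(spots = spots, reads = reads, shifts = al$shifts, sd_image = sd_img,
       matrices = matrices)
}
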