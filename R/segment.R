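#' Segment nuclei from a DAPI image
#'
#' Classical segmenter: Gaussian smoothing, a global threshold (Otsu by
#' default), connected-component labelling, and a distance-transform
#' watershed to split touching nuclei. Regions smaller than `min_area_px`
#' are removed and the labels renumbered consecutively. The contract is
#' pluggable: any function of the DAPI image returning an integer label
#' matrix (e.g. a pretrained deep-learning segmenter) can stand in via
#' `method`.
#'
#' @param dapi 2-D non-negative numeric matrix.
#' @param min_area_px Minimum region area in pixels.
#' @param smooth_sigma Gaussian smoothing sigma (px).
#' @param threshold Absolute intensity threshold; `NULL` selects Otsu's
#'   threshold on the smoothed image.
#' @param split Split touching nuclei by distance-transform watershed.
#' @param method Optional replacement segmenter `function(dapi) -> label
#'   matrix`; when given, all other parameters are ignored.
#' @return Integer label matrix (0 = background); all-zero input gives an
#'   empty labelling, not an error.
#' @seealso [segmentCells()], [measureMorphology()]
#' @export
segmentNuclei <- function(dapi, min_area_px = 50L, smooth_sigma = 2,
                          threshold = NULL, split = TRUE, method = NULL) {
  stopifnot(is.matrix(dapi), all(dapi >= 0))
  if (!is.null(method)) return(method(dapi))
  if (max(dapi) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  sm <- EBImage::gblur(dapi, sigma = smooth_sigma)
  if (is.null(threshold)) {
    rng <- range(sm)
    if (diff(rng) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
    norm <- (sm - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  mask <- sm > threshold
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  labels <- if (split) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    wl <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    matrix(as.integer(EBImage::imageData(wl)), nrow(dapi), ncol(dapi))
  } else {
    matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask * 1))),
           nrow(dapi), ncol(dapi))
  }
  dropSmallRegions(labels, min_area_px)
}

dropSmallRegions <- function(labels, min_area_px) {
  if (!any(labels > 0)) return(labels)
  tab <- tabulate(labels)
  keep <- which(tab >= min_area_px)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  out
}

#' Segment cell bodies by seeded watershed on the SBS channels
#'
#' Builds a topographic surface as the per-pixel median over the four
#' non-DAPI SBS channels (cycle 1 by default, or the median over all
#' cycles), masks the background by a threshold on the surface, and grows
#' cell regions from the nucleus labels by a seeded watershed. Every cell
#' region is a superset of its nucleus (nucleus pixels are always inside
#' the mask), and labels are conserved: cell k contains nucleus k.
#'
#' @param nuclei Integer label matrix from [segmentNuclei()].
#' @param stack An [SBSImageStack-class] sharing the nuclei's shape.
#' @param use_cycles `"first"` (default) or `"all"`: which cycles enter the
#'   median surface.
#' @param threshold Absolute background threshold on the surface; `NULL`
#'   selects Otsu. `NA` disables masking (cells = nuclei plus watershed over
#'   the whole frame is rarely wanted; with a flat surface this degenerates
#'   to nuclei only).
#' @return Integer label matrix of cells, same label set as `nuclei`.
#' @export
segmentCells <- function(nuclei, stack, use_cycles = c("first", "all"),
                         threshold = NULL) {
  use_cycles <- match.arg(use_cycles)
  stopifnot(is(stack, "SBSImageStack"))
  d <- dim(stack@pixels)
  stopifnot(all(dim(nuclei) == d[3:4]))
  if (!any(nuclei > 0)) return(matrix(0L, d[3], d[4]))
  surface <- if (use_cycles == "first") {
    apply(stack@pixels[1, 2:5, , , drop = FALSE], c(3, 4), stats::median)
  } else {
    apply(stack@pixels[, 2:5, , , drop = FALSE], c(3, 4), stats::median)
  }
  if (is.null(threshold)) {
    rng <- range(surface)
    mask <- if (diff(rng) == 0) nuclei > 0 else {
      norm <- (surface - rng[1]) / diff(rng)
      surface > rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
    }
  } else if (is.na(threshold)) {
    mask <- matrix(TRUE, d[3], d[4])
    if (diff(range(surface)) == 0) mask <- nuclei > 0
  } else {
    mask <- surface > threshold
  }
  mask <- mask | nuclei > 0
  cells <- EBImage::propagate(EBImage::Image(surface), nuclei,
                              mask = mask)
  matrix(as.integer(EBImage::imageData(cells)), d[3], d[4])
}

#' Measure per-region morphology in physical units
#'
#' For every label: area (pixel count times squared pixel size), perimeter
#' (Crofton four-direction boundary estimator times pixel size), eccentricity
#' from the second central moments of the pixel coordinates, solidity as
#' pixel count over the number of lattice points inside the convex hull of
#' the pixel centres (exactly 1 for digitally convex regions at any
#' resolution), the
#' centroid in pixels, and the mean intensity of any supplied images.
#' Measured in micrometres, these properties are approximately invariant to
#' magnification, which is what cross-magnification cell matching relies on.
#'
#' @param labels Integer label matrix.
#' @param fov [FOVMetadata-class] supplying the pixel size.
#' @param intensity_images Optional named list of matrices; a
#'   `mean_<name>` column is added per entry.
#' @return data.frame with one row per label: label, area_um2, perimeter_um,
#'   eccentricity, solidity, centroid_row_px, centroid_col_px, degenerate.
#'   Regions under 3 px are flagged degenerate with eccentricity 0.
#' @export
measureMorphology <- function(labels, fov, intensity_images = list()) {
  stopifnot(is.matrix(labels))
  ps <- fov@pixel_size_um
  labs <- sort(unique(labels[labels > 0]))
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    k <- labs[i]
    idx <- which(labels == k, arr.ind = TRUE)
    n <- nrow(idx)
    degenerate <- n < 3L
    # bounding-box crop for the perimeter estimator
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- labels[r0:r1, c0:c1, drop = FALSE] == k
    per <- croftonPerimeter(sub) * ps
    cen <- colMeans(idx)
    ecc <- 0
    if (!degenerate) {
      dr <- idx[, 1] - cen[1]; dc <- idx[, 2] - cen[2]
      C <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2)
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      if (ev[1] > 0) ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
      ecc <- min(ecc, 1 - 1e-12)
    }
    hullN <- latticeHullCount(idx)
    sol <- if (hullN > 0) min(1, n / hullN) else 1
    rec <- data.frame(label = k, area_um2 = n * ps^2, perimeter_um = per,
                      eccentricity = ecc, solidity = sol,
                      centroid_row_px = cen[1], centroid_col_px = cen[2],
                      degenerate = degenerate)
    for (nm in names(intensity_images))
      rec[[paste0("mean_", nm)]] <- mean(intensity_images[[nm]][labels == k])
    out[[i]] <- rec
  }
  if (!length(out)) {
    base <- data.frame(label = integer(), area_um2 = numeric(),
                       perimeter_um = numeric(), eccentricity = numeric(),
                       solidity = numeric(), centroid_row_px = numeric(),
                       centroid_col_px = numeric(), degenerate = logical())
    for (nm in names(intensity_images))
      base[[paste0("mean_", nm)]] <- numeric()
    return(base)
  }
  do.call(rbind, out)
}

# Number of lattice points (pixel centres) inside or on the convex hull of
# the region's pixel centres, by convex scanline. Digitally convex regions
# (rasterized ellipses, disks) contain exactly their hull's lattice points,
# so solidity = n / count is 1 at any resolution — the scale invariance the
# cross-magnification match relies on.
latticeHullCount <- function(idx) {
  n <- nrow(idx)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  if (length(h) < 3) return(n)
  y <- idx[h, 1]; x <- idx[h, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  total <- 0L
  for (r in ceiling(min(y)):floor(max(y))) {
    xs <- c()
    flat <- y == y2
    xs <- c(xs, x[flat & y == r], x2[flat & y == r])
    cross <- !flat & pmin(y, y2) <= r & pmax(y, y2) >= r
    xs <- c(xs, x[cross] + (r - y[cross]) * (x2[cross] - x[cross]) /
              (y2[cross] - y[cross]))
    if (!length(xs)) next
    total <- total + max(0L, floor(max(xs) + 1e-9) -
                           ceiling(min(xs) - 1e-9) + 1L)
  }
  max(total, n)
}
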