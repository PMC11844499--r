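#' Mean immunofluorescence intensity per cell
#'
#' The mean pixel intensity of an IF image over each labelled region —
#' the readout used for lamin A-style knock-down phenotypes, where a
#' targeted population shows a bulk reduction in mean staining.
#'
#' @param cells Integer label matrix (cell bodies or nuclei).
#' @param image Numeric matrix sharing the labels' shape.
#' @param fov_id FOV identifier stamped into the records.
#' @return data.frame: cell_label, fov_id, mode = "mean_if", mean_intensity.
#' @export
meanIFIntensity <- function(cells, image, fov_id = "fov") {
  stopifnot(all(dim(cells) == dim(image)))
  labs <- sort(unique(cells[cells > 0]))
  if (!length(labs))
    return(data.frame(cell_label = integer(), fov_id = character(),
                      mode = character(), mean_intensity = numeric()))
  means <- vapply(labs, function(k) mean(image[cells == k]), numeric(1))
  data.frame(cell_label = labs, fov_id = fov_id, mode = "mean_if",
             mean_intensity = means)
}

#' Detect nuclear nFISH spots by top-hat filtering
#'
#' Applies a grayscale white top-hat (image minus its morphological opening
#' with a square structuring window of half-width `tophat_radius_px`),
#' which removes structures larger than the window and performs the
#' background subtraction implicitly. Local maxima above `k_sigma` robust
#' noise scales of the top-hat image, falling inside a nucleus, are
#' retained; each spot's integrated value is the sum of the top-hat image
#' over the spot's connected above-threshold region dilated by 2 px (the
#' dilation recovers the sub-threshold tails of the spot profile).
#'
#' @param image Numeric phenotype image (nFISH channel).
#' @param nuclei Integer nucleus label matrix; spots outside any nucleus
#'   are not reported.
#' @param tophat_radius_px Structuring-element radius (default 5).
#' @param k_sigma Detection threshold in robust noise units (default 5).
#' @param min_distance_px Minimum peak separation (default 2).
#' @return data.frame: row, col, nucleus_label, integrated (A.U.).
#' @seealso [integratedNfishIntensity()]
#' @export
detectNfishSpots <- function(image, nuclei, tophat_radius_px = 5L,
                             k_sigma = 5, min_distance_px = 2) {
  stopifnot(all(dim(image) == dim(nuclei)))
  empty <- data.frame(row = integer(), col = integer(),
                      nucleus_label = integer(), integrated = numeric())
  if (!any(nuclei > 0)) return(empty)
  th <- grayTopHat(image, as.integer(tophat_radius_px))
  if (diff(range(th)) == 0) return(empty)
  med <- stats::median(th)
  thr <- med + k_sigma * robustScale(th)
  pk <- selectPeaks(th, min_distance_px, thr, mask = nuclei > 0)
  pk <- pk[pk$value > med, , drop = FALSE]
  if (!nrow(pk)) return(empty)
  # connected above-threshold regions, dilated to recover profile tails,
  # define each spot's support
  regions <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel((th > thr) * 1))), nrow(image), ncol(image))
  grown <- maxFilter(regions, 2L)
  reg_sum <- tapply(th[grown > 0], grown[grown > 0], sum)
  rid <- regions[cbind(pk$row, pk$col)]
  # a region with several peaks splits its mass equally between them
  mult <- table(rid)
  integ <- as.numeric(reg_sum[as.character(rid)]) /
    as.numeric(mult[as.character(rid)])
  data.frame(row = pk$row, col = pk$col,
             nucleus_label = nuclei[cbind(pk$row, pk$col)],
             integrated = integ)
}

#' Integrated telomeric nFISH intensity per nucleus
#'
#' Sums each nucleus's spot integrated values; nuclei with no detected
#' spots report 0. Integrated intensity is additive over spots and scales
#' linearly with the image (after the top-hat background model is
#' re-estimated on the scaled image).
#'
#' @param spots Spot table from [detectNfishSpots()].
#' @param nuclei Integer nucleus label matrix (defines the full set of
#'   reported nuclei).
#' @param fov_id FOV identifier stamped into the records.
#' @return data.frame: cell_label, fov_id, mode = "nfish",
#'   nfish_spot_count, nfish_integrated_intensity.
#' @export
integratedNfishIntensity <- function(spots, nuclei, fov_id = "fov") {
  labs <- sort(unique(nuclei[nuclei > 0]))
  out <- data.frame(cell_label = labs, fov_id = rep(fov_id, length(labs)),
                    mode = rep("nfish", length(labs)),
                    nfish_spot_count = 0L,
                    nfish_integrated_intensity = 0)
  if (nrow(spots)) {
    agg_n <- table(spots$nucleus_label)
    agg_s <- tapply(spots$integrated, spots$nucleus_label, sum)
    m <- match(names(agg_s), as.character(labs))
    ok <- !is.na(m)
    out$nfish_spot_count[m[ok]] <- as.integer(agg_n[ok])
    out$nfish_integrated_intensity[m[ok]] <- as.numeric(agg_s[ok])
  }
  out
}
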