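#' Convert a pixel centroid to global stage coordinates
#'
#' The FOV's stage coordinate refers to its centre; pixel (row, col) maps to
#' `x = stage_x + (col - (width-1)/2 - 1) * pixel_size` and likewise for y
#' (which grows with the row index). Centroids are 1-based pixel
#' coordinates, so the image centre pixel maps exactly onto the stage
#' coordinate.
#'
#' @param centroid_px Numeric length-2 `(row, col)` or a 2-column matrix.
#' @param fov A [FOVMetadata-class].
#' @return Numeric `(global_x_um, global_y_um)`, or a 2-column matrix.
#' @export
toGlobal <- function(centroid_px, fov) {
  ps <- fov@pixel_size_um
  if (is.matrix(centroid_px)) {
    x <- fov@stage_x_um + (centroid_px[, 2] - (fov@width_px - 1) / 2 - 1) * ps
    y <- fov@stage_y_um + (centroid_px[, 1] - (fov@height_px - 1) / 2 - 1) * ps
    return(cbind(global_x_um = x, global_y_um = y))
  }
  c(global_x_um = fov@stage_x_um +
      (centroid_px[2] - (fov@width_px - 1) / 2 - 1) * ps,
    global_y_um = fov@stage_y_um +
      (centroid_px[1] - (fov@height_px - 1) / 2 - 1) * ps)
}

# All pairwise squared distances between two point sets (n x 2, m x 2).
pairDist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

#' Estimate the systematic stage offset between two datasets
#'
#' Finds mutual nearest-neighbour pairs between the ISS and phenotype cell
#' tables within a coarse gate, and returns the componentwise median
#' displacement (ISS minus phenotype). The median makes the estimate robust
#' to a minority of wrong pairings. The offset should be added to the
#' phenotype coordinates before final matching.
#'
#' @param iss_cells,pheno_cells data.frames with `global_x_um`,
#'   `global_y_um` columns.
#' @param gate_um Coarse candidate gate (default 30).
#' @param min_pairs Minimum mutual-NN pairs required (default 10); below
#'   this the offset is (0, 0) with `warning = TRUE`.
#' @return list(dx_um, dy_um, n_pairs, warning).
#' @seealso [matchCells()]
#' @export
estimateOffset <- function(iss_cells, pheno_cells, gate_um = 30,
                           min_pairs = 10L) {
  a <- cbind(iss_cells$global_x_um, iss_cells$global_y_um)
  b <- cbind(pheno_cells$global_x_um, pheno_cells$global_y_um)
  if (!nrow(a) || !nrow(b))
    return(list(dx_um = 0, dy_um = 0, n_pairs = 0L, warning = TRUE))
  d2 <- pairDist2(a, b)
  nn_ab <- max.col(-d2, ties.method = "first")
  nn_ba <- max.col(-t(d2), ties.method = "first")
  i <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == i
  ok <- mutual & d2[cbind(i, nn_ab)] <= gate_um^2
  n <- sum(ok)
  if (n < min_pairs)
    return(list(dx_um = 0, dy_um = 0, n_pairs = n, warning = TRUE))
  dx <- stats::median(a[ok, 1] - b[nn_ab[ok], 1])
  dy <- stats::median(a[ok, 2] - b[nn_ab[ok], 2])
  list(dx_um = dx, dy_um = dy, n_pairs = n, warning = FALSE)
}

#' Match cells across magnifications with morphology verification
#'
#' Assumes the systematic offset has already been applied (or passes
#' `offset`). Candidate pairs are nearest neighbours within `gate_um`;
#' assignment is greedy one-to-one in order of increasing residual. A pair
#' is accepted only if all four morphological features (area and perimeter
#' in micrometre units, eccentricity and solidity dimensionless) agree to
#' within `morph_threshold` relative difference:
#' `|f_iss - f_ph| / max(f_iss, f_ph, eps) <= morph_threshold`.
#'
#' @param iss_cells,pheno_cells data.frames with global coordinates and
#'   morphology columns (area_um2, perimeter_um, eccentricity, solidity).
#' @param gate_um Candidate distance gate (default 15).
#' @param morph_threshold Per-feature relative tolerance (default 0.10).
#' @param offset Optional list from [estimateOffset()] applied to the
#'   phenotype coordinates first.
#' @param eps Guard for near-zero features (default 1e-6).
#' @return data.frame of candidate pairs: iss_fov, iss_label, pheno_fov,
#'   pheno_label, residual_um, rel_area, rel_perimeter, rel_eccentricity,
#'   rel_solidity, accepted. Accepted pairs are one-to-one.
#' @export
matchCells <- function(iss_cells, pheno_cells, gate_um = 15,
                       morph_threshold = 0.10, offset = NULL,
                       eps = 1e-6) {
  empty <- data.frame(iss_fov = character(), iss_label = integer(),
                      pheno_fov = character(), pheno_label = integer(),
                      residual_um = numeric(), rel_area = numeric(),
                      rel_perimeter = numeric(),
                      rel_eccentricity = numeric(),
                      rel_solidity = numeric(), accepted = logical())
  if (!nrow(iss_cells) || !nrow(pheno_cells)) return(empty)
  px <- pheno_cells$global_x_um
  py <- pheno_cells$global_y_um
  if (!is.null(offset)) { px <- px + offset$dx_um; py <- py + offset$dy_um }
  a <- cbind(iss_cells$global_x_um, iss_cells$global_y_um)
  b <- cbind(px, py)
  d2 <- pairDist2(a, b)
  nn <- max.col(-d2, ties.method = "first")
  res <- sqrt(d2[cbind(seq_len(nrow(a)), nn)])
  cand <- which(res <= gate_um)
  if (!length(cand)) return(empty)
  relDiff <- function(f) {
    fa <- iss_cells[[f]][cand]; fb <- pheno_cells[[f]][nn[cand]]
    abs(fa - fb) / pmax(fa, fb, eps)
  }
  out <- data.frame(
    iss_fov = iss_cells$fov_id[cand], iss_label = iss_cells$cell_label[cand],
    pheno_fov = pheno_cells$fov_id[nn[cand]],
    pheno_label = pheno_cells$cell_label[nn[cand]],
    residual_um = res[cand],
    rel_area = relDiff("area_um2"),
    rel_perimeter = relDiff("perimeter_um"),
    rel_eccentricity = relDiff("eccentricity"),
    rel_solidity = relDiff("solidity"))
  morph_ok <- out$rel_area <= morph_threshold &
    out$rel_perimeter <= morph_threshold &
    out$rel_eccentricity <= morph_threshold &
    out$rel_solidity <= morph_threshold
  # greedy one-to-one by increasing residual
  ord <- order(out$residual_um)
  used_ph <- character(0)
  accepted <- rep(FALSE, nrow(out))
  for (j in ord) {
    key <- paste(out$pheno_fov[j], out$pheno_label[j])
    if (morph_ok[j] && !(key %in% used_ph)) {
      accepted[j] <- TRUE
      used_ph <- c(used_ph, key)
    }
  }
  out$accepted <- accepted
  out
}
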