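#' Mann-Whitney U test with exact enumeration for small samples
#'
#' The statistic is `U = sum over pairs [x_i > y_j] + 1/2 [x_i = y_j]`.
#' When `n_x * n_y` does not exceed `exact_bound`, the two-sided p-value is
#' computed by full enumeration of all label arrangements of the pooled
#' sample (ties handled exactly): `p = min(1, 2 * min(P(U' <= U),
#' P(U' >= U)))`. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_bound Enumeration bound on `n_x * n_y` (default 64).
#' @return list(U, p, method) with method `"exact"` or `"normal"`.
#' @seealso [compareSgrnas()]
#' @export
mannWhitneyU <- function(x, y, exact_bound = 64L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)                       # midranks for ties
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx * ny <= exact_bound) {
    combs <- utils::combn(nx + ny, nx)
    Us <- apply(combs, 2, function(ix)
      sum(rk[ix]) - nx * (nx + 1) / 2)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    return(list(U = U, p = p, method = "exact"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Compare every sgRNA's phenotype distribution against control cells
#'
#' Tests each non-control sgRNA's per-cell phenotype values against the
#' pooled control cells with a two-sided Mann-Whitney U test, applies a
#' Bonferroni correction over the number of non-control sgRNAs, and
#' reports fold changes of means. sgRNAs with fewer than `min_cells` cells
#' are flagged `low_n` but still reported.
#'
#' @param cells data.frame with columns `sgrna_id`, `value` and optionally
#'   `gene`.
#' @param control_ids Character vector of control sgRNA ids whose cells are
#'   pooled as the reference sample.
#' @param min_cells Reporting threshold on cells per sgRNA (default 3000);
#'   a flag, not a filter.
#' @param exact_bound Passed to [mannWhitneyU()].
#' @param sgrna_ids Optional full roster of non-control sgRNA ids to report;
#'   ids with no cells get an NA-statistics row. Defaults to the non-control
#'   ids present in `cells`.
#' @return data.frame (one row per non-control sgRNA): sgrna_id, gene,
#'   n_cells, mean_intensity, median_intensity, fold_change_vs_control, U,
#'   p_raw, p_bonferroni, n_tests, low_n.
#' @export
compareSgrnas <- function(cells, control_ids, min_cells = 3000L,
                          exact_bound = 64L, sgrna_ids = NULL) {
  stopifnot(all(c("sgrna_id", "value") %in% names(cells)))
  ctl <- cells$value[cells$sgrna_id %in% control_ids]
  if (!length(ctl)) stop("no control cells")
  test_ids <- if (is.null(sgrna_ids))
    setdiff(unique(cells$sgrna_id), control_ids)
  else setdiff(sgrna_ids, control_ids)
  n_tests <- sum(vapply(test_ids, function(id)
    any(cells$sgrna_id == id), logical(1)))
  rows <- lapply(test_ids, function(id) {
    v <- cells$value[cells$sgrna_id == id]
    mw <- if (length(v)) mannWhitneyU(v, ctl, exact_bound) else
      list(U = NA_real_, p = NA_real_)
    data.frame(
      sgrna_id = id,
      gene = if ("gene" %in% names(cells))
        cells$gene[match(id, cells$sgrna_id)] else NA_character_,
      n_cells = length(v),
      mean_intensity = if (length(v)) mean(v) else NA_real_,
      median_intensity = if (length(v)) stats::median(v) else NA_real_,
      fold_change_vs_control = if (length(v)) mean(v) / mean(ctl)
        else NA_real_,
      U = mw$U, p_raw = mw$p,
      p_bonferroni = min(1, mw$p * n_tests),
      n_tests = n_tests,
      low_n = length(v) < min_cells)
  })
  do.call(rbind, rows)
}

#' Empirical cumulative distribution function table
#'
#' Right-continuous ECDF as a step table: at each distinct value, the
#' fraction of observations less than or equal to it. `ECDF(max) = 1` and
#' the function is 0 below the minimum.
#'
#' @param values Non-empty numeric sample.
#' @return data.frame(value, ecdf), sorted by value.
#' @export
ecdfTable <- function(values) {
  stopifnot(length(values) > 0)
  v <- sort(unique(values))
  f <- stats::ecdf(values)
  data.frame(value = v, ecdf = f(v))
}
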