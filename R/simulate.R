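#' Default 14-sgRNA screen codebook
#'
#' A fixed codebook mirroring the design of a focused ALT-activity screen:
#' three sgRNAs each against FANCM, DDX39A and BLM, three non-targeting
#' controls and two safe-targeting controls, for a total of 14 sgRNAs. The
#' 12-nt barcodes are fixed and base-balanced: minimum pairwise Hamming
#' distance 6, every base appearing at least three times at every position
#' (the colour balance SBS panel design calls for, and what keeps every
#' base class populated when estimating the per-cycle crosstalk-correction
#' matrix), and every barcode using at least three distinct bases so that
#' each spot shows cycle-to-cycle channel variation.
#'
#' @return A [Codebook-class] with 14 entries.
#' @export
defaultCodebook <- function() {
  Codebook(
    sgrna_id = c("sgFANCM-1", "sgFANCM-2", "sgFANCM-3",
                 "sgDDX39A-1", "sgDDX39A-2", "sgDDX39A-3",
                 "sgBLM-1", "sgBLM-2", "sgBLM-3",
                 "sgCTL-1", "sgCTL-2", "sgCTL-3",
                 "sgSafe-1", "sgSafe-2"),
    barcode = c("GGTACTCTGGTT", "GACTGCGTCAAT", "CGACCGGAGAGG",
                "AGTACGTATGCG", "CAGGACAGCACG", "CACCTCACTTGT",
                "CGCGATTGACTA", "GCGGTAGGTAGA", "GTTTGGACCTGT",
                "TTTTGTCCGTTC", "ATGCCGTCATCC", "TACATACTCGAC",
                "ACAGAACATCTC", "TCACAAAGACAA"),
    gene = c(rep("FANCM", 3), rep("DDX39A", 3), rep("BLM", 3),
             rep("CTL", 3), rep("Safe", 2)),
    role = c(rep("targeting", 9), rep("non_targeting_control", 3),
             rep("safe_targeting", 2))
  )
}

#' Default channel crosstalk matrix
#'
#' Column-stochastic 4x4 mixing matrix applied to the one-hot base signal:
#' diagonal 0.8, off-diagonal 0.2/3, emulating spectral bleed-through between
#' the four SBS dye channels.
#'
#' @param diag_value Diagonal (on-channel) fraction; off-diagonals share the
#'   remaining `1 - diag_value` equally.
#' @return 4x4 numeric matrix with rows/cols ordered G, T, A, C.
#' @export
defaultCrosstalk <- function(diag_value = 0.8) {
  off <- (1 - diag_value) / 3
  M <- matrix(off, 4, 4, dimnames = list(SBS_BASES, SBS_BASES))
  diag(M) <- diag_value
  M
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic optical-pooled-screen generator. The
#' defaults define the reference study conditions: 12 SBS cycles, a mean of
#' 2.5 reads per cell, one sgRNA per cell (the low-MOI idealization), channel
#' crosstalk with a 0.8 diagonal, per-cycle signal decay and growing
#' fluorescence background, and phenotype effects of 2.90x (FANCM), 1.0x
#' (DDX39A) and 0.80x (BLM) on a log-normal nFISH intensity baseline with
#' mean 1144 A.U.
#'
#' @param seed Integer seed; all randomness in [simulateScreen()] flows from it.
#' @param n_fovs_iss Number of ISS fields of view (laid out on a near-square
#'   grid of adjacent stage positions).
#' @param fov_px ISS FOV side length in pixels.
#' @param cells_per_fov Mean cell count per ISS FOV (Poisson).
#' @param codebook A [Codebook-class]; default [defaultCodebook()].
#' @param sgrna_proportions Optional named numeric vector of sgRNA sampling
#'   weights; default uniform.
#' @param reads_per_cell_mean Mean ISS spots per cell (Poisson).
#' @param n_cycles Number of SBS cycles (must not exceed barcode length).
#' @param signal_amplitude Peak on-channel spot intensity at cycle 1 (A.U.).
#' @param decay_per_cycle Multiplicative signal decay per cycle, in (0, 1].
#' @param background_start,background_growth_per_cycle Fluorescence
#'   background level at cycle 1 and its additive growth per cycle.
#' @param crosstalk 4x4 mixing matrix (columns = true base G,T,A,C); must be
#'   diagonally dominant.
#' @param jitter_px_max Maximum absolute integer stage jitter per cycle (px).
#' @param noise_sd Additive Gaussian read noise SD (A.U. per pixel).
#' @param poisson_noise If TRUE, adds shot noise (Poisson resampling of the
#'   noiseless frame) before the Gaussian term.
#' @param psf_sigma_px Gaussian point-spread sigma for ISS spots (px). The
#'   default 1.0 px at 10X (0.65 um, FWHM ~1.5 um) reflects a ~1 um
#'   rolling-circle amplicon imaged through a 10X widefield objective.
#' @param dapi_amplitude Nuclear DAPI intensity above background.
#' @param optical_blur_um Gaussian optical blur applied to rendered nuclei
#'   and cytoplasm, in micrometres (a physical point-spread, so the same
#'   cell renders consistently at every magnification).
#' @param doublet_rate Fraction of cells carrying a second sgRNA.
#' @param nucleus_radius_um_range Range of nucleus semi-major axis (um).
#' @param nucleus_axis_ratio_range Range of the major/minor axis ratio.
#'   The lower bound stays away from 1 (perfect circles) because adherent
#'   cancer-line nuclei are visibly elongated and a relative eccentricity
#'   comparison is only informative away from the circular degeneracy.
#' @param cell_expand_um Cytoplasm expansion beyond the nucleus (um).
#' @param phenotype_effects Named per-gene multiplicative effects on the
#'   nFISH intensity mean; genes absent from the map have effect 1.
#' @param phenotype_baseline_mean Mean integrated nFISH intensity of control
#'   cells (A.U.).
#' @param phenotype_log_sd Log-scale SD of the per-cell log-normal intensity.
#' @param nfish_spots_mean Mean number of telomeric nFISH spots per nucleus.
#' @param nfish_psf_sigma_um Gaussian sigma of rendered nFISH spots (um).
#' @param nfish_background,nfish_noise_sd Background level and noise SD of
#'   phenotype images.
#' @param pixel_size_um Named vector of um/pixel per magnification.
#' @param phenotype_magnification Magnification label of phenotype imaging.
#' @param phenotype_fov_px Phenotype FOV side length in pixels.
#' @param phenotype_stage_offset_um Systematic (x, y) offset planted in the
#'   phenotype FOV stage metadata (um), emulating a stage re-homing between
#'   acquisitions; the match module must recover it.
#' @param render_phenotype If FALSE, skip rendering the phenotype-
#'   magnification tiles (ground-truth phenotype values are still drawn).
#' @return A validated list of class `ops_sim_config`.
#' @seealso [simulateScreen()], [simulatePhenotypeValues()]
#' @export
simConfig <- function(seed = 1L,
                      n_fovs_iss = 4L,
                      fov_px = 200L,
                      cells_per_fov = 25,
                      codebook = defaultCodebook(),
                      sgrna_proportions = NULL,
                      reads_per_cell_mean = 2.5,
                      n_cycles = 12L,
                      signal_amplitude = 1000,
                      decay_per_cycle = 0.97,
                      background_start = 100,
                      background_growth_per_cycle = 10,
                      crosstalk = defaultCrosstalk(),
                      jitter_px_max = 5L,
                      noise_sd = 50,
                      poisson_noise = FALSE,
                      psf_sigma_px = 1.0,
                      dapi_amplitude = 600,
                      optical_blur_um = 0.5,
                      doublet_rate = 0,
                      nucleus_radius_um_range = c(4, 6),
                      nucleus_axis_ratio_range = c(1.2, 1.8),
                      cell_expand_um = 2.5,
                      phenotype_effects = c(FANCM = 2.90, BLM = 0.80,
                                            DDX39A = 1.0),
                      phenotype_baseline_mean = 1144,
                      phenotype_log_sd = 0.8,
                      nfish_spots_mean = 4,
                      nfish_psf_sigma_um = 0.25,
                      nfish_background = 10,
                      nfish_noise_sd = 2,
                      pixel_size_um = c("10X" = 0.65, "20X" = 0.325,
                                        "40X" = 0.1625),
                      phenotype_magnification = "40X",
                      phenotype_fov_px = 400L,
                      phenotype_stage_offset_um = c(0, 0),
                      render_phenotype = TRUE) {
  cfg <- as.list(environment())
  stopifnot(is(codebook, "Codebook"))
  if (!(decay_per_cycle > 0 && decay_per_cycle <= 1))
    stop("decay_per_cycle must lie in (0, 1]")
  if (!all(dim(crosstalk) == c(4, 4)))
    stop("crosstalk must be a 4x4 matrix")
  if (any(diag(crosstalk) <= rowSums(crosstalk) - diag(crosstalk) - 1e-9))
    stop("crosstalk must be diagonally dominant")
  if (any(cfg$phenotype_effects <= 0))
    stop("phenotype effects must be > 0")
  if (n_cycles > nchar(barcodes(codebook)[1]))
    stop("n_cycles exceeds barcode length")
  if (!phenotype_magnification %in% names(pixel_size_um))
    stop("no pixel size for phenotype magnification")
  class(cfg) <- "ops_sim_config"
  cfg
}

#' Add a Gaussian spot to an image
#'
#' Adds an isotropic 2-D Gaussian with peak height `amplitude` and scale
#' `sigma` at the (possibly fractional) position `pos = (row, col)`. For
#' `sigma >= 1` px the total added intensity for an interior spot equals
#' `amplitude * 2 * pi * sigma^2` to well within 1\% (lattice summation of
#' the Gaussian); spots are truncated beyond `6 * sigma`.
#'
#' @param image Numeric matrix.
#' @param pos Numeric length-2 `(row, col)`, 1-based, inside the image.
#' @param amplitude Peak height (0 leaves the image unchanged).
#' @param sigma Gaussian sigma in pixels.
#' @return The image with the spot added (linear superposition).
#' @export
renderSpot <- function(image, pos, amplitude, sigma) {
  if (amplitude == 0) return(image)
  if (pos[1] < 1 || pos[1] > nrow(image) || pos[2] < 1 || pos[2] > ncol(image))
    stop("spot position outside the image")
  r <- ceiling(6 * sigma)
  r0 <- max(1L, floor(pos[1]) - r); r1 <- min(nrow(image), ceiling(pos[1]) + r)
  c0 <- max(1L, floor(pos[2]) - r); c1 <- min(ncol(image), ceiling(pos[2]) + r)
  rr <- r0:r1; cc <- c0:c1
  g <- amplitude *
    exp(-outer((rr - pos[1])^2, (cc - pos[2])^2, "+") / (2 * sigma^2))
  image[rr, cc] <- image[rr, cc] + g
  image
}

# Near-square grid layout for n FOVs; returns data.frame(ix, iy) of 0-based
# grid indices.
fovGrid <- function(n) {
  ncol_ <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  data.frame(ix = idx %% ncol_, iy = idx %/% ncol_)
}

#' Simulate a full optical pooled screen with ground truth
#'
#' Generates a synthetic screen with the statistical structure the analysis
#' pipeline assumes: cells with elliptical nuclei and expanded cell bodies on
#' a shared physical world; one sgRNA per cell (optional doublets); ISS spot
#' counts Poisson with the configured mean; per-cycle on-channel signal
#' `signal_amplitude * decay^(cycle-1)` mixed through the crosstalk matrix,
#' on a background `background_start + (cycle-1) * growth`, blurred by a
#' Gaussian point-spread, translated by a per-cycle integer stage jitter
#' (recorded in the ground truth) and corrupted by additive Gaussian noise;
#' and a second rendering of the same cells at phenotype magnification where
#' each nucleus carries telomeric nFISH spots whose integrated intensity is
#' log-normal scaled by the per-gene effect.
#'
#' @param cfg An `ops_sim_config` from [simConfig()].
#' @return A list with elements:
#'   \describe{
#'     \item{iss}{list of [SBSImageStack-class], one per ISS FOV.}
#'     \item{phenotype}{list of per-FOV lists with `fov` ([FOVMetadata-class]),
#'       `dapi` and `nfish` image matrices.}
#'     \item{truth}{list of data.frames `cells`, `spots`, `shifts`, plus
#'       `phenotype_offset_um`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulateScreen <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "ops_sim_config"))
  set.seed(cfg$seed)
  ps_iss <- cfg$pixel_size_um[["10X"]]
  h <- cfg$fov_px; w <- cfg$fov_px
  fw_um <- w * ps_iss; fh_um <- h * ps_iss
  grid <- fovGrid(cfg$n_fovs_iss)
  cb <- codebookTable(cfg$codebook)
  probs <- cfg$sgrna_proportions
  if (is.null(probs)) probs <- stats::setNames(rep(1, nrow(cb)), cb$sgrna_id)
  probs <- probs[cb$sgrna_id] / sum(probs)

  cells <- list(); spots <- list(); shifts <- list(); stacks <- list()
  cell_id0 <- 0L
  for (fi in seq_len(cfg$n_fovs_iss)) {
    fov_id <- sprintf("iss_%03d", fi)
    cx <- grid$ix[fi] * fw_um + fw_um / 2
    cy <- grid$iy[fi] * fh_um + fh_um / 2
    fov <- FOVMetadata(fov_id, stage_x_um = cx, stage_y_um = cy,
                       pixel_size_um = ps_iss, magnification = "10X",
                       height_px = h, width_px = w)
    n_cells <- stats::rpois(1, cfg$cells_per_fov)
    fcells <- placeCells(n_cells, h, w, ps_iss, cfg, cell_id0, fov_id)
    cell_id0 <- cell_id0 + n_cells
    # assign sgRNAs and spots
    if (n_cells > 0) {
      idx <- sample.int(nrow(cb), n_cells, replace = TRUE, prob = probs)
      fcells$sgrna_id <- cb$sgrna_id[idx]
      fcells$gene <- cb$gene[idx]
      fcells$barcode <- cb$barcode[idx]
      dbl <- stats::runif(n_cells) < cfg$doublet_rate
      idx2 <- ifelse(dbl, sample.int(nrow(cb), n_cells, replace = TRUE), NA)
      fcells$second_sgrna_id <- ifelse(dbl, cb$sgrna_id[idx2], NA_character_)
      fcells$second_barcode <- ifelse(dbl, cb$barcode[idx2], NA_character_)
    }
    fspots <- placeSpots(fcells, cfg, ps_iss)
    # per-cycle jitter (cycle 1 is the reference: zero)
    jy <- c(0L, sample(seq(-cfg$jitter_px_max, cfg$jitter_px_max),
                       cfg$n_cycles - 1L, replace = TRUE))
    jx <- c(0L, sample(seq(-cfg$jitter_px_max, cfg$jitter_px_max),
                       cfg$n_cycles - 1L, replace = TRUE))
    stacks[[fi]] <- renderISSFov(fcells, fspots, jy, jx, fov, cfg)
    shifts[[fi]] <- data.frame(fov_id = fov_id, cycle = seq_len(cfg$n_cycles),
                               jy_px = jy, jx_px = jx)
    cells[[fi]] <- fcells
    spots[[fi]] <- fspots
  }
  cells <- do.call(rbind, cells)
  spots <- do.call(rbind, spots)
  shifts <- do.call(rbind, shifts)

  # phenotype intensities: log-normal baseline scaled per gene
  if (nrow(cells)) {
    eff <- effectFor(cells$gene, cfg$phenotype_effects)
    mu <- log(cfg$phenotype_baseline_mean * eff) - cfg$phenotype_log_sd^2 / 2
    cells$nfish_true <- stats::rlnorm(nrow(cells), meanlog = mu,
                                      sdlog = cfg$phenotype_log_sd)
  } else cells$nfish_true <- numeric(0)

  pheno <- if (cfg$render_phenotype) renderPhenotypeFovs(cells, cfg)
    else list()

  list(
    iss = stacks,
    phenotype = pheno,
    truth = list(cells = cells, spots = spots, shifts = shifts,
                 phenotype_offset_um = cfg$phenotype_stage_offset_um),
    config = cfg
  )
}

effectFor <- function(gene, effects) {
  e <- effects[gene]
  e[is.na(e)] <- 1
  unname(e)
}

# Place cells on a jittered grid inside one FOV; coordinates in the FOV pixel
# frame plus global um. Cells whose nucleus would cross the border are
# clipped and flagged.
placeCells <- function(n, h, w, ps, cfg, id0, fov_id) {
  if (n == 0L)
    return(data.frame(cell_id = integer(), fov_id = character(),
                      row_px = numeric(), col_px = numeric(),
                      a_um = numeric(), b_um = numeric(), theta = numeric(),
                      clipped = logical(), sgrna_id = character(),
                      gene = character(), barcode = character(),
                      second_sgrna_id = character(),
                      second_barcode = character()))
  k <- ceiling(sqrt(n))
  slots <- sample(k * k, n)
  sr <- (slots - 1) %/% k; sc <- (slots - 1) %% k
  cell_r <- (max(cfg$nucleus_radius_um_range) + cfg$cell_expand_um) / ps
  pitch_r <- (h - 2 * cell_r) / k; pitch_c <- (w - 2 * cell_r) / k
  jit <- 0.25
  row_px <- cell_r + (sr + 0.5 + stats::runif(n, -jit, jit)) * pitch_r
  col_px <- cell_r + (sc + 0.5 + stats::runif(n, -jit, jit)) * pitch_c
  a_um <- stats::runif(n, cfg$nucleus_radius_um_range[1],
                       cfg$nucleus_radius_um_range[2])
  ratio <- stats::runif(n, cfg$nucleus_axis_ratio_range[1],
                        cfg$nucleus_axis_ratio_range[2])
  b_um <- a_um / ratio
  theta <- stats::runif(n, 0, pi)
  clipped <- row_px - a_um / ps < 1 | row_px + a_um / ps > h |
             col_px - a_um / ps < 1 | col_px + a_um / ps > w
  data.frame(cell_id = id0 + seq_len(n), fov_id = fov_id,
             row_px = row_px, col_px = col_px,
             a_um = a_um, b_um = b_um, theta = theta, clipped = clipped,
             sgrna_id = NA_character_, gene = NA_character_,
             barcode = NA_character_, second_sgrna_id = NA_character_,
             second_barcode = NA_character_)
}

# Poisson spot counts per cell; uniform positions inside the cell body
# ellipse (nucleus expanded by cell_expand_um). Doublet cells split reads
# between their two barcodes.
placeSpots <- function(fcells, cfg, ps) {
  out <- list()
  for (i in seq_len(nrow(fcells))) {
    n_sp <- stats::rpois(1, cfg$reads_per_cell_mean)
    if (n_sp == 0) next
    ce <- fcells[i, ]
    a_px <- (ce$a_um + cfg$cell_expand_um) / ps
    b_px <- (ce$b_um + cfg$cell_expand_um) / ps
    # rejection-free: sample in unit disk, map to ellipse
    r <- sqrt(stats::runif(n_sp)) * 0.9
    ang <- stats::runif(n_sp, 0, 2 * pi)
    u <- r * cos(ang) * a_px; v <- r * sin(ang) * b_px
    row <- ce$row_px + u * sin(ce$theta) + v * cos(ce$theta)
    col <- ce$col_px + u * cos(ce$theta) - v * sin(ce$theta)
    bcode <- ce$barcode
    if (!is.na(ce$second_barcode)) {
      use2 <- stats::runif(n_sp) < 0.5
      bcode <- ifelse(use2, ce$second_barcode, ce$barcode)
    }
    out[[length(out) + 1L]] <-
      data.frame(cell_id = ce$cell_id, fov_id = ce$fov_id,
                 row_px = row, col_px = col,
                 barcode = if (length(bcode) == 1) rep(bcode, n_sp) else bcode)
  }
  if (!length(out))
    return(data.frame(spot_id = integer(), cell_id = integer(),
                      fov_id = character(), row_px = numeric(),
                      col_px = numeric(), barcode = character()))
  sp <- do.call(rbind, out)
  sp$spot_id <- seq_len(nrow(sp))
  sp[, c("spot_id", "cell_id", "fov_id", "row_px", "col_px", "barcode")]
}

# Render one ISS FOV: a padded noiseless canvas per cycle/channel, cropped at
# the cycle's jitter offset, then noise. DAPI content is identical across
# cycles (up to jitter + noise).
renderISSFov <- function(fcells, fspots, jy, jx, fov, cfg) {
  h <- fov@height_px; w <- fov@width_px
  p <- cfg$jitter_px_max
  ph <- h + 2L * p; pw <- w + 2L * p
  ps <- fov@pixel_size_um
  # DAPI canvas: nuclei ellipses, softened
  dapi <- matrix(0, ph, pw)
  for (i in seq_len(nrow(fcells))) {
    ce <- fcells[i, ]
    m <- ellipseMask(ph, pw, ce$row_px + p, ce$col_px + p,
                     ce$a_um / ps, ce$b_um / ps, ce$theta)
    dapi <- dapi + m * cfg$dapi_amplitude
  }
  blur_px <- max(cfg$optical_blur_um / ps, 0.4)
  if (nrow(fcells)) dapi <- EBImage::gblur(dapi, sigma = blur_px)
  # cytoplasm canvas (shared signal floor on SBS channels so cell bodies are
  # visible to the watershed): faint uniform cytoplasmic autofluorescence
  cyto <- matrix(0, ph, pw)
  for (i in seq_len(nrow(fcells))) {
    ce <- fcells[i, ]
    m <- ellipseMask(ph, pw, ce$row_px + p, ce$col_px + p,
                     (ce$a_um + cfg$cell_expand_um) / ps,
                     (ce$b_um + cfg$cell_expand_um) / ps, ce$theta)
    cyto <- cyto + m * 0.08 * cfg$signal_amplitude
  }
  if (nrow(fcells)) cyto <- EBImage::gblur(cyto, sigma = blur_px)

  # per-spot Gaussian patches (position-dependent, channel-independent)
  n_sp <- nrow(fspots)
  patch <- vector("list", n_sp)
  if (n_sp) {
    rad <- ceiling(6 * cfg$psf_sigma_px)
    for (si in seq_len(n_sp)) {
      pr <- fspots$row_px[si] + p; pc <- fspots$col_px[si] + p
      r0 <- max(1L, floor(pr) - rad); r1 <- min(ph, ceiling(pr) + rad)
      c0 <- max(1L, floor(pc) - rad); c1 <- min(pw, ceiling(pc) + rad)
      rr <- r0:r1; cc <- c0:c1
      patch[[si]] <- list(rr = rr, cc = cc,
        g = exp(-outer((rr - pr)^2, (cc - pc)^2, "+") /
                  (2 * cfg$psf_sigma_px^2)))
    }
  }
  px <- array(0, dim = c(cfg$n_cycles, 5L, h, w))
  for (cyc in seq_len(cfg$n_cycles)) {
    bg <- cfg$background_start + (cyc - 1) * cfg$background_growth_per_cycle
    sig <- cfg$signal_amplitude * cfg$decay_per_cycle^(cyc - 1)
    base_idx <- if (n_sp) match(substr(fspots$barcode, cyc, cyc), SBS_BASES)
    frames <- vector("list", 5L)
    for (b in 1:4) {
      m <- bg + cyto
      for (si in seq_len(n_sp)) {
        amp <- cfg$crosstalk[b, base_idx[si]] * sig
        pt <- patch[[si]]
        m[pt$rr, pt$cc] <- m[pt$rr, pt$cc] + amp * pt$g
      }
      frames[[b + 1L]] <- m
    }
    # crop window offset by the planted jitter: frame = scene translated by
    # (jy, jx)
    rows <- (p + 1L - jy[cyc]):(p + h - jy[cyc])
    cols <- (p + 1L - jx[cyc]):(p + w - jx[cyc])
    frames[[1]] <- (dapi + cfg$background_start)[rows, cols]
    for (b in 2:5) frames[[b]] <- frames[[b]][rows, cols]
    for (k in 1:5) {
      f <- frames[[k]]
      if (cfg$poisson_noise) f <- matrix(stats::rpois(length(f), pmax(f, 0)),
                                         nrow(f), ncol(f))
      if (cfg$noise_sd > 0)
        f <- f + matrix(stats::rnorm(length(f), 0, cfg$noise_sd),
                        nrow(f), ncol(f))
      px[cyc, k, , ] <- pmax(f, 0)
    }
  }
  SBSImageStack(px, fov = fov)
}

# Render the phenotype-magnification tiles covering the ISS world: DAPI plus
# an nFISH channel whose per-nucleus spots sum to the planted intensity.
renderPhenotypeFovs <- function(cells, cfg) {
  ps <- cfg$pixel_size_um[[cfg$phenotype_magnification]]
  ps_iss <- cfg$pixel_size_um[["10X"]]
  grid <- fovGrid(cfg$n_fovs_iss)
  world_w_um <- (max(grid$ix) + 1) * cfg$fov_px * ps_iss
  world_h_um <- (max(grid$iy) + 1) * cfg$fov_px * ps_iss
  fp <- cfg$phenotype_fov_px
  f_um <- fp * ps
  nx <- max(1L, ceiling(world_w_um / f_um))
  ny <- max(1L, ceiling(world_h_um / f_um))
  off <- cfg$phenotype_stage_offset_um
  # pre-draw nFISH spot decomposition per cell (deterministic given seed)
  spot_list <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- 1L + stats::rpois(1, max(cfg$nfish_spots_mean - 1, 0))
    wgt <- stats::rexp(k); wgt <- wgt / sum(wgt)
    r <- sqrt(stats::runif(k)) * 0.85
    ang <- stats::runif(k, 0, 2 * pi)
    spot_list[[i]] <- data.frame(
      frac = wgt,
      du_um = r * cos(ang) * cells$a_um[i],
      dv_um = r * sin(ang) * cells$b_um[i])
  }
  gx <- cellGlobalX(cells, cfg)   # true world coordinates, um
  gy <- cellGlobalY(cells, cfg)
  out <- list()
  fi <- 0L
  for (iy in seq_len(ny) - 1L) {
    for (ix in seq_len(nx) - 1L) {
      fi <- fi + 1L
      cx <- ix * f_um + f_um / 2
      cy <- iy * f_um + f_um / 2
      fov <- FOVMetadata(sprintf("ph_%03d", fi),
                         stage_x_um = cx + off[1], stage_y_um = cy + off[2],
                         pixel_size_um = ps,
                         magnification = cfg$phenotype_magnification,
                         height_px = fp, width_px = fp)
      dapi <- matrix(0, fp, fp)
      nfish <- matrix(0, fp, fp)
      # cells whose nucleus can intersect this tile
      margin <- max(cells$a_um, 0) + 2
      sel <- which(gx > cx - f_um / 2 - margin & gx < cx + f_um / 2 + margin &
                   gy > cy - f_um / 2 - margin & gy < cy + f_um / 2 + margin)
      for (i in sel) {
        row <- (gy[i] - (cy - f_um / 2)) / ps + 0.5
        col <- (gx[i] - (cx - f_um / 2)) / ps + 0.5
        m <- ellipseMask(fp, fp, row, col, cells$a_um[i] / ps,
                         cells$b_um[i] / ps, cells$theta[i])
        dapi <- dapi + m * cfg$dapi_amplitude
        sp <- spot_list[[i]]
        sig_px <- cfg$nfish_psf_sigma_um / ps
        for (j in seq_len(nrow(sp))) {
          srow <- row + (sp$du_um[j] * sin(cells$theta[i]) +
                         sp$dv_um[j] * cos(cells$theta[i])) / ps
          scol <- col + (sp$du_um[j] * cos(cells$theta[i]) -
                         sp$dv_um[j] * sin(cells$theta[i])) / ps
          if (srow >= 1 && srow <= fp && scol >= 1 && scol <= fp) {
            amp <- cells$nfish_true[i] * sp$frac[j] / (2 * pi * sig_px^2)
            nfish <- renderSpot(nfish, c(srow, scol), amp, sig_px)
          }
        }
      }
      dapi <- EBImage::gblur(dapi + cfg$nfish_background,
                             sigma = cfg$optical_blur_um / ps)
      nfish <- nfish + cfg$nfish_background
      if (cfg$nfish_noise_sd > 0) {
        dapi <- dapi + matrix(stats::rnorm(fp * fp, 0, cfg$nfish_noise_sd), fp, fp)
        nfish <- nfish + matrix(stats::rnorm(fp * fp, 0, cfg$nfish_noise_sd), fp, fp)
      }
      out[[fi]] <- list(fov = fov, dapi = pmax(dapi, 0),
                        nfish = pmax(nfish, 0))
    }
  }
  out
}

# True global coordinates (um) of simulated cells from their ISS FOV frame.
cellGlobalX <- function(cells, cfg) {
  ps <- cfg$pixel_size_um[["10X"]]
  grid <- fovGrid(cfg$n_fovs_iss)
  fi <- as.integer(sub("iss_", "", cells$fov_id))
  grid$ix[fi] * cfg$fov_px * ps + (cells$col_px - 0.5) * ps
}

cellGlobalY <- function(cells, cfg) {
  ps <- cfg$pixel_size_um[["10X"]]
  grid <- fovGrid(cfg$n_fovs_iss)
  fi <- as.integer(sub("iss_", "", cells$fov_id))
  grid$iy[fi] * cfg$fov_px * ps + (cells$row_px - 0.5) * ps
}

#' Draw per-cell phenotype values from the generative model
#'
#' Samples integrated nFISH intensities for `n_per_sgrna` cells per sgRNA
#' directly from the simulator's log-normal phenotype model (baseline mean
#' scaled by the per-gene effect), without image rendering. This is the
#' generator used for statistical power / calibration experiments at cell
#' counts where rendering images would add nothing.
#'
#' @param codebook A [Codebook-class].
#' @param n_per_sgrna Cells per sgRNA.
#' @param effects Named per-gene multiplicative effects (default as in
#'   [simConfig()]).
#' @param baseline_mean Control-cell mean integrated intensity (A.U.).
#' @param log_sd Log-scale SD.
#' @return data.frame with columns sgrna_id, gene, role, value.
#' @export
simulatePhenotypeValues <- function(codebook = defaultCodebook(),
                                    n_per_sgrna = 3000,
                                    effects = c(FANCM = 2.90, BLM = 0.80,
                                                DDX39A = 1.0),
                                    baseline_mean = 1144,
                                    log_sd = 0.8) {
  cb <- codebookTable(codebook)
  n_tot <- nrow(cb) * n_per_sgrna
  gene <- rep(cb$gene, each = n_per_sgrna)
  eff <- effectFor(gene, effects)
  mu <- log(baseline_mean * eff) - log_sd^2 / 2
  data.frame(
    sgrna_id = rep(cb$sgrna_id, each = n_per_sgrna),
    gene = gene,
    role = rep(cb$role, each = n_per_sgrna),
    value = stats::rlnorm(n_tot, meanlog = mu, sdlog = log_sd)
  )
}

#' Simulate matched two-magnification cell tables
#'
#' Builds the table-level fixture for cross-magnification matching: the same
#' simulated cells measured at ISS (10X) and phenotype (default 40X)
#' magnification. Each cell's nucleus ellipse is rasterized independently at
#' both pixel sizes and measured with [measureMorphology()], so morphology
#' differences reflect genuine rasterization effects; centroids receive
#' Gaussian noise of `centroid_noise_um`, and the phenotype dataset's
#' coordinates carry the planted systematic stage offset.
#'
#' @param n_cells Number of cells.
#' @param centroid_noise_um Per-axis Gaussian centroid noise (um).
#' @param offset_um Planted (x, y) systematic offset of the phenotype stage
#'   metadata (um).
#' @param cfg An `ops_sim_config` controlling geometry and pixel sizes.
#' @return list(iss_cells, pheno_cells, pairs): two global-cell data.frames
#'   (columns dataset, fov_id, cell_label, global_x_um, global_y_um,
#'   area_um2, perimeter_um, eccentricity, solidity) and the true pairing.
#' @export
simulateCellTables <- function(n_cells = 300, centroid_noise_um = 1,
                               offset_um = c(0, 0), cfg = simConfig()) {
  set.seed(cfg$seed + 7L)
  a_um <- stats::runif(n_cells, cfg$nucleus_radius_um_range[1],
                       cfg$nucleus_radius_um_range[2])
  ratio <- stats::runif(n_cells, cfg$nucleus_axis_ratio_range[1],
                        cfg$nucleus_axis_ratio_range[2])
  b_um <- a_um / ratio
  theta <- stats::runif(n_cells, 0, pi)
  # spread cells so nearest neighbours are well separated relative to noise
  side <- ceiling(sqrt(n_cells))
  pitch <- 30  # um
  gx <- ((seq_len(n_cells) - 1L) %% side) * pitch +
    stats::runif(n_cells, -8, 8)
  gy <- ((seq_len(n_cells) - 1L) %/% side) * pitch +
    stats::runif(n_cells, -8, 8)
  measureOne <- function(i, ps) {
    a <- a_um[i] / ps; b <- b_um[i] / ps
    sz <- ceiling(2 * a + 8)
    m <- ellipseMask(sz, sz, sz / 2, sz / 2, a, b, theta[i])
    fov <- FOVMetadata("tmp", pixel_size_um = ps, height_px = sz,
                       width_px = sz)
    measureMorphology(m * 1L, fov)[1, ]
  }
  ps_iss <- cfg$pixel_size_um[["10X"]]
  ps_ph <- cfg$pixel_size_um[[cfg$phenotype_magnification]]
  m_iss <- do.call(rbind, lapply(seq_len(n_cells), measureOne, ps = ps_iss))
  m_ph <- do.call(rbind, lapply(seq_len(n_cells), measureOne, ps = ps_ph))
  noise <- function(n) stats::rnorm(n, 0, centroid_noise_um)
  iss_cells <- data.frame(
    dataset = "iss", fov_id = "iss_all", cell_label = seq_len(n_cells),
    global_x_um = gx + noise(n_cells), global_y_um = gy + noise(n_cells),
    area_um2 = m_iss$area_um2, perimeter_um = m_iss$perimeter_um,
    eccentricity = m_iss$eccentricity, solidity = m_iss$solidity)
  # phenotype metadata carries the systematic offset: reported coordinates
  # are true position + offset
  pheno_cells <- data.frame(
    dataset = "phenotype", fov_id = "ph_all", cell_label = seq_len(n_cells),
    global_x_um = gx + offset_um[1] + noise(n_cells),
    global_y_um = gy + offset_um[2] + noise(n_cells),
    area_um2 = m_ph$area_um2, perimeter_um = m_ph$perimeter_um,
    eccentricity = m_ph$eccentricity, solidity = m_ph$solidity)
  list(iss_cells = iss_cells, pheno_cells = pheno_cells,
       pairs = data.frame(iss_label = seq_len(n_cells),
                          pheno_label = seq_len(n_cells)))
}

#' Write a simulated screen to disk in the package's on-disk layout
#'
#' Writes each ISS FOV as a per-FOV TIFF directory ([writeImageStack()]),
#' phenotype FOVs as TIFF pairs with their `fov.json`, the codebook, and
#' the ground-truth tables (`ground_truth_cells.csv`, `ground_truth_spots.csv`,
#' `ground_truth_shifts.csv`).
#'
#' @param sim Result of [simulateScreen()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
writeScreen <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in sim$iss)
    writeImageStack(st, file.path(out_dir, "iss", st@fov@fov_id))
  for (pf in sim$phenotype) {
    d <- file.path(out_dir, "phenotype", pf$fov@fov_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(pmin(pmax(round(pf$dapi), 0), 65535) / 65535,
                    file.path(d, "dapi.tif"), bits.per.sample = 16L,
                    compression = "deflate")
    tiff::writeTIFF(pmin(pmax(round(pf$nfish), 0), 65535) / 65535,
                    file.path(d, "nfish.tif"), bits.per.sample = 16L,
                    compression = "deflate")
    writeFOVMetadata(pf$fov, file.path(d, "fov.json"))
  }
  writeCodebook(sim$config$codebook, file.path(out_dir, "codebook.csv"))
  writeResultTable(sim$truth$cells, file.path(out_dir, "ground_truth_cells.csv"))
  writeResultTable(sim$truth$spots, file.path(out_dir, "ground_truth_spots.csv"))
  writeResultTable(sim$truth$shifts, file.path(out_dir, "ground_truth_shifts.csv"))
  invisible(out_dir)
}
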