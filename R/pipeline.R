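#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with defaults; [runScreen()]
#' validates supplied configurations against this schema (unknown keys are
#' rejected) and checks stage dependencies before anything runs.
#'
#' @return Named list of class `ops_pipeline_config`.
#' @export
defaultPipelineConfig <- function() {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, segment = TRUE, decode = TRUE,
                  genotype = TRUE, phenotype = TRUE, match = TRUE,
                  stats = TRUE),
    sim = list(),
    segment = list(min_area_px = 50L, smooth_sigma_um = 0.65),
    decode = list(),
    genotype = list(read_length = 12L, quality_min = 0, max_distance = 0L),
    phenotype = list(tophat_radius_px = 5L, k_sigma = 5,
                     min_area_px = 200L, border_margin_um = 7),
    match = list(gate_um = 15, morph_threshold = 0.10, offset_gate_um = 30,
                 min_pairs = 10L),
    stats = list(min_cells = 3000L, exact_bound = 64L)
  )
  class(cfg) <- "ops_pipeline_config"
  cfg
}

# Merge user config over defaults, rejecting unknown keys at both levels.
validatePipelineConfig <- function(config) {
  def <- defaultPipelineConfig()
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (k in c("stages", "segment", "genotype", "phenotype", "match",
              "stats")) {
    bad <- setdiff(names(config[[k]]), names(def[[k]]))
    if (length(bad))
      stop(sprintf("unknown keys in '%s': %s", k, paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config)
  st <- cfg$stages
  if (st$genotype && !(st$decode && st$segment))
    stop("stage dependency violated: genotype requires decode and segment")
  if (st$decode && !st$simulate)
    stop("stage dependency violated: decode requires simulate inputs")
  if (st$match && !(st$genotype && st$phenotype))
    stop("stage dependency violated: match requires genotype and phenotype")
  if (st$stats && !st$match)
    stop("stage dependency violated: stats requires match")
  class(cfg) <- "ops_pipeline_config"
  cfg
}

#' Run the full screen pipeline
#'
#' Orchestrates simulate, segment, register+decode, genotype, phenotype,
#' match and stats in fixed order under one seed, writing every
#' intermediate table plus a run manifest (configuration, its hash,
#' package and R versions, per-stage counts) to the run directory.
#' Rerunning with the same configuration and seed reproduces the outputs.
#'
#' @param config A nested list (see [defaultPipelineConfig()]), or the path
#'   to a YAML file with the same structure.
#' @return Invisibly, a list with the run directory and the in-memory
#'   results (`sim`, `genotypes`, `phenotypes`, `matches`, `results`,
#'   `summary`).
#' @export
runScreen <- function(config = list()) {
  cfg <- validatePipelineConfig(config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("ops_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  counts <- list()

  sim_cfg <- do.call(simConfig, utils::modifyList(list(seed = cfg$seed),
                                                  cfg$sim))
  sim <- simulateScreen(sim_cfg)
  counts$n_iss_fovs <- length(sim$iss)
  counts$n_true_cells <- nrow(sim$truth$cells)

  iss_cells_tab <- NULL; all_reads <- NULL; all_genotypes <- NULL
  gt_summaries <- list()
  if (cfg$stages$decode) {
    iss_rows <- list(); read_rows <- list(); shift_rows <- list()
    for (fi in seq_along(sim$iss)) {
      st <- sim$iss[[fi]]
      nuclei <- NULL; cells <- NULL
      if (cfg$stages$segment) {
        nuclei <- segmentNuclei(st@pixels[1, 1, , ],
                                min_area_px = cfg$segment$min_area_px,
                                smooth_sigma = cfg$segment$smooth_sigma_um /
                                  st@fov@pixel_size_um)
        cells <- segmentCells(nuclei, st)
      }
      dec <- decodeFov(st, cells = cells, params = cfg$decode)
      read_rows[[fi]] <- dec$reads
      shift_rows[[fi]] <- cbind(fov_id = st@fov@fov_id, dec$shifts)
      if (cfg$stages$genotype && !is.null(cells)) {
        labs <- sort(unique(cells[cells > 0]))
        gt <- genotypeCells(dec$reads, labs, sim_cfg$codebook,
                            read_length = cfg$genotype$read_length,
                            quality_min = cfg$genotype$quality_min,
                            max_distance = cfg$genotype$max_distance)
        gt_summaries[[fi]] <- gt$summary
        g <- gt$genotypes
        morph <- measureMorphology(nuclei, st@fov)
        m <- match(g$cell_label, morph$label)
        gl <- toGlobal(cbind(morph$centroid_row_px[m],
                             morph$centroid_col_px[m]), st@fov)
        iss_rows[[fi]] <- cbind(
          data.frame(dataset = "iss", fov_id = st@fov@fov_id,
                     cell_label = g$cell_label,
                     global_x_um = gl[, 1], global_y_um = gl[, 2],
                     area_um2 = morph$area_um2[m],
                     perimeter_um = morph$perimeter_um[m],
                     eccentricity = morph$eccentricity[m],
                     solidity = morph$solidity[m]),
          g[, c("n_reads", "top_barcode", "top_count", "mapped_sgrna_id",
                "gene", "ambiguous")])
      }
    }
    all_reads <- do.call(rbind, read_rows)
    writeResultTable(all_reads, file.path(out_dir, "reads.csv"))
    writeResultTable(do.call(rbind, shift_rows),
                     file.path(out_dir, "shifts.csv"))
    counts$n_reads <- nrow(all_reads)
    if (length(iss_rows)) {
      all_genotypes <- do.call(rbind, iss_rows)
      writeResultTable(all_genotypes, file.path(out_dir, "genotypes.csv"))
      counts$n_genotyped_cells <- sum(all_genotypes$mapped_sgrna_id !=
                                        "unmapped")
    }
  }

  pheno_tab <- NULL
  if (cfg$stages$phenotype) {
    rows <- list()
    for (pi in seq_along(sim$phenotype)) {
      pf <- sim$phenotype[[pi]]
      nuc <- segmentNuclei(pf$dapi, min_area_px = cfg$phenotype$min_area_px,
                           smooth_sigma = cfg$segment$smooth_sigma_um /
                             pf$fov@pixel_size_um)
      sp <- detectNfishSpots(pf$nfish, nuc,
                             tophat_radius_px = cfg$phenotype$tophat_radius_px,
                             k_sigma = cfg$phenotype$k_sigma)
      ph <- integratedNfishIntensity(sp, nuc, fov_id = pf$fov@fov_id)
      if (!nrow(ph)) next
      morph <- measureMorphology(nuc, pf$fov)
      m <- match(ph$cell_label, morph$label)
      # drop border-clipped nuclei: their morphology cannot match the ISS view
      mg <- cfg$phenotype$border_margin_um / pf$fov@pixel_size_um
      interior <- morph$centroid_row_px[m] > mg &
        morph$centroid_row_px[m] < nrow(pf$dapi) - mg &
        morph$centroid_col_px[m] > mg &
        morph$centroid_col_px[m] < ncol(pf$dapi) - mg
      gl <- toGlobal(cbind(morph$centroid_row_px[m],
                           morph$centroid_col_px[m]), pf$fov)
      rows[[pi]] <- data.frame(
        dataset = "phenotype", fov_id = pf$fov@fov_id,
        cell_label = ph$cell_label,
        global_x_um = gl[, 1], global_y_um = gl[, 2],
        area_um2 = morph$area_um2[m], perimeter_um = morph$perimeter_um[m],
        eccentricity = morph$eccentricity[m], solidity = morph$solidity[m],
        nfish_spot_count = ph$nfish_spot_count,
        nfish_integrated_intensity = ph$nfish_integrated_intensity
      )[interior, , drop = FALSE]
    }
    pheno_tab <- do.call(rbind, rows)
    if (!is.null(pheno_tab))
      writeResultTable(pheno_tab, file.path(out_dir, "phenotypes.csv"))
    counts$n_phenotype_cells <- if (is.null(pheno_tab)) 0L else nrow(pheno_tab)
  }

  matches <- NULL; matched_cells <- NULL
  if (cfg$stages$match && !is.null(all_genotypes) && !is.null(pheno_tab)) {
    g_ok <- all_genotypes[all_genotypes$mapped_sgrna_id != "unmapped", ,
                          drop = FALSE]
    off <- estimateOffset(g_ok, pheno_tab, gate_um = cfg$match$offset_gate_um,
                          min_pairs = cfg$match$min_pairs)
    matches <- matchCells(g_ok, pheno_tab, gate_um = cfg$match$gate_um,
                          morph_threshold = cfg$match$morph_threshold,
                          offset = off)
    writeResultTable(matches, file.path(out_dir, "matches.csv"))
    acc <- matches[matches$accepted, , drop = FALSE]
    gi <- match(paste(acc$iss_fov, acc$iss_label),
                paste(g_ok$fov_id, g_ok$cell_label))
    pj <- match(paste(acc$pheno_fov, acc$pheno_label),
                paste(pheno_tab$fov_id, pheno_tab$cell_label))
    matched_cells <- data.frame(
      sgrna_id = g_ok$mapped_sgrna_id[gi], gene = g_ok$gene[gi],
      value = pheno_tab$nfish_integrated_intensity[pj])
    counts$n_matched_cells <- nrow(matched_cells)
    counts$offset_dx_um <- off$dx_um
    counts$offset_dy_um <- off$dy_um
  }

  results <- NULL
  if (cfg$stages$stats && !is.null(matched_cells) && nrow(matched_cells)) {
    ctl <- controlIds(sim_cfg$codebook)
    cbt <- codebookTable(sim_cfg$codebook)
    results <- compareSgrnas(matched_cells, ctl,
                             min_cells = cfg$stats$min_cells,
                             exact_bound = cfg$stats$exact_bound,
                             sgrna_ids = cbt$sgrna_id)
    results$gene <- cbt$gene[match(results$sgrna_id, cbt$sgrna_id)]
    writeResultTable(results, file.path(out_dir, "results.csv"))
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_plain <- unclass(cfg)
  cfg_plain$sim <- utils::modifyList(cfg_plain$sim,
                                     list(codebook = NULL))
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("opscreen")),
    r_version = R.version.string,
    seed = cfg$seed,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, sim = sim, genotypes = all_genotypes,
                 reads = all_reads, phenotypes = pheno_tab,
                 matches = matches, matched_cells = matched_cells,
                 results = results,
                 summary = gt_summaries, manifest = manifest))
}
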