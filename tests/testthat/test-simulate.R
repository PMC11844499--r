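test_that("renderSpot integrates to amplitude * 2*pi*sigma^2 and is linear", {
  img <- matrix(0, 41, 41)
  expect_identical(renderSpot(img, c(21, 21), 0, 1.5), img)
  for (s in c(1, 1.5, 2.5)) {
    out <- renderSpot(img, c(21, 21), 10, s)
    expect_equal(sum(out), 10 * 2 * pi * s^2, tolerance = 0.01)
  }
  a <- renderSpot(img, c(15, 15), 5, 1.2)
  b <- renderSpot(img, c(28, 30), 7, 1.2)
  both <- renderSpot(renderSpot(img, c(15, 15), 5, 1.2), c(28, 30), 7, 1.2)
  expect_equal(both, a + b)
  expect_error(renderSpot(img, c(0, 5), 1, 1), "outside")
})

test_that("ground truth is self-consistent and spot counts follow the mean", {
  cfg <- simConfig(seed = 21, n_fovs_iss = 2, fov_px = 220,
                   cells_per_fov = 40, render_phenotype = FALSE)
  sim <- simulateScreen(cfg)
  cells <- sim$truth$cells
  spots <- sim$truth$spots
  # every spot's barcode equals its cell's codebook barcode (no doublets)
  m <- match(spots$cell_id, cells$cell_id)
  expect_true(all(spots$barcode == cells$barcode[m]))
  # reads per cell ~ Poisson(2.5): mean within 4 SD of the sampling error
  n_per_cell <- tabulate(m, nbins = nrow(cells))
  se <- sqrt(2.5 / nrow(cells))
  expect_lt(abs(mean(n_per_cell) - 2.5), 4 * se)
  # planted shifts have cycle-1 reference at zero
  sh <- sim$truth$shifts
  expect_true(all(sh$jy_px[sh$cycle == 1] == 0))
  expect_true(all(abs(sh$jy_px) <= cfg$jitter_px_max))
})

test_that("the generator is deterministic in its seed", {
  cfg <- simConfig(seed = 4, n_fovs_iss = 1, fov_px = 80, cells_per_fov = 5,
                   phenotype_fov_px = 160)
  a <- simulateScreen(cfg)
  b <- simulateScreen(cfg)
  expect_identical(a$iss[[1]]@pixels, b$iss[[1]]@pixels)
  expect_identical(a$truth$cells, b$truth$cells)
  cfg2 <- simConfig(seed = 5, n_fovs_iss = 1, fov_px = 80, cells_per_fov = 5,
                    phenotype_fov_px = 160)
  c <- simulateScreen(cfg2)
  expect_false(identical(a$truth$spots$row_px, c$truth$spots$row_px))
})

test_that("planted phenotype effects scale the ground-truth means", {
  cfg <- simConfig(seed = 31, n_fovs_iss = 4, fov_px = 150,
                   cells_per_fov = 120, render_phenotype = FALSE,
                   reads_per_cell_mean = 0)
  sim <- simulateScreen(cfg)
  cells <- sim$truth$cells
  base <- mean(cells$nfish_true[cells$gene %in% c("CTL", "Safe")])
  for (g in c("FANCM", "BLM")) {
    eff <- unname(cfg$phenotype_effects[g])
    ratio <- mean(cells$nfish_true[cells$gene == g]) / base
    expect_lt(abs(ratio - eff) / eff, 0.25)  # ~100 cells/gene sampling error
  }
})

test_that("direct phenotype draws reproduce the configured fold changes", {
  set.seed(100)
  df <- simulatePhenotypeValues(n_per_sgrna = 4000)
  ctl <- mean(df$value[df$role != "targeting"])
  expect_equal(mean(df$value[df$gene == "FANCM"]) / ctl, 2.90,
               tolerance = 0.05)
  expect_equal(mean(df$value[df$gene == "BLM"]) / ctl, 0.80,
               tolerance = 0.05)
  expect_equal(ctl, 1144, tolerance = 0.05)
})

test_that("a zero-cell configuration yields empty outputs without error", {
  cfg <- simConfig(seed = 1, n_fovs_iss = 1, fov_px = 60, cells_per_fov = 0,
                   phenotype_fov_px = 120)
  sim <- simulateScreen(cfg)
  expect_equal(nrow(sim$truth$cells), 0L)
  expect_equal(nrow(sim$truth$spots), 0L)
  expect_equal(dim(sim$iss[[1]]@pixels), c(12L, 5L, 60L, 60L))
})

test_that("noiseless identity-crosstalk spots carry their barcode in raw argmax", {
  cfg <- simConfig(seed = 8, n_fovs_iss = 1, fov_px = 150, cells_per_fov = 8,
                   noise_sd = 0, jitter_px_max = 0, crosstalk = diag(4),
                   render_phenotype = FALSE)
  sim <- simulateScreen(cfg)
  st <- sim$iss[[1]]
  sp <- sim$truth$spots
  for (i in seq_len(nrow(sp))) {
    r <- round(sp$row_px[i]); c <- round(sp$col_px[i])
    called <- sapply(seq_len(12), function(cyc)
      SBS_BASES[which.max(st@pixels[cyc, 2:5, r, c])])
    expect_equal(paste(called, collapse = ""), sp$barcode[i])
  }
})

test_that("config invariants are enforced", {
  expect_error(simConfig(decay_per_cycle = 0), "decay")
  expect_error(simConfig(decay_per_cycle = 1.2), "decay")
  expect_error(simConfig(crosstalk = matrix(0.25, 4, 4)), "dominant")
  expect_error(simConfig(phenotype_effects = c(FANCM = -1)), "> 0")
  expect_error(simConfig(n_cycles = 20L), "barcode length")
})
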