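test_that("mean IF intensity is the plain per-region mean", {
  cells <- matrix(0L, 30, 30)
  cells[5:10, 5:10] <- 1L
  cells[20:25, 20:25] <- 2L
  uni <- matrix(7.5, 30, 30)
  m <- meanIFIntensity(cells, uni)
  expect_equal(m$mean_intensity, c(7.5, 7.5))
  img <- matrix(0, 30, 30)
  img[cells == 1L] <- 100
  img[cells == 2L] <- 70   # a 30% reduction
  m2 <- meanIFIntensity(cells, img)
  expect_equal(m2$mean_intensity, c(100, 70))
  expect_equal(nrow(meanIFIntensity(matrix(0L, 5, 5), matrix(0, 5, 5))), 0L)
})

test_that("nFISH spots are found inside nuclei and integrate their mass", {
  nuc <- matrix(0L, 80, 80)
  nuc[opscreen:::ellipseMask(80, 80, 40, 40, 25, 20)] <- 1L
  expect_equal(nrow(detectNfishSpots(matrix(0, 80, 80), nuc)), 0L)
  # one Gaussian of known above-background mass
  A <- 40; s <- 1.6
  img <- renderSpot(matrix(10, 80, 80), c(40, 42), A, s)
  sp <- detectNfishSpots(img, nuc, tophat_radius_px = 5, k_sigma = 5)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$integrated, A * 2 * pi * s^2, tolerance = 0.1)
  expect_equal(sp$nucleus_label, 1L)
  # the same spot outside any nucleus is not reported
  img2 <- renderSpot(matrix(10, 80, 80), c(5, 70), A, s)
  expect_equal(nrow(detectNfishSpots(img2, nuc)), 0L)
})

test_that("integrated intensity is additive per nucleus and zero without spots", {
  nuc <- matrix(0L, 20, 20)
  nuc[2:8, 2:8] <- 1L; nuc[12:18, 12:18] <- 2L
  spots <- data.frame(row = c(4, 6, 14), col = c(4, 6, 14),
                      nucleus_label = c(1L, 1L, 2L),
                      integrated = c(50, 70, 30))
  ph <- integratedNfishIntensity(spots, nuc)
  expect_equal(ph$nfish_integrated_intensity, c(120, 30))
  expect_equal(ph$nfish_spot_count, c(2L, 1L))
  ph0 <- integratedNfishIntensity(spots[0, ], nuc)
  expect_equal(ph0$nfish_integrated_intensity, c(0, 0))
})

test_that("integrated intensities scale linearly with the image", {
  set.seed(41)
  nuc <- matrix(0L, 60, 60)
  nuc[opscreen:::ellipseMask(60, 60, 30, 30, 22, 18)] <- 1L
  img <- matrix(5, 60, 60)
  for (i in 1:3)
    img <- renderSpot(img, c(runif(1, 20, 40), runif(1, 20, 40)), 30, 1.5)
  ph1 <- integratedNfishIntensity(detectNfishSpots(img, nuc), nuc)
  ph3 <- integratedNfishIntensity(detectNfishSpots(img * 3, nuc), nuc)
  expect_equal(ph3$nfish_integrated_intensity,
               3 * ph1$nfish_integrated_intensity, tolerance = 0.02)
})

test_that("recovered per-cell intensity tracks the planted log-normal values", {
  cfg <- simConfig(seed = 5, n_fovs_iss = 1, fov_px = 250, cells_per_fov = 30)
  sim <- simulateScreen(cfg)
  gtx <- opscreen:::cellGlobalX(sim$truth$cells, cfg)
  gty <- opscreen:::cellGlobalY(sim$truth$cells, cfg)
  rec <- c(); tru <- c()
  for (pf in sim$phenotype) {
    nuc <- segmentNuclei(pf$dapi, min_area_px = 200, smooth_sigma = 4)
    if (max(nuc) == 0) next
    ph <- integratedNfishIntensity(detectNfishSpots(pf$nfish, nuc), nuc,
                                   pf$fov@fov_id)
    mm <- measureMorphology(nuc, pf$fov)
    gl <- toGlobal(cbind(mm$centroid_row_px, mm$centroid_col_px), pf$fov)
    fp <- nrow(pf$dapi)
    interior <- mm$centroid_row_px > 40 & mm$centroid_row_px < fp - 40 &
      mm$centroid_col_px > 40 & mm$centroid_col_px < fp - 40
    for (i in which(interior)) {
      d <- sqrt((gtx - gl[i, 1])^2 + (gty - gl[i, 2])^2)
      j <- which.min(d)
      if (d[j] < 3) {
        rec <- c(rec, ph$nfish_integrated_intensity[
          match(mm$label[i], ph$cell_label)])
        tru <- c(tru, sim$truth$cells$nfish_true[j])
      }
    }
  }
  expect_gt(length(rec), 15)
  expect_gt(cor(rec, tru, method = "spearman"), 0.9)
})
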