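test_that("SD image matches analytic values and the two-loop reference", {
  # constant stack -> zero SD
  px <- array(7, dim = c(12, 5, 8, 8))
  expect_true(all(computeSDImage(SBSImageStack(px)) == 0))
  # one pixel alternating 0/1 in one channel: population SD 0.5, /4 channels
  px[, 2, 4, 4] <- rep(c(0, 1), 6)
  sd1 <- computeSDImage(SBSImageStack(px))
  expect_equal(sd1[4, 4], 0.125)
  # all four channels alternating identically -> 0.5
  for (ch in 2:5) px[, ch, 5, 5] <- rep(c(0, 1), 6)
  expect_equal(computeSDImage(SBSImageStack(px))[5, 5], 0.5)
  # random stacks vs direct two-loop oracle
  set.seed(77)
  for (i in 1:3) {
    rp <- array(runif(6 * 5 * 16 * 16, 0, 100), dim = c(6, 5, 16, 16))
    expect_equal(computeSDImage(SBSImageStack(rp)), sdTwoLoop(rp),
                 tolerance = 1e-12)
  }
  expect_error(computeSDImage(SBSImageStack(array(1, dim = c(1, 5, 4, 4)))),
               "2 cycles")
})

test_that("spot detection finds rendered peaks and nothing on flat images", {
  expect_equal(nrow(detectSpots(matrix(1, 30, 30))), 0L)
  img <- renderSpot(matrix(0, 50, 50), c(24.4, 31.2), 10, 1.5)
  sp <- detectSpots(img, threshold_abs = 1)
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt((sp$row - 24.4)^2 + (sp$col - 31.2)^2), 1.2)
  # plateau ties resolve to the smallest (row, col)
  plat <- matrix(0, 20, 20); plat[10:11, 10:11] <- 5
  sp2 <- detectSpots(plat, threshold_abs = 1, min_distance_px = 3)
  expect_equal(c(sp2$row, sp2$col), c(10L, 10L))
})

test_that("the consistency filter requires signal in every cycle", {
  # build a 12-cycle stack with one solid spot and one dropping out at cycle 6
  px <- array(0, dim = c(12, 5, 40, 40))
  for (cyc in 1:12) {
    f <- matrix(0, 40, 40)
    f <- renderSpot(f, c(12, 12), 100, 1.5)
    if (cyc != 6) f <- renderSpot(f, c(28, 28), 100, 1.5)
    px[cyc, 2, , ] <- f
  }
  st <- SBSImageStack(px, aligned = TRUE)
  spots <- data.frame(spot_id = c("a", "b"), fov_id = "f",
                      row = c(12L, 28L), col = c(12L, 28L),
                      sd_score = 1, consistent = NA, cell_label = 0L)
  out <- consistencyFilter(st, spots, k_sigma = 3)
  expect_true(out$consistent[out$spot_id == "a"])
  expect_false(out$consistent[out$spot_id == "b"])
  # k_sigma = 0 with zero background: every detected spot is consistent
  out0 <- consistencyFilter(st, spots[1, ], k_sigma = 0)
  expect_true(all(out0$consistent))
})

test_that("intensity extraction honours the aperture contract", {
  px <- array(0, dim = c(2, 5, 20, 20))
  px[1, 3, 10, 10] <- 50   # T channel centre pixel
  px[1, 3, 11, 10] <- 80   # neighbour
  st <- SBSImageStack(px, aligned = TRUE)
  sp <- data.frame(spot_id = "s", fov_id = "f", row = 10L, col = 10L,
                   sd_score = 1, consistent = TRUE, cell_label = 0L)
  r0 <- extractIntensities(st, sp, aperture_px = 0L, stat = "max",
                           subtract_background = FALSE)
  expect_equal(r0$values[1, 1, "T"], 50)
  r1 <- extractIntensities(st, sp, aperture_px = 1L, stat = "max",
                           subtract_background = FALSE)
  expect_equal(r1$values[1, 1, "T"], 80)
  expect_false(r1$clipped[1])
  # border spot flags clipping
  spb <- sp; spb$row <- 1L
  expect_true(extractIntensities(st, spb, aperture_px = 1L)$clipped[1])
  # noiseless mixed spot is proportional to the crosstalk column
  C <- defaultCrosstalk()
  px2 <- array(0, dim = c(1, 5, 9, 9))
  for (b in 1:4) px2[1, b + 1, , ] <- renderSpot(matrix(0, 9, 9), c(5, 5),
                                                 100 * C[b, 2], 1.2)
  r2 <- extractIntensities(SBSImageStack(px2, aligned = TRUE),
                           data.frame(spot_id = "s", fov_id = "f", row = 5L,
                                      col = 5L, sd_score = 1,
                                      consistent = TRUE, cell_label = 0L),
                           aperture_px = 0L, subtract_background = FALSE)
  v <- as.numeric(r2$values[1, 1, ])
  expect_equal(v / max(v), C[, 2] / max(C[, 2]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the median correction matrix recovers known mixing exactly", {
  cb <- barcodes(defaultCodebook())
  # balanced noiseless one-hot spots, identity mixing -> identity matrix
  v <- tensorFromBarcodes(rep(cb, 8))
  cm <- estimateCorrectionMatrix(asIntensities(v), 1)
  expect_false(cm$fallback_used)
  expect_equal(unname(cm$M), diag(4))
  # known mixing with 0.2 off-diagonals: medians are exact
  C <- matrix(0.2, 4, 4); diag(C) <- 1
  vC <- tensorFromBarcodes(rep(cb, 8), mixing = C)
  cmC <- estimateCorrectionMatrix(asIntensities(vC), 1)
  expect_equal(unname(cmC$M), C / rep(apply(C, 2, max), each = 4))
  # corrected vectors are one-hot again, reproducing the barcodes
  corr <- correctIntensities(asIntensities(vC), rep(list(cmC), 12))
  calls <- callBases(corr)
  expect_equal(calls$barcode[seq_along(cb)], cb)
})

test_that("per-channel rescaling leaves corrected base calls unchanged", {
  cb <- barcodes(defaultCodebook())
  set.seed(3)
  v <- tensorFromBarcodes(rep(cb, 6)) +
    array(runif(length(cb) * 6 * 12 * 4, 0, 10),
          dim = c(length(cb) * 6, 12, 4))
  base <- callBases(correctIntensities(asIntensities(v)))
  vs <- v
  vs[, , 3] <- vs[, , 3] * 2   # channel A gain doubled
  scaled <- callBases(correctIntensities(asIntensities(vs)))
  expect_equal(scaled$barcode, base$barcode)
})

test_that("base calling applies the G,T,A,C tie order and quality formula", {
  v <- array(0, dim = c(3, 1, 4))
  v[1, 1, ] <- c(4, 1, 0, 0)
  v[2, 1, ] <- c(0, 0, 5, 5)    # tie between A and C -> A (order), flagged
  v[3, 1, ] <- c(0, 0, 0, 0)
  calls <- callBases(asIntensities(v))
  expect_equal(calls$barcode, c("G", "A", "G"))
  expect_equal(calls$q1, c(0.75, 0, 0))
  expect_equal(calls$tie, c(FALSE, TRUE, TRUE))
  # all-cycle one-hot G
  g <- callBases(asIntensities(tensorFromBarcodes("GGGGGGGGGGGG")))
  expect_equal(g$barcode, "GGGGGGGGGGGG")
  expect_equal(g$spot_quality, 1)
})

test_that("spots take the cell label at their exact pixel", {
  cells <- matrix(0L, 10, 10)
  cells[3:6, 3:6] <- 1L
  cells[3:6, 7] <- 2L   # border column between cells
  sp <- data.frame(spot_id = c("a", "b", "c"), fov_id = "f",
                   row = c(4L, 4L, 9L), col = c(4L, 7L, 9L),
                   sd_score = 1, consistent = TRUE, cell_label = 0L)
  out <- assignReadsToCells(sp, cells)
  expect_equal(out$cell_label, c(1L, 2L, 0L))
})

test_that("noiseless screens decode every consistent spot exactly", {
  cfg <- simConfig(seed = 17, n_fovs_iss = 1, fov_px = 220,
                   cells_per_fov = 30, noise_sd = 0, jitter_px_max = 0,
                   crosstalk = diag(4), render_phenotype = FALSE)
  sim <- simulateScreen(cfg)
  dec <- decodeFov(sim$iss[[1]])
  expect_gt(nrow(dec$reads), 30)
  mt <- matchReadsToTruth(dec$reads, sim$truth$spots)
  expect_equal(mt$accuracy, 1)
})

test_that("genotyping accuracy rises with the spot-quality threshold", {
  cfg <- simConfig(seed = 23, n_fovs_iss = 1, fov_px = 300,
                   cells_per_fov = 80, noise_sd = 200,
                   render_phenotype = FALSE)
  sim <- simulateScreen(cfg)
  dec <- decodeFov(sim$iss[[1]])
  gt <- sim$truth$spots
  d2 <- outer(dec$reads$row, gt$row_px, "-")^2 +
    outer(dec$reads$col, gt$col_px, "-")^2
  nn <- apply(d2, 1, which.min)
  ok <- sqrt(d2[cbind(seq_len(nrow(dec$reads)), nn)]) <= 2
  correct <- dec$reads$barcode == gt$barcode[nn]
  accs <- sapply(c(0, 0.1, 0.2, 0.3), function(q) {
    sel <- ok & dec$reads$spot_quality >= q
    mean(correct[sel])
  })
  # trend check: stricter thresholds end higher, and no step dips by more
  # than one read's worth of counting noise
  expect_gte(accs[4], accs[1])
  expect_true(all(diff(accs) >= -1 / sum(ok)))
})
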