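test_that("blank images give empty labelings, not errors", {
  z <- matrix(0, 40, 40)
  expect_equal(max(segmentNuclei(z)), 0L)
  st <- SBSImageStack(array(0, dim = c(1, 5, 40, 40)))
  expect_equal(max(segmentCells(matrix(0L, 40, 40), st)), 0L)
})

test_that("well-separated disks are each found with accurate centroids", {
  img <- matrix(0, 120, 120)
  centers <- rbind(c(20, 20), c(20, 90), c(60, 55), c(100, 25), c(100, 100))
  for (i in seq_len(nrow(centers)))
    img[diskMask(120, 120, centers[i, 1], centers[i, 2], 9)] <- 500
  lab <- segmentNuclei(img, min_area_px = 30)
  expect_equal(max(lab), 5L)
  fov <- FOVMetadata("f", pixel_size_um = 1, height_px = 120, width_px = 120)
  m <- measureMorphology(lab, fov)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((m$centroid_row_px - centers[i, 1])^2 +
                (m$centroid_col_px - centers[i, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("touching disks with distinct distance maxima are split", {
  img <- matrix(0, 60, 90)
  img[diskMask(60, 90, 30, 30, 12)] <- 500
  img[diskMask(60, 90, 30, 52, 12)] <- 500
  lab <- segmentNuclei(img, min_area_px = 30)
  expect_equal(max(lab), 2L)
})

test_that("cells grow from nuclei seeds and contain them", {
  cfg <- simConfig(seed = 6, n_fovs_iss = 1, fov_px = 200,
                   cells_per_fov = 20, render_phenotype = FALSE)
  sim <- simulateScreen(cfg)
  st <- sim$iss[[1]]
  nuc <- segmentNuclei(st@pixels[1, 1, , ], smooth_sigma = 1)
  cells <- segmentCells(nuc, st)
  expect_gt(max(nuc), 0L)
  # label conservation and nucleus containment
  expect_setequal(unique(cells[cells > 0]), unique(nuc[nuc > 0]))
  expect_true(all(cells[nuc > 0] == nuc[nuc > 0]))
  # two nuclei in one connected region split along a watershed line
  surface <- apply(st@pixels[1, 2:5, , , drop = FALSE], c(3, 4), median)
  expect_true(all(table(cells[cells > 0]) > 0))
})

test_that("a flat surface with masking off degenerates to nuclei only", {
  nuc <- matrix(0L, 40, 40)
  nuc[diskMask(40, 40, 20, 20, 6)] <- 1L
  st <- SBSImageStack(array(0, dim = c(1, 5, 40, 40)))
  cells <- segmentCells(nuc, st, threshold = NA)
  expect_identical(cells, nuc)
})

test_that("morphology matches analytic shapes", {
  fov <- FOVMetadata("f", pixel_size_um = 0.65, height_px = 80,
                     width_px = 80)
  disk <- matrix(0L, 80, 80)
  disk[diskMask(80, 80, 40, 40, 20)] <- 1L
  m <- measureMorphology(disk, fov)
  expect_equal(m$area_um2, pi * 13^2, tolerance = 0.02)
  expect_equal(m$perimeter_um, 2 * pi * 13, tolerance = 0.03)
  expect_lt(m$eccentricity, 0.1)
  expect_gte(m$solidity, 0.98)
  # 2:1 ellipse
  ell <- opscreen:::ellipseMask(80, 80, 40, 40, 30, 15, 0.4) * 1L
  me <- measureMorphology(ell, fov)
  expect_equal(me$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.025)
})

test_that("morphology in micrometres is invariant to magnification", {
  for (i in 1:4) {
    a_um <- runif(1, 4, 6); ratio <- runif(1, 1.2, 1.8)
    th <- runif(1, 0, pi)
    ms <- lapply(c(0.65, 0.1625), function(ps) {
      sz <- ceiling(2 * a_um / ps + 8)
      mask <- opscreen:::ellipseMask(sz, sz, sz / 2, sz / 2, a_um / ps,
                                     a_um / ratio / ps, th) * 1L
      fov <- FOVMetadata("f", pixel_size_um = ps, height_px = sz,
                         width_px = sz)
      measureMorphology(mask, fov)
    })
    expect_equal(ms[[1]]$area_um2, ms[[2]]$area_um2, tolerance = 0.05)
    expect_equal(ms[[1]]$perimeter_um, ms[[2]]$perimeter_um,
                 tolerance = 0.05)
    expect_equal(ms[[1]]$eccentricity, ms[[2]]$eccentricity,
                 tolerance = 0.08)
    expect_equal(ms[[1]]$solidity, ms[[2]]$solidity, tolerance = 0.05)
  }
})

test_that("tiny regions are flagged degenerate", {
  lab <- matrix(0L, 10, 10)
  lab[5, 5] <- 1L
  fov <- FOVMetadata("f", pixel_size_um = 1, height_px = 10, width_px = 10)
  m <- measureMorphology(lab, fov)
  expect_true(m$degenerate)
  expect_equal(m$eccentricity, 0)
})
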