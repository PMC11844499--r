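mkReads <- function(cell, barcode, quality = 1) {
  data.frame(spot_id = paste0("s", seq_along(cell), recycle0 = TRUE),
             barcode = barcode,
             spot_quality = rep_len(quality, length(cell)), tie = rep_len(FALSE, length(cell)),
             cell_label = cell)
}

test_that("read aggregation filters, truncates and counts", {
  r <- mkReads(c(1, 1, 1, 1), c("GGTA", "GGTA", "GGTA", "ACTT"))
  agg <- aggregateReads(r, read_length = 4)
  expect_equal(agg[["1"]], c(ACTT = 1L, GGTA = 3L))
  # quality floor above everything empties the map
  expect_length(aggregateReads(r, 4, quality_min = 2), 0L)
  # read_length 1 collapses shared first bases
  agg1 <- aggregateReads(r, read_length = 1)
  expect_equal(agg1[["1"]], c(A = 1L, G = 3L))
  # unassigned reads are dropped
  r0 <- mkReads(c(0, 1), c("GG", "GG"))
  expect_equal(sum(aggregateReads(r0, 2)[["1"]]), 1L)
})

test_that("dominant barcode selection follows count-then-lexicographic order", {
  expect_equal(dominantBarcodes(c(A = 3L, B = 1L)),
               list(top = "A", top_count = 3L, second = "B",
                    second_count = 1L, ambiguous = FALSE))
  tie <- dominantBarcodes(c(B = 2L, A = 2L))
  expect_equal(tie$top, "A")
  expect_true(tie$ambiguous)
  solo <- dominantBarcodes(c(A = 5L))
  expect_equal(solo$second, NA_character_)
  expect_equal(solo$second_count, 0L)
  empty <- dominantBarcodes(integer(0))
  expect_equal(empty$top, NA_character_)
  expect_false(empty$ambiguous)
})

test_that("codebook mapping is exact at distance 0 and matches a DP oracle", {
  cb <- defaultCodebook()
  bcs <- barcodes(cb)
  ids <- codebookTable(cb)$sgrna_id
  expect_equal(mapToCodebook(bcs[3], cb), ids[3])
  # one substitution away -> unmapped at distance 0
  mut <- bcs[3]
  substr(mut, 5, 5) <- setdiff(c("G", "T", "A", "C"),
                               substr(bcs[3], 5, 5))[1]
  expect_equal(mapToCodebook(mut, cb), "unmapped")
  # distance-1 extension agrees with exhaustive DP Levenshtein
  set.seed(12)
  for (i in 1:25) {
    q <- paste(sample(c("G", "T", "A", "C"), 12, replace = TRUE),
               collapse = "")
    got <- mapToCodebook(q, cb, max_distance = 1L)
    d <- vapply(bcs, levDP, 0L, a = q)
    want <- if (min(d) <= 1 && sum(d == min(d)) == 1)
      ids[which.min(d)] else "unmapped"
    expect_equal(got, want)
  }
  # distance-0 mapping is set membership
  for (i in 1:25) {
    q <- sample(c(bcs, paste(sample(c("G", "T", "A", "C"), 12,
                                    replace = TRUE), collapse = "")), 1)
    expect_equal(mapToCodebook(q, cb) != "unmapped", q %in% bcs)
  }
})

test_that("prefix collisions at short read lengths are an error", {
  cb <- Codebook(c("a", "b"), c("GGTTAACC", "GGTTCCAA"), c("X", "Y"))
  expect_equal(mapToCodebook("GGTTA", cb, read_length = 5), "a")
  expect_error(mapToCodebook("GGTT", cb, read_length = 4),
               "ambiguous at length 4")
})

test_that("cells are genotyped with exact summary definitions", {
  cb <- defaultCodebook()
  bcs <- barcodes(cb)
  reads <- mkReads(c(1, 1, 1, 2, 2, 3),
                   c(bcs[1], bcs[1], bcs[2], bcs[5], bcs[5], "GGGGGGGGGGGG"))
  out <- genotypeCells(reads, cell_labels = 1:4, codebook = cb)
  g <- out$genotypes
  expect_equal(g$mapped_sgrna_id[g$cell_label == 1],
               codebookTable(cb)$sgrna_id[1])
  expect_equal(g$second_count[g$cell_label == 1], 1L)
  expect_equal(g$mapped_sgrna_id[g$cell_label == 3], "unmapped")
  expect_equal(g$n_reads[g$cell_label == 4], 0L)
  s <- out$summary
  expect_equal(s$fraction_cells_with_reads, 3 / 4)
  expect_equal(s$reads_per_cell_mean, 6 / 4)
  expect_equal(s$fraction_reads_mapped, 5 / 6)
})

test_that("zero-read inputs give a flagged zero summary", {
  out <- genotypeCells(mkReads(integer(0), character(0)),
                       cell_labels = 1:3, codebook = defaultCodebook())
  expect_equal(out$summary$fraction_cells_with_reads, 0)
  expect_equal(out$summary$reads_per_cell_mean, 0)
  expect_equal(out$summary$fraction_reads_mapped, 0)
  expect_true(out$summary$no_reads)
})

test_that("doublet cells surface as second barcodes or ambiguity", {
  cb <- defaultCodebook()
  bcs <- barcodes(cb)
  set.seed(5)
  # 40 singlet cells, 10 doublets with reads split between two barcodes
  cells <- list(); k <- 0L
  truth_dbl <- logical(0)
  for (i in 1:50) {
    k <- k + 1L
    dbl <- i > 40
    n <- 2 + rpois(1, 2)
    pick <- sample(14, 2)
    bc <- if (dbl) sample(bcs[pick], n, replace = TRUE)
      else rep(bcs[pick[1]], n)
    cells[[i]] <- mkReads(rep(k, n), bc)
    truth_dbl <- c(truth_dbl, dbl)
  }
  reads <- do.call(rbind, cells)
  reads$spot_id <- paste0("s", seq_len(nrow(reads)))
  g <- genotypeCells(reads, 1:50, cb)$genotypes
  flagged <- g$second_count > 0 | g$ambiguous
  expect_gt(mean(flagged[truth_dbl]), mean(flagged[!truth_dbl]))
  expect_equal(mean(flagged[!truth_dbl]), 0)
})

test_that("genotype tables are deterministic", {
  cb <- defaultCodebook()
  reads <- mkReads(c(2, 1, 2), c(barcodes(cb)[1], barcodes(cb)[2],
                                 barcodes(cb)[1]))
  a <- genotypeCells(reads, 1:2, cb)
  b <- genotypeCells(reads, 1:2, cb)
  expect_identical(a, b)
})
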