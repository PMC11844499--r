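test_that("Mann-Whitney U matches hand-derived exact cases", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  tie <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$U, 4.5)
  expect_equal(tie$p, 1)
  small <- mannWhitneyU(c(1, 2), 3)
  expect_equal(small$U, 0)
  expect_equal(small$p, 2 / 3)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("exact p equals full enumeration for every size with nx*ny <= 64", {
  set.seed(9)
  for (nx in 1:8) {
    for (ny in seq_len(min(8L, 64L %/% nx))) {
      # ties included via rounding
      x <- round(runif(nx, 0, 4))
      y <- round(runif(ny, 0, 4))
      got <- mannWhitneyU(x, y)
      want <- mwOracle(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p)
    }
  }
})

test_that("normal approximation agrees with the exact branch near the bound", {
  # at 8 vs 8 (the switchover) the continuity-corrected normal approximation
  # sits within ~0.011 of the exact discrete p in the worst case
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    pe <- mannWhitneyU(x, y, exact_bound = 64)$p
    pa <- mannWhitneyU(x, y, exact_bound = 0)$p
    expect_lt(abs(pe - pa), 0.015)
  }
})

test_that("the approximate branch reproduces wilcox.test with continuity correction", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(10:40, 1)); y <- rnorm(sample(10:40, 1))
    w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    m <- mannWhitneyU(x, y, exact_bound = 0)
    expect_equal(m$U, unname(w$statistic))
    expect_equal(m$p, w$p.value)
  }
})

test_that("screen comparisons apply Bonferroni and reporting rules", {
  set.seed(12)
  cells <- simulatePhenotypeValues(n_per_sgrna = 120)
  ctl <- controlIds(defaultCodebook())
  res <- compareSgrnas(cells, ctl, min_cells = 3000)
  expect_equal(nrow(res), 9L)           # 9 targeting sgRNAs
  expect_true(all(res$p_bonferroni >= res$p_raw))
  expect_equal(res$p_bonferroni,
               pmin(1, res$p_raw * res$n_tests))
  expect_true(all(res$low_n))           # 120 < 3000
  expect_true(all(res$n_tests == 9L))
  expect_error(compareSgrnas(cells, "not_an_id"), "no control")
  # full-roster reporting fills missing sgRNAs with NA rows
  res2 <- compareSgrnas(cells[cells$sgrna_id != "sgBLM-1", ], ctl,
                        sgrna_ids = codebookTable(defaultCodebook())$sgrna_id)
  expect_equal(nrow(res2), 9L)
  expect_true(is.na(res2$p_raw[res2$sgrna_id == "sgBLM-1"]))
  expect_equal(res2$n_tests[1], 8L)
})

test_that("planted effects at full power are detected with correct fold changes", {
  set.seed(13)
  cells <- simulatePhenotypeValues(n_per_sgrna = 3000)
  res <- compareSgrnas(cells, controlIds(defaultCodebook()))
  fancm <- res[res$gene == "FANCM", ]
  blm <- res[res$gene == "BLM", ]
  expect_true(all(abs(fancm$fold_change_vs_control - 2.90) / 2.90 < 0.1))
  expect_true(all(abs(blm$fold_change_vs_control - 0.80) / 0.80 < 0.1))
  expect_true(all(fancm$p_bonferroni < 0.05))
  expect_true(all(blm$p_bonferroni < 0.05))
  expect_false(any(res$low_n))
})

test_that("the ECDF table is the right-continuous step function", {
  e <- ecdfTable(c(1, 2, 3))
  expect_equal(e$ecdf[e$value == 2], 2 / 3)
  expect_equal(max(e$ecdf), 1)
  same <- ecdfTable(rep(4.2, 10))
  expect_equal(same$ecdf, 1)
  # sorted-rank oracle on random values
  set.seed(14)
  v <- rnorm(100)
  e2 <- ecdfTable(v)
  for (q in sample(v, 10))
    expect_equal(e2$ecdf[e2$value == q], mean(v <= q))
})
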