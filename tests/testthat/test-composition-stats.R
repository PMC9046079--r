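compTable <- function(ctrl, trt, stratum = "d1") {
  types <- names(ctrl)
  rbind(data.frame(condition = "control", stratum = stratum,
                   cell_type = types, n_cells = unname(ctrl),
                   stringsAsFactors = FALSE),
        data.frame(condition = "treated", stratum = stratum,
                   cell_type = types, n_cells = unname(trt),
                   stringsAsFactors = FALSE))
}

test_that("abundance filter gates on both conditions, inclusively", {
  ## 0.4% in treated vs 1% in control: ineligible in fraction mode
  tab <- compTable(c(paneth = 10, rest = 990), c(paneth = 4, rest = 996))
  ef <- abundanceFilter(tab)
  expect_false(ef$eligible[ef$cell_type == "paneth"])
  ## exactly 0.5% in both: eligible ('at least' is inclusive)
  tab2 <- compTable(c(paneth = 5, rest = 995), c(paneth = 5, rest = 995))
  expect_true(abundanceFilter(tab2)$eligible[1])
  ## count mode: 9 cells in one condition fails the >= 10 rule
  tab3 <- compTable(c(paneth = 9, rest = 991), c(paneth = 50, rest = 950))
  ef3 <- abundanceFilter(tab3, mode = "count")
  expect_false(ef3$eligible[ef3$cell_type == "paneth"])
  expect_match(ef3$reason[ef3$cell_type == "paneth"], "fewer than 10")
})

test_that("Fisher enrichment matches the cross-product OR and the exact test", {
  r <- fisherEnrichment(30, 70, 15, 85)
  expect_equal(r$odds_ratio, (30 * 85) / (70 * 15), tolerance = 1e-12)
  expect_equal(r$p, fisher.test(matrix(c(30, 15, 70, 85), 2))$p.value,
               tolerance = 1e-9)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  ## proportional table: independence
  r2 <- fisherEnrichment(20, 80, 10, 40)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)
  ## transposing conditions inverts the OR, p unchanged
  r3 <- fisherEnrichment(15, 85, 30, 70)
  expect_equal(r3$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  expect_equal(r3$p, r$p, tolerance = 1e-12)
  ## zero cell triggers the Haldane correction; empty margin is untested
  rz <- fisherEnrichment(0, 50, 10, 40)
  expect_true(rz$tested)
  expect_equal(rz$odds_ratio, (0.5 * 40.5) / (50.5 * 10.5), tolerance = 1e-12)
  rm <- fisherEnrichment(0, 0, 10, 40)
  expect_false(rm$tested)
  expect_match(rm$filter_reason, "margin")
})

test_that("exact p equals the independent implementation over all small tables", {
  ## exhaustive small-instance check against stats::fisher.test
  for (N in c(8L, 12L, 16L)) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
        next
      expect_equal(fisherEnrichment(a, b, cc, d)$p,
                   fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                   tolerance = 1e-9)
    }
  }
  ## and on a sample of larger tables with margins up to 30
  set.seed(10)
  for (i in 1:50) {
    x <- as.integer(sample(0:30, 4, replace = TRUE))
    if ((x[1] + x[2]) == 0 || (x[3] + x[4]) == 0 ||
        (x[1] + x[3]) == 0 || (x[2] + x[4]) == 0) next
    expect_equal(fisherEnrichment(x[1], x[2], x[3], x[4])$p,
                 fisher.test(matrix(c(x[1], x[3], x[2], x[4]), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("FDR adjustment follows BH step-up and Bonferroni with capping", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrAdjust(0.042), 0.042)
  expect_equal(fdrAdjust(c(0.01, 0.5, 1.0), method = "bonferroni"),
               c(0.03, 1.0, 1.0))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  ## monotone in sorted p and never below raw p
  set.seed(2)
  p <- runif(50)
  q <- fdrAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("Cohen's d uses the pooled SD and the standard magnitude bins", {
  same <- cohensD(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$magnitude_bin, "negligible")
  ## zero pooled SD flagged
  z <- cohensD(c(0, 0), c(1, 1))
  expect_true(is.na(z$cohens_d))
  expect_equal(z$status, "zero_pooled_sd")
  ## a shift of exactly one pooled SD gives d = 1 in the 'medium' bin
  y <- c(1, 2, 3, 4)
  sp <- sd(y)  # equal-variance groups: pooled SD = common SD
  d1 <- cohensD(y + sp, y)
  expect_equal(d1$cohens_d, 1, tolerance = 1e-12)
  expect_equal(d1$magnitude_bin, "medium")
  expect_equal(effectSizeBin(c(0.3, 0.6, 1.0, 1.5, 2.5)),
               c("negligible", "small", "medium", "large", "very large"))
})

test_that("min-max scaling maps to [0,1] and is affine invariant", {
  expect_equal(minmaxScale(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(4)
  x <- rnorm(20)
  s <- minmaxScale(x)
  expect_equal(range(s), c(0, 1))
  expect_equal(minmaxScale(3 * x - 7), s, tolerance = 1e-12)
  expect_error(minmaxScale(rep(1, 5)), "constant")
})

test_that("exceedance fraction uses the inverse-ECDF cutoff and strict exceedance", {
  r <- exceedanceFraction(c(2, 3, 3, 3, 4, 4, 4, 4, 4, 5), c(5, 6, 4, 3, 5))
  expect_equal(r$cutoff, 4)
  expect_equal(r$fraction, 3 / 5)
  expect_equal(exceedanceFraction(1:10, c(1, 2, 3))$fraction, 0)
  expect_equal(exceedanceFraction(c(3, 1, 7), c(2), percentile = 0)$cutoff, 1)
  expect_error(exceedanceFraction(integer(), 1), "nonempty")
})

test_that("timecourse enrichment reports untested strata and calibrated CIs", {
  ## ineligible types appear with tested = FALSE and a reason
  tab <- rbind(compTable(c(paneth = 2, rest = 998),
                         c(paneth = 30, rest = 970), "d1"),
               compTable(c(paneth = 200, rest = 800),
                         c(paneth = 333, rest = 667), "d2"))
  out <- enrichmentTimecourse(tab)
  expect_false(out$tested[out$cell_type == "paneth" & out$stratum == "d1"])
  expect_true(nzchar(out$filter_reason[out$cell_type == "paneth" &
                                         out$stratum == "d2"]) == FALSE)
  expect_true(out$tested[out$cell_type == "paneth" & out$stratum == "d2"])
  expect_gt(out$odds_ratio[out$cell_type == "paneth" & out$stratum == "d2"],
            1.5)

  ## coverage: the 95% CI covers a designed OR of 2 in >= 93% of replicates
  hits <- 0L
  for (s in 1:200) {
    cc <- simulateCompositionCounts(s, "d1",
      c(paneth = 0.2, rest = 0.8),
      designedOR = data.frame(cell_type = c("paneth", "rest"),
                              timepoint = "d1", or = c(2, 0.5)),
      cellsPerSample = 10000)
    res <- enrichmentTimecourse(cc$table)
    row <- res[res$cell_type == "paneth", ]
    hits <- hits + (row$ci_low <= 2 && 2 <= row$ci_high)
  }
  expect_gte(hits / 200, 0.93)
})

test_that("null composition designs keep the discovery rate controlled", {
  sig <- 0L; total <- 0L
  for (s in 1:40) {
    cc <- simulateCompositionCounts(1000 + s, c("d1", "d2"),
      c(a = 0.3, b = 0.3, c = 0.4), cellsPerSample = 3000)
    res <- enrichmentTimecourse(cc$table)
    sig <- sig + sum(res$q < 0.05, na.rm = TRUE)
    total <- total + sum(res$tested)
  }
  expect_lte(sig / total, 0.05)
})
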