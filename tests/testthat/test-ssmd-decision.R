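test_that("UMVUE factor matches an independent gamma evaluation", {
  expect_equal(umvueFactor(3), 1 / sqrt(pi), tolerance = 1e-12)
  for (n in c(3, 4, 8, 25)) {
    expect_equal(umvueFactor(n),
                 gamma((n - 1) / 2) / gamma((n - 2) / 2) * sqrt(2 / (n - 1)),
                 tolerance = 1e-12)
  }
  expect_error(umvueFactor(2), "n >= 3")
  expect_equal(kFactor(3), sqrt(1 / 3))
})

test_that("group summaries compute replicate mean/variance and flag singletons", {
  tw <- do.call(rbind, lapply(1:3, function(d) {
    w <- toyWellTable()
    w$donor <- paste0("m", d)
    w$plate <- paste0("m", d, "_P1")
    w
  }))
  ds <- ScreenDataset(tw, geometry = c(2L, 3L))
  w <- wells(ds)
  ## per donor mean fold change of the two compound wells: 0.2, 0.4, 0.6
  w$fold_change <- NA_real_
  for (d in 1:3)
    w$fold_change[w$donor == paste0("m", d) & w$role == "COMPOUND"] <-
      0.2 * d + c(-0.05, 0.05)
  g <- summarizeGroups(initialize(ds, wells = w))
  gl <- g[g$assay == "LYZ.NS", ]
  expect_equal(gl$n, 3L)
  expect_equal(gl$d_bar, 0.4, tolerance = 1e-12)
  expect_equal(gl$s2, 0.04, tolerance = 1e-12)
  ## replicate order does not matter
  w2 <- w[sample.int(nrow(w)), ]
  g2 <- summarizeGroups(initialize(ds, wells = w2))
  expect_equal(g2, g)
  ## single-replicate group flagged, not scored
  w3 <- w[w$donor == "m1", ]
  g3 <- replicateSSMD(summarizeGroups(initialize(ds, wells = w3)),
                      wI = 1, w0 = 0)
  expect_true(all(g3$status == "too_few_replicates"))
  expect_true(all(is.na(g3$ssmd)))
})

test_that("variance pooling is the per-assay median of group variances", {
  g <- data.frame(treatment_id = letters[1:3], target_annotation = "",
                  dose_uM = 1, assay = "ATP", n = 3L, d_bar = 0,
                  s2 = c(0.01, 0.04, 0.09), status = "ok")
  expect_equal(poolVariance(g)$s0_sq, 0.04)
  g$s2 <- 0.02
  expect_equal(poolVariance(g)$s0_sq, 0.02)
  g2 <- g[1:2, ]; g2$s2 <- c(0.01, 0.04)
  expect_equal(poolVariance(g2)$s0_sq, 0.025)
})

test_that("replicate SSMD matches the hand-computed UMVUE and its symmetries", {
  g <- data.frame(treatment_id = "t", target_annotation = "", dose_uM = 1,
                  assay = "LYZ.NS", n = 3L, d_bar = 0.4, s2 = 0.04,
                  status = "ok")
  p <- data.frame(assay = "LYZ.NS", s0_sq = 0.04, n_groups_pooled = 1L)
  expect_equal(replicateSSMD(g, p)$ssmd, (1 / sqrt(pi)) * 0.4 / 0.2,
               tolerance = 1e-12)
  ## zero mean difference
  g0 <- g; g0$d_bar <- 0
  expect_equal(replicateSSMD(g0, p)$ssmd, 0)
  ## antisymmetry and scale invariance
  gneg <- g; gneg$d_bar <- -g$d_bar
  expect_equal(replicateSSMD(gneg, p)$ssmd, -replicateSSMD(g, p)$ssmd)
  lam <- 3.7
  gs <- g; gs$d_bar <- g$d_bar * lam; gs$s2 <- g$s2 * lam^2
  ps <- p; ps$s0_sq <- p$s0_sq * lam^2
  expect_equal(replicateSSMD(gs, ps)$ssmd, replicateSSMD(g, p)$ssmd,
               tolerance = 1e-12)
  ## zero denominator is flagged
  gz <- g; gz$s2 <- 0
  pz <- p; pz$s0_sq <- 0
  out <- replicateSSMD(gz, pz)
  expect_true(is.na(out$ssmd))
  expect_equal(out$status, "zero_denominator")
  expect_error(replicateSSMD(g, p, wI = 0.6, w0 = 0.6), "wI \\+ w0")
})

test_that("z-scores standardize by the assay-wide sample SD of mean FCs", {
  g <- data.frame(treatment_id = letters[1:3], target_annotation = "",
                  dose_uM = 1, assay = "ATP", n = 3L,
                  d_bar = c(-1, 0, 1), s2 = 0.1, status = "ok")
  z <- foldChangeZScores(g)
  expect_equal(sd(g$d_bar), 1)  # sample (n-1) SD
  expect_equal(z$z, c(-1, 0, 1))
  ## mean FC 0.3 over population SD 0.15 gives z = 2
  g2 <- g
  g2$d_bar <- c(0.15, 0.3, 0.45)  # sample SD exactly 0.15
  z2 <- foldChangeZScores(g2)
  expect_equal(z2$z[2], 2)
  ## degenerate population flagged
  g3 <- g; g3$d_bar <- 0
  expect_true(all(foldChangeZScores(g3)$status == "zscore_undefined"))
})

test_that("FPL/FNL curves are monotone and hit the reported error level", {
  dp <- decisionParams(n = 3)
  ## central limit: beta = 0 with zero effect bound gives 0.5
  dp0 <- decisionParams(n = 3, beta2 = 0)
  expect_equal(fplCurve(0, dp0), 0.5)
  ## monotonicity
  expect_gt(fplCurve(0.5, dp), fplCurve(1.5, dp))
  expect_lt(fnlCurve(0.5, dp), fnlCurve(1.5, dp))
  ## at the anchor critical value both error levels equal 0.084
  expect_equal(fplCurve(0.997, dp), 0.084, tolerance = 1e-2)
  expect_equal(fnlCurve(0.997, dp), 0.084, tolerance = 1e-2)
  expect_lt(abs(fplCurve(0.997, dp) - fnlCurve(0.997, dp)), 5e-4)
})

test_that("optimal critical values reproduce both reference designs", {
  prim <- optimalCriticalValue(decisionParams(n = 3))
  expect_equal(round(betaAlpha1(prim), 3), 0.997)
  expect_equal(unname(achievedErrors(prim)["FPL"]), 0.084, tolerance = 1e-2)
  expect_equal(unname(achievedErrors(prim)["FPL"]),
               unname(achievedErrors(prim)["FNL"]), tolerance = 1e-6)
  val <- optimalCriticalValue(decisionParams(n = 8, fpl = 0.05,
                                             mode = "fpl_only"))
  expect_equal(betaAlpha1(val), 0.889, tolerance = 1e-3)
  expect_equal(unname(achievedErrors(val)["FPL"]), 0.05, tolerance = 1e-6)
  ## stringency is monotone in the FPL target (brute-force grid check)
  b01 <- betaAlpha1(optimalCriticalValue(decisionParams(n = 8, fpl = 0.01,
                                                        mode = "fpl_only")))
  b10 <- betaAlpha1(optimalCriticalValue(decisionParams(n = 8, fpl = 0.10,
                                                        mode = "fpl_only")))
  expect_gt(b01, b10)
  grid <- seq(0.05, 3, by = 0.05)
  fpl_grid <- fplCurve(grid, decisionParams(n = 8))
  expect_true(all(diff(fpl_grid) < 0))
  ## solver stability under bracket choice
  prim2 <- optimalCriticalValue(decisionParams(n = 3), upper = 5)
  expect_equal(betaAlpha1(prim2), betaAlpha1(prim), tolerance = 1e-5)
  ## raw-scale variant stays available and differs by exactly c_n
  raw <- optimalCriticalValue(decisionParams(n = 3, scale = "raw"))
  expect_equal(betaAlpha1(raw) * umvueFactor(3), betaAlpha1(prim),
               tolerance = 1e-5)
})

test_that("noncentral t CDF agrees with the Monte-Carlo integral oracle", {
  expect_equal(noncentralTCDF(0, 5, 0), 0.5)
  expect_equal(noncentralTCDF(500, 3, 2), 1, tolerance = 1e-6)
  set.seed(31)
  for (df in c(2L, 7L)) {
    draws <- rchisq(2e5, df)
    for (ncp in c(sqrt(3) * 0.25, sqrt(3) * 3, sqrt(8) * 0.25)) {
      for (x in c(1, 3)) {
        mc <- mcNoncentralTCDF(x, df, ncp, draws)
        expect_lt(abs(noncentralTCDF(x, df, ncp) - mc["est"]),
                  3 * mc["se"] + 1e-6)
      }
    }
  }
})

test_that("the SSMD gate achieves its designed error rates in simulation", {
  ## 10,000 replicate groups of n = 3 at the FPL design bound (true
  ## standardized effect 0.25): flag rate at the 0.997 cutoff ~ 0.084;
  ## at the FNL bound (effect 3): miss rate ~ 0.084. Unit weight on the
  ## per-group variance isolates the noncentral-t theory.
  prim <- optimalCriticalValue(decisionParams(n = 3))
  cut <- betaAlpha1(prim)
  n <- 3L
  nsim <- 10000L
  simRate <- function(beta, seed) {
    set.seed(seed)
    d_bar <- rnorm(nsim, beta, 1 / sqrt(n))
    s2 <- rchisq(nsim, n - 1) / (n - 1)
    groups <- data.frame(treatment_id = sprintf("g%05d", seq_len(nsim)),
                         target_annotation = "", dose_uM = 1,
                         assay = "LYZ.NS", n = n, d_bar = d_bar, s2 = s2,
                         status = "ok", stringsAsFactors = FALSE)
    scored <- replicateSSMD(groups, wI = 1, w0 = 0)
    mean(scored$ssmd > cut)
  }
  se <- sqrt(0.084 * (1 - 0.084) / nsim)
  expect_lt(abs(simRate(0.25, 101) - 0.084), 3 * se)
  expect_lt(abs((1 - simRate(3, 102)) - 0.084), 3 * se)
})

test_that("the UMVUE SSMD is empirically unbiased at large replication", {
  set.seed(77)
  n <- 3L
  for (beta in c(0, 1, 3)) {
    d_bar <- rnorm(1e5, beta, 1 / sqrt(n))
    s2 <- rchisq(1e5, n - 1) / (n - 1)
    groups <- data.frame(treatment_id = sprintf("g%06d", seq_len(1e5)),
                         target_annotation = "", dose_uM = 1,
                         assay = "LYZ.NS", n = n, d_bar = d_bar, s2 = s2,
                         status = "ok", stringsAsFactors = FALSE)
    scored <- replicateSSMD(groups, wI = 1, w0 = 0)
    expect_lt(abs(mean(scored$ssmd) - beta), 0.05)
  }
})
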