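test_that("log10 transform is exact and guards non-positive values", {
  tw <- toyWellTable()
  tw$raw_value <- c(1000, rep(1, nrow(tw) - 1))
  ds <- log10Transform(ScreenDataset(tw, geometry = c(2L, 3L)))
  expect_equal(wells(ds)$log10_value[1], 3)
  expect_equal(wells(ds)$log10_value[2], 0)
  expect_equal(10^wells(ds)$log10_value, wells(ds)$raw_value,
               tolerance = 1e-12)
})

test_that("LOESS correction satisfies constant identity and shift equivariance", {
  set.seed(1)
  base <- matrix(rnorm(16 * 24, 3, 0.1), 16, 24)
  ## constant plate: corrected equals input exactly
  const <- matrix(2.5, 16, 24)
  res <- loessSurfaceCorrect(PlateGrid("P", "ATP", const))
  expect_equal(gridValues(res$corrected), const, tolerance = 1e-9,
               ignore_attr = TRUE)
  ## shift equivariance: corrected(x + c) = corrected(x) + c
  r1 <- loessSurfaceCorrect(PlateGrid("P", "ATP", base))
  r2 <- loessSurfaceCorrect(PlateGrid("P", "ATP", base + 0.7))
  expect_equal(gridValues(r2$corrected), gridValues(r1$corrected) + 0.7,
               tolerance = 1e-9)
  ## invalid span
  expect_error(loessSurfaceCorrect(PlateGrid("P", "ATP", base), span = 1.5),
               "span")
})

test_that("a global linear gradient is flattened to the row-value median", {
  ## with span 1 the local quadratic fit reproduces a linear trend exactly,
  ## so every corrected value equals the median of the gradient values
  m <- matrix(rep(seq_len(16) * 0.05, 24), 16, 24)
  res <- loessSurfaceCorrect(PlateGrid("P", "LYZ.NS", m))
  expect_equal(gridValues(res$fit), m, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.vector(gridValues(res$corrected)),
               rep(median(m), length(m)), tolerance = 1e-6)
})

test_that("planted smooth artifacts are removed (variance and R2)", {
  set.seed(7)
  sigma <- 0.05
  amp <- 2 * sigma
  r <- (seq_len(16) - 8.5) / 16
  cc <- (seq_len(24) - 12.5) / 24
  surf <- outer(r, cc, function(x, y) x + 0.8 * y + 1.5 * x * y)
  surf <- (surf - mean(surf)) / sd(as.vector(surf)) * amp
  noise <- matrix(rnorm(384, 0, sigma), 16, 24)
  plate <- 3 + surf + noise
  res <- loessSurfaceCorrect(PlateGrid("P", "ATP", plate))
  corr <- gridValues(res$corrected)
  expect_lt(var(as.vector(corr - 3)), var(as.vector(plate - 3)))
  est <- gridValues(res$fit) - median(gridValues(res$fit))
  r2 <- 1 - sum((est - surf)^2) / sum((surf - mean(surf))^2)
  expect_gte(r2, 0.9)
})

test_that("masked wells receive a surface value but never influence the fit", {
  set.seed(2)
  m <- matrix(rnorm(384, 3, 0.05), 16, 24)
  masked <- m
  masked[1:2, 1:2] <- NA  # mask four wells
  res <- loessSurfaceCorrect(PlateGrid("P", "ATP", masked))
  expect_true(all(is.finite(gridValues(res$fit))))
  expect_equal(sum(is.na(gridValues(res$corrected))), 4L)
  ## end to end: wild NO_CELL values must not move other wells' correction
  cfg <- smallConfig(seed = 9, backgroundEffectSd = 0)
  sim <- simulatePrimaryScreen(cfg)
  w2 <- wells(sim$dataset)
  boost <- w2
  nc <- boost$role == "NO_CELL"
  boost$raw_value[nc] <- boost$raw_value[nc] * 1000
  n1 <- wells(normalizeScreen(sim$dataset))
  n2 <- wells(normalizeScreen(ScreenDataset(boost,
                                            geometry = geometry(sim$dataset))))
  expect_equal(n2$corrected[!nc], n1$corrected[!nc], tolerance = 1e-12)
  expect_equal(n2$fold_change[!nc], n1$fold_change[!nc], tolerance = 1e-12)
})

test_that("plate-median fold change centers included wells at zero", {
  m <- matrix(NA_real_, 2, 3)
  m[1, ] <- c(1, 2, 3); m[2, ] <- c(4, 5, NA)
  ds <- plateFromMatrix(m)
  w <- wells(ds); w$corrected <- log10(w$raw_value)
  ds <- organoidScreen::ScreenDataset(w, geometry = c(2L, 3L))
  out <- wells(plateFoldChange(ds, excludeRoles = character()))
  expect_equal(sort(out$fold_change), c(-2, -1, 0, 1, 2))
  expect_equal(median(out$fold_change), 0)
  ## a well at the plate median has fold change zero
  expect_equal(out$fold_change[out$corrected == median(out$corrected)], 0)
  ## excluding everything errors
  expect_error(plateFoldChange(ds, excludeRoles = "COMPOUND"), "excluded")
})

test_that("control-median fold change selects assay-specific control roles", {
  ## build one plate where role A and C vehicle wells differ; the LYZ.S
  ## reference must be the role-A median only
  mk <- function(role, col, vals, assay) {
    data.frame(screen_id = "v", donor = "r1", plate = "V1",
               well_row = seq_along(vals), well_col = col, role = role,
               treatment_id = ifelse(role == "COMPOUND", "cmpdX", ""),
               target_annotation = "", dose_uM = ifelse(role == "COMPOUND",
                                                        1, NA_real_),
               assay = assay, raw_value = 10^vals, stringsAsFactors = FALSE)
  }
  w <- rbind(mk("VEHICLE_A", 1, c(2.0, 2.1, 2.2), "LYZ.S"),
             mk("VEHICLE_C", 2, c(3.0, 3.1, 3.2), "LYZ.S"),
             mk("COMPOUND", 3, c(2.4, 2.5), "LYZ.S"))
  ds <- log10Transform(ScreenDataset(w, geometry = c(3L, 3L)))
  out <- wells(controlFoldChange(ds))
  cmp <- out[out$role == "COMPOUND", ]
  expect_equal(cmp$fold_change, c(2.4, 2.5) - 2.1, tolerance = 1e-12)
  ## all wells equal -> all fold changes zero
  w2 <- mk("VEHICLE_A", 1, rep(2, 3), "ATP")
  w2 <- rbind(w2, mk("COMPOUND", 2, rep(2, 3), "ATP"))
  out2 <- wells(controlFoldChange(log10Transform(
    ScreenDataset(w2, geometry = c(3L, 3L)))))
  expect_true(all(out2$fold_change == 0))
  ## missing controls is an error naming the plate/assay
  w3 <- mk("COMPOUND", 1, c(2, 2.2), "ATP")
  expect_error(controlFoldChange(log10Transform(
    ScreenDataset(w3, geometry = c(3L, 3L)))), "V1")
})

test_that("normalizeScreen recovers planted spatial artifacts end to end", {
  ## purely smooth planted surface (no edge offsets) at amplitude 2 sigma
  cfg <- smallConfig(seed = 21, spatialAmplitudeLog10 = 0.2,
                     spatialEdgeWeight = 0,
                     backgroundEffectSd = 0, hitSpec = data.frame(),
                     toxicitySpec = data.frame())
  sim <- simulatePrimaryScreen(cfg)
  norm <- normalizeScreen(sim$dataset)
  w <- wells(norm)
  offs <- sim$truth$wellOffsets
  key <- paste(w$plate, w$assay, w$well_row, w$well_col, sep = "\r")
  okey <- paste(offs$plate, offs$assay, offs$well_row, offs$well_col,
                sep = "\r")
  w$true_off <- offs$spatial_offset_log10[match(key, okey)]
  for (k in unique(paste(w$plate, w$assay, sep = "\r"))) {
    sel <- paste(w$plate, w$assay, sep = "\r") == k & w$role != "NO_CELL"
    est <- w$log10_value[sel] - w$corrected[sel]  # fitted artifact (centred)
    tru <- w$true_off[sel]
    resid_corr <- w$corrected[sel] - (w$log10_value[sel] - tru)
    ## corrected residual variance does not exceed the planted artifact's
    expect_lte(var(resid_corr), var(tru))
    r2 <- 1 - sum((est - mean(est) - (tru - mean(tru)))^2) /
      sum((tru - mean(tru))^2)
    expect_gte(r2, 0.9)
  }
})
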