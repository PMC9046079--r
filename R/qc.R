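#' Control-well separation contrasts
#'
#' Tests the five screen QC contrasts on log10 values with a two-sample
#' unequal-variance (Welch) t test: vehicle vs no-cell in ATP; stimulated
#' (C+D) vs basal (A+B) vehicle wells in LYZ.NS; stimulated (A) vs basal (B)
#' vehicle wells in LYZ.S; no-cell vs basal vehicle (A+B) in LYZ.NS; and
#' no-cell vs the compound-scheme vehicle wells (A) in LYZ.S. A contrast
#' whose well sets are missing or degenerate (fewer than 2 wells per side)
#' is marked unavailable, never fatal.
#'
#' @param dataset A \linkS4class{ScreenDataset} with \code{log10_value} (see
#'   [log10Transform()]).
#' @param test \code{"welch"} (default) or \code{"wilcoxon"}.
#' @return \code{data.frame(contrast, assay, set_x, set_y, n_x, n_y, mean_x,
#'   mean_y, statistic, p, available)}.
#' @export
controlSeparation <- function(dataset, test = c("welch", "wilcoxon")) {
  stopifnot(is(dataset, "ScreenDataset"))
  test <- match.arg(test)
  w <- wells(dataset)
  if (!"log10_value" %in% names(w))
    stopf("dataset has no log10_value column; run log10Transform() first")
  veh <- paste0("VEHICLE_", c("A", "B", "C", "D"))
  contrasts <- list(
    list(name = "vehicle_vs_no_cell_ATP", assay = "ATP",
         x = veh, y = "NO_CELL"),
    list(name = "stimAB_contrast_LYZ.NS", assay = "LYZ.NS",
         x = c("VEHICLE_C", "VEHICLE_D"), y = c("VEHICLE_A", "VEHICLE_B")),
    list(name = "A_vs_B_LYZ.S", assay = "LYZ.S",
         x = "VEHICLE_A", y = "VEHICLE_B"),
    list(name = "AB_vs_no_cell_LYZ.NS", assay = "LYZ.NS",
         x = c("VEHICLE_A", "VEHICLE_B"), y = "NO_CELL"),
    list(name = "A_vs_no_cell_LYZ.S", assay = "LYZ.S",
         x = "VEHICLE_A", y = "NO_CELL"))
  rows <- lapply(contrasts, function(cn) {
    x <- w$log10_value[w$assay == cn$assay & w$role %in% cn$x]
    y <- w$log10_value[w$assay == cn$assay & w$role %in% cn$y]
    base <- data.frame(contrast = cn$name, assay = cn$assay,
                       set_x = paste(cn$x, collapse = "+"),
                       set_y = paste(cn$y, collapse = "+"),
                       n_x = length(x), n_y = length(y),
                       mean_x = if (length(x)) mean(x) else NA_real_,
                       mean_y = if (length(y)) mean(y) else NA_real_,
                       statistic = NA_real_, p = NA_real_,
                       available = FALSE, stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L) return(base)
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      base$statistic <- 0; base$p <- 1; base$available <- TRUE
      return(base)
    }
    tt <- tryCatch(
      if (test == "welch") stats::t.test(x, y, var.equal = FALSE)
      else stats::wilcox.test(x, y, exact = FALSE),
      error = function(e) NULL)
    if (is.null(tt)) return(base)  # degenerate (e.g. both sides constant)
    base$statistic <- unname(tt$statistic)
    base$p <- tt$p.value
    base$available <- TRUE
    base
  })
  do.call(rbind, rows)
}

#' Replicate (donor-pair) Pearson correlations
#'
#' Correlates matched treatment-dose group mean fold changes between every
#' pair of donors, per assay -- the screen's replicate-agreement diagnostic.
#' Pairs with fewer than 3 matched groups are flagged unavailable.
#'
#' @param dataset A normalized \linkS4class{ScreenDataset} (with
#'   \code{fold_change}).
#' @return \code{data.frame(assay, donor_x, donor_y, r, n_matched,
#'   available)}.
#' @export
replicateCorrelation <- function(dataset) {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  if (!"fold_change" %in% names(w))
    stopf("dataset has no fold_change column; run normalizeScreen() first")
  w <- w[w$role == "COMPOUND", , drop = FALSE]
  donors <- sort(unique(w$donor))
  if (length(donors) < 2L) stopf("need >= 2 donors for replicate correlation")
  gkey <- paste(w$treatment_id, w$dose_uM, sep = "\r")
  rows <- list()
  for (a in sort(unique(w$assay))) {
    wa <- w[w$assay == a, , drop = FALSE]
    ka <- gkey[w$assay == a]
    means <- tapply(wa$fold_change, list(paste(ka), wa$donor), mean)
    for (i in seq_len(length(donors) - 1L)) {
      for (j in seq(i + 1L, length(donors))) {
        dx <- donors[i]; dy <- donors[j]
        if (!all(c(dx, dy) %in% colnames(means))) next
        ok <- stats::complete.cases(means[, c(dx, dy), drop = FALSE])
        nm <- sum(ok)
        r <- if (nm >= 3L) stats::cor(means[ok, dx], means[ok, dy]) else
          NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(assay = a, donor_x = dx, donor_y = dy, r = r,
                     n_matched = nm, available = nm >= 3L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stopf("no overlapping treatment-dose groups across donors")
  do.call(rbind, rows)
}

#' Per-plate distribution diagnostics
#'
#' Summarizes every plate x assay distribution of normalized values: mean,
#' SD, sample skewness and the fraction of wells below mean - 2 SD (the
#' low-value tail where toxic compounds accumulate). Constant plates are
#' flagged (SD 0, skewness undefined).
#'
#' @param dataset A \linkS4class{ScreenDataset}.
#' @param valueColumn Column to summarize (default \code{"fold_change"}).
#' @param minWells Minimum wells per plate x assay (default 10).
#' @return \code{data.frame(plate, assay, n, mean, sd, skewness,
#'   frac_low_tail, status)}.
#' @export
distributionSummary <- function(dataset, valueColumn = "fold_change",
                                minWells = 10L) {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  if (!valueColumn %in% names(w))
    stopf("well table has no column '%s'", valueColumn)
  key <- paste(w$plate, w$assay, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    x <- w[[valueColumn]][key == k]
    x <- x[is.finite(x)]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    if (length(x) < minWells)
      return(data.frame(plate = parts[1L], assay = parts[2L], n = length(x),
                        mean = NA_real_, sd = NA_real_, skewness = NA_real_,
                        frac_low_tail = NA_real_, status = "too_few_wells",
                        stringsAsFactors = FALSE))
    m <- mean(x); s <- stats::sd(x)
    data.frame(plate = parts[1L], assay = parts[2L], n = length(x),
               mean = m, sd = s,
               skewness = if (s > 0) sampleSkewness(x) else NA_real_,
               frac_low_tail = if (s > 0) mean(x < m - 2 * s) else NA_real_,
               status = if (s > 0) "ok" else "constant_plate",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$plate, out$assay), , drop = FALSE]
}

#' Assemble the full screen QC report
#'
#' Runs [controlSeparation()], [replicateCorrelation()] and
#' [distributionSummary()] and bundles them; purely reporting, the dataset
#' is never mutated.
#'
#' @param dataset A normalized \linkS4class{ScreenDataset}.
#' @return A \linkS4class{QCReport}.
#' @export
screenQC <- function(dataset) {
  new("QCReport",
      controlContrasts = controlSeparation(dataset),
      replicateCorrelations = replicateCorrelation(dataset),
      distributionSummaries = distributionSummary(dataset))
}
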