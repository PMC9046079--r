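#' Log10-transform raw well values
#'
#' Adds a \code{log10_value} column to the well table. All downstream
#' normalization and scoring operates on the log10 scale; fold changes are
#' differences of logs.
#'
#' @param dataset A \linkS4class{ScreenDataset}.
#' @return The dataset with a \code{log10_value} column.
#' @export
log10Transform <- function(dataset) {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  bad <- !is.finite(w$raw_value) | w$raw_value <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("log10 undefined for non-positive raw_value at plate %s row %d col %d assay %s",
          w$plate[i], w$well_row[i], w$well_col[i], w$assay[i])
  }
  w$log10_value <- log10(w$raw_value)
  initialize(dataset, wells = w)
}

#' LOESS spatial surface correction for one plate
#'
#' Fits a two-predictor local regression surface over (row, col) positions of
#' the non-masked wells (tricube weights, configurable span and polynomial
#' degree, no robustness iterations) and subtracts the centred surface:
#' \code{corrected = x - (fit - median(fit))}, where the median is taken over
#' the fitted (non-masked) wells. This removes smooth row/column/edge
#' artifacts while leaving the plate's central tendency untouched: a constant
#' plate is returned exactly unchanged, and adding a constant shifts the
#' output by exactly that constant. Masked wells receive a corrected value by
#' surface evaluation but never influence the fit.
#'
#' @param grid A \linkS4class{PlateGrid} of log10 values (masked wells
#'   \code{NA}).
#' @param span LOESS span as a fraction of points in each local fit, in
#'   (0, 1]; default 1.
#' @param degree Local polynomial degree (default 2).
#' @param family Passed to [stats::loess()]; default \code{"gaussian"} (no
#'   robustness iterations).
#' @return List of two \linkS4class{PlateGrid}s: \code{corrected} and
#'   \code{fit} (the raw surface).
#' @seealso [normalizeScreen()] for the dataset-level wrapper.
#' @export
loessSurfaceCorrect <- function(grid, span = 1, degree = 2,
                                family = "gaussian") {
  stopifnot(is(grid, "PlateGrid"))
  if (span <= 0 || span > 1) stopf("span must be in (0, 1]")
  v <- gridValues(grid)
  obs <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(obs) < (degree + 1)^2)
    stopf("plate %s/%s has too few wells (%d) for a degree-%d surface",
          grid@plateId, grid@assay, nrow(obs), degree)
  df <- data.frame(x = obs[, 1L], y = obs[, 2L], z = v[obs])
  fit <- stats::loess(z ~ x + y, data = df, span = span, degree = degree,
                      family = family, normalize = TRUE,
                      surface = "direct",
                      control = stats::loess.control(iterations = 1L))
  all_idx <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  surf <- matrix(stats::predict(fit, newdata = all_idx), nrow(v), ncol(v))
  med <- stats::median(surf[obs])
  corrected <- v - (surf - med)
  ## masked wells: evaluate the surface but the input value is NA there, so
  ## the corrected grid stays NA; callers correct masked wells via the
  ## returned fit grid on the long table (see normalizeScreen).
  list(corrected = PlateGrid(grid@plateId, grid@assay, corrected),
       fit = PlateGrid(grid@plateId, grid@assay, surf))
}

#' Plate-median fold change
#'
#' The primary-screen normalization across plates: the fold change of a well
#' is its corrected log10 value minus the median corrected value over the
#' non-excluded wells of the same plate and assay (the plate itself acting as
#' the control). By construction the median fold change over included wells
#' is exactly zero.
#'
#' @param dataset A \linkS4class{ScreenDataset} whose well table carries
#'   \code{valueColumn}.
#' @param valueColumn Column to normalize (default \code{"corrected"}).
#' @param excludeRoles Roles excluded from the median (and from a defined
#'   fold change is still computed for them); default \code{"NO_CELL"},
#'   whose background signal would bias the plate median.
#' @return The dataset with a \code{fold_change} column (log10-scale
#'   difference).
#' @export
plateFoldChange <- function(dataset, valueColumn = "corrected",
                            excludeRoles = "NO_CELL") {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  if (!valueColumn %in% names(w))
    stopf("well table has no column '%s'", valueColumn)
  key <- paste(w$plate, w$assay, sep = "\r")
  w$fold_change <- NA_real_
  for (k in unique(key)) {
    sel <- key == k
    incl <- sel & !(w$role %in% excludeRoles)
    if (!any(incl))
      stopf("all wells excluded from plate median for %s", gsub("\r", "/", k))
    med <- stats::median(w[[valueColumn]][incl], na.rm = TRUE)
    w$fold_change[sel] <- w[[valueColumn]][sel] - med
  }
  initialize(dataset, wells = w)
}

# Control-well roles eligible as the normalization reference for each assay:
# ATP uses every vehicle well; LYZ.NS uses the vehicle wells basal in the NS
# phase (roles A and B); LYZ.S uses the wells that were basal in the NS phase
# and then stimulated (role A), i.e. the wells following the compound-well
# stimulation scheme.
controlRolesForAssay <- function(assay) {
  switch(assay,
         "ATP" = paste0("VEHICLE_", c("A", "B", "C", "D")),
         "LYZ.NS" = c("VEHICLE_A", "VEHICLE_B"),
         "LYZ.S" = "VEHICLE_A",
         stopf("unknown assay '%s'", assay))
}

#' Control-median fold change (validation screen)
#'
#' The secondary-screen normalization: the fold change of a well is its log10
#' value minus the median log10 value of the eligible vehicle control wells
#' on the same plate, with assay-specific control selection (ATP: all vehicle
#' wells; LYZ.NS: vehicle wells basal in the non-stimulated phase, roles A
#' and B; LYZ.S: vehicle wells non-stimulated first and then stimulated,
#' role A). No LOESS correction is applied in this mode.
#'
#' @param dataset A \linkS4class{ScreenDataset} with a \code{log10_value}
#'   column (see [log10Transform()]).
#' @param valueColumn Column to normalize (default \code{"log10_value"}).
#' @return The dataset with a \code{fold_change} column.
#' @export
controlFoldChange <- function(dataset, valueColumn = "log10_value") {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  if (!valueColumn %in% names(w))
    stopf("well table has no column '%s'", valueColumn)
  key <- paste(w$plate, w$assay, sep = "\r")
  w$fold_change <- NA_real_
  for (k in unique(key)) {
    sel <- key == k
    assay <- w$assay[sel][1L]
    ctl <- sel & w$role %in% controlRolesForAssay(assay)
    if (!any(ctl))
      stopf("no eligible control wells for plate %s assay %s",
            w$plate[sel][1L], assay)
    med <- stats::median(w[[valueColumn]][ctl], na.rm = TRUE)
    w$fold_change[sel] <- w[[valueColumn]][sel] - med
  }
  initialize(dataset, wells = w)
}

#' Normalize a screen dataset end to end
#'
#' The dataset-level normalization stage. In \code{"plate-median"} mode
#' (primary screen): log10 transform, per plate x assay LOESS surface
#' correction (no-cell wells masked from the fit but still corrected by
#' surface evaluation), then plate-median fold change on the corrected
#' values. In \code{"control-median"} mode (validation screen): log10
#' transform followed by the vehicle-control-median fold change; no surface
#' correction.
#'
#' @param dataset A \linkS4class{ScreenDataset}.
#' @param fcMode \code{"plate-median"} or \code{"control-median"}.
#' @param span,degree LOESS parameters (plate-median mode only).
#' @param maskRoles Roles masked from the surface fit and excluded from the
#'   plate median; default \code{"NO_CELL"}.
#' @return The dataset with columns \code{log10_value, loess_fit, corrected,
#'   fold_change} added (\code{loess_fit}/\code{corrected} are \code{NA} in
#'   control-median mode, which does not fit a surface).
#' @examples
#' sim <- simulatePrimaryScreen(simulationConfig(seed = 1, donors = 2,
#'   platesPerDonor = 1, nCompounds = 20, nTargets = 10))
#' norm <- normalizeScreen(sim$dataset)
#' head(wells(norm)[, c("plate", "assay", "log10_value", "fold_change")])
#' @export
normalizeScreen <- function(dataset, fcMode = c("plate-median",
                                                "control-median"),
                            span = 1, degree = 2, maskRoles = "NO_CELL") {
  fcMode <- match.arg(fcMode)
  dataset <- log10Transform(dataset)
  if (fcMode == "control-median") {
    w <- wells(dataset)
    w$loess_fit <- NA_real_
    w$corrected <- NA_real_
    dataset <- initialize(dataset, wells = w)
    ds <- controlFoldChange(dataset, valueColumn = "log10_value")
    pv <- provenance(ds)
    pv$normalization <- list(fcMode = fcMode)
    return(initialize(ds, provenance = pv))
  }
  w <- wells(dataset)
  w$loess_fit <- NA_real_
  w$corrected <- NA_real_
  key <- paste(w$plate, w$assay, sep = "\r")
  for (k in unique(key)) {
    sel <- which(key == k)
    plateId <- w$plate[sel[1L]]
    assay <- w$assay[sel[1L]]
    grid <- pivotToGrid(dataset, plateId, assay, maskRoles = maskRoles,
                        value = "log10_value")
    res <- loessSurfaceCorrect(grid, span = span, degree = degree)
    surf <- gridValues(res$fit)
    obs <- !is.na(gridValues(grid))
    med <- stats::median(surf[obs])
    idx <- cbind(w$well_row[sel], w$well_col[sel])
    w$loess_fit[sel] <- surf[idx]
    w$corrected[sel] <- w$log10_value[sel] - (surf[idx] - med)
  }
  ds <- initialize(dataset, wells = w)
  ds <- plateFoldChange(ds, valueColumn = "corrected",
                        excludeRoles = maskRoles)
  pv <- provenance(ds)
  pv$normalization <- list(fcMode = fcMode, span = span, degree = degree,
                           maskRoles = maskRoles)
  initialize(ds, provenance = pv)
}
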