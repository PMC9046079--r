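#' Read a long-format well table from CSV
#'
#' The well-table CSV is the package's interchange format: one row per well
#' and assay, with header columns \code{screen_id, donor, plate, well_row,
#' well_col, role, treatment_id, target_annotation, dose_uM, assay,
#' raw_value}. Plate rows may be written as letters (A--P for a 384-well
#' plate) or 1-based integers; letters are mapped to indices on read.
#' Parsing is locale-independent (UTF-8, '.' decimal separator).
#'
#' @param path Path to the CSV file.
#' @param geometry Integer \code{c(rows, cols)} plate geometry; default
#'   384-well (16 x 24).
#' @return A validated \linkS4class{ScreenDataset}.
#' @seealso [writeWellTable()] for the inverse; the pair is a lossless
#'   round-trip.
#' @examples
#' sim <- simulatePrimaryScreen(simulationConfig(seed = 1, donors = 2,
#'   platesPerDonor = 1, nCompounds = 10, nTargets = 5))
#' f <- tempfile(fileext = ".csv")
#' writeWellTable(sim$dataset, f)
#' identical(wells(readWellTable(f)), wells(sim$dataset))
#' @export
readWellTable <- function(path, geometry = c(16L, 24L)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.WELL_COLUMNS, names(df))
  if (length(missing_cols))
    stopf("well table %s lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  df <- df[.WELL_COLUMNS]
  df$well_row <- rowLetterToIndex(df$well_row)
  df$well_col <- as.integer(df$well_col)
  df$dose_uM <- suppressWarnings(as.numeric(df$dose_uM))
  df$raw_value <- suppressWarnings(as.numeric(df$raw_value))
  ScreenDataset(df, geometry = geometry,
                provenance = list(source = normalizePath(path)))
}

#' Write a ScreenDataset to the well-table CSV
#'
#' Rows are ordered by (plate, row, col, assay) and plate rows are written as
#' letters, matching plate-reader export conventions.
#'
#' @param dataset A \linkS4class{ScreenDataset}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeWellTable <- function(dataset, path) {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  if (nrow(w)) {
    w <- w[order(w$plate, w$well_row, w$well_col, w$assay), , drop = FALSE]
    w$well_row <- rowIndexToLetter(w$well_row)
  }
  utils::write.csv(w, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pivot one plate and assay to a row-by-column matrix
#'
#' Produces the \linkS4class{PlateGrid} the spatial LOESS correction operates
#' on. Wells whose role is in \code{maskRoles} are set to \code{NA} (they do
#' not influence a surface fit but still occupy their position); wells absent
#' from the dataset are \code{NA} as well.
#'
#' @param dataset A \linkS4class{ScreenDataset}.
#' @param plateId Plate identifier.
#' @param assay One of [screenAssays()].
#' @param maskRoles Character vector of roles to mask (default none).
#' @param value Column of the well table to pivot (default
#'   \code{"raw_value"}; use \code{"log10_value"} after [log10Transform()]).
#' @return A \linkS4class{PlateGrid}.
#' @export
pivotToGrid <- function(dataset, plateId, assay, maskRoles = character(),
                        value = "raw_value") {
  stopifnot(is(dataset, "ScreenDataset"))
  w <- wells(dataset)
  sel <- w$plate == plateId & w$assay == assay
  if (!any(sel)) stopf("no records for plate '%s', assay '%s'", plateId, assay)
  w <- w[sel, , drop = FALSE]
  if (!value %in% names(w)) stopf("well table has no column '%s'", value)
  geom <- geometry(dataset)
  m <- matrix(NA_real_, nrow = geom[1L], ncol = geom[2L],
              dimnames = list(rowIndexToLetter(seq_len(geom[1L])),
                              seq_len(geom[2L])))
  keep <- !(w$role %in% maskRoles)
  m[cbind(w$well_row[keep], w$well_col[keep])] <- w[[value]][keep]
  PlateGrid(plateId, assay, m)
}

#' Flatten a PlateGrid back to long form
#'
#' Inverse of [pivotToGrid()] for the unmasked wells: returns one row per
#' non-missing cell with 1-based coordinates.
#'
#' @param grid A \linkS4class{PlateGrid}.
#' @return \code{data.frame} with columns \code{plate, well_row, well_col,
#'   assay, value}.
#' @export
flattenGrid <- function(grid) {
  stopifnot(is(grid, "PlateGrid"))
  v <- gridValues(grid)
  idx <- which(!is.na(v), arr.ind = TRUE)
  data.frame(plate = grid@plateId,
             well_row = as.integer(idx[, 1L]),
             well_col = as.integer(idx[, 2L]),
             assay = grid@assay,
             value = v[idx],
             stringsAsFactors = FALSE)
}
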