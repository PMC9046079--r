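#' @import methods
NULL

#' Assay names of the triplexed screen readout
#'
#' The screen measures three quantities per well: cellular ATP (viability),
#' basal (non-stimulated) lysozyme secretion \code{LYZ.NS}, and
#' carbachol-stimulated lysozyme secretion \code{LYZ.S}.
#'
#' @return Character vector of the three assay names.
#' @examples
#' screenAssays()
#' @export
screenAssays <- function() c("ATP", "LYZ.NS", "LYZ.S")

#' Well roles on a screening plate
#'
#' Compound wells carry a treatment and dose. Vehicle (DMSO) control wells are
#' labelled A--D by the order in which they are exposed to the secretagogue
#' across the two lysozyme assay phases; no-cell wells measure assay
#' background. Vehicle and no-cell roles never carry a treatment or dose.
#'
#' @return Character vector of valid role labels.
#' @examples
#' wellRoles()
#' @export
wellRoles <- function() {
  c("COMPOUND", "VEHICLE_A", "VEHICLE_B", "VEHICLE_C", "VEHICLE_D", "NO_CELL")
}

#' Vehicle roles stimulated in each lysozyme assay phase
#'
#' The four vehicle roles encode the stimulation order: role A is basal during
#' the LYZ.NS phase and stimulated during the LYZ.S phase (the same scheme a
#' compound well follows); B is basal in both phases; C is stimulated in both;
#' D is stimulated first, basal second. This is recorded here as explicit
#' metadata so control-selection rules can be reconfigured in one place.
#'
#' @param phase Either \code{"NS"} (first, non-stimulated assay phase) or
#'   \code{"S"} (second, stimulated phase).
#' @return Character vector of vehicle roles that are stimulated in the
#'   requested phase.
#' @examples
#' stimulatedRoles("NS")
#' stimulatedRoles("S")
#' @export
stimulatedRoles <- function(phase = c("NS", "S")) {
  phase <- match.arg(phase)
  if (phase == "NS") c("VEHICLE_C", "VEHICLE_D") else c("VEHICLE_A", "VEHICLE_C")
}

.WELL_COLUMNS <- c("screen_id", "donor", "plate", "well_row", "well_col",
                   "role", "treatment_id", "target_annotation", "dose_uM",
                   "assay", "raw_value")

#' ScreenDataset: a validated long-format table of well measurements
#'
#' The central container of the package. One row of \code{wells} is one assay
#' measurement of one well, with plate-position, donor, role, treatment and
#' dose metadata. Validity enforces the invariants every downstream stage
#' relies on: positive raw values (so log10 is defined), plate coordinates
#' within the geometry, a unique (plate, row, col, assay) triple per record,
#' and role/treatment consistency (exactly the compound wells carry a
#' treatment and dose).
#'
#' @slot wells \code{data.frame} with columns \code{screen_id, donor, plate,
#'   well_row, well_col, role, treatment_id, target_annotation, dose_uM,
#'   assay, raw_value}. \code{well_row}/\code{well_col} are 1-based integers.
#' @slot geometry Integer vector \code{c(rows, cols)}; default 16 x 24
#'   (384-well).
#' @slot provenance List of free-form metadata (simulation config echo, seed,
#'   analysis parameters).
#'
#' @seealso [ScreenDataset()] for construction, [readWellTable()] /
#'   [writeWellTable()] for CSV round-trips.
#' @export
setClass("ScreenDataset",
  representation(wells = "data.frame", geometry = "integer",
                 provenance = "list"),
  prototype(wells = data.frame(), geometry = c(16L, 24L), provenance = list())
)

setValidity("ScreenDataset", function(object) {
  w <- object@wells
  geom <- object@geometry
  msgs <- character()
  if (length(geom) != 2L || any(is.na(geom)) || any(geom < 1L))
    return("geometry must be two positive integers c(rows, cols)")
  missing_cols <- setdiff(.WELL_COLUMNS, names(w))
  if (length(missing_cols))
    return(paste0("missing well-table column(s): ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(w) == 0L) return(TRUE)
  if (!all(w$role %in% wellRoles()))
    msgs <- c(msgs, paste0("invalid role value(s): ",
                           paste(unique(setdiff(w$role, wellRoles())),
                                 collapse = ", ")))
  if (!all(w$assay %in% screenAssays()))
    msgs <- c(msgs, paste0("invalid assay value(s): ",
                           paste(unique(setdiff(w$assay, screenAssays())),
                                 collapse = ", ")))
  bad_row <- !is.finite(w$well_row) | w$well_row < 1L | w$well_row > geom[1L]
  bad_col <- !is.finite(w$well_col) | w$well_col < 1L | w$well_col > geom[2L]
  if (any(bad_row | bad_col))
    msgs <- c(msgs, sprintf("%d well(s) outside the %dx%d plate geometry",
                            sum(bad_row | bad_col), geom[1L], geom[2L]))
  bad_val <- !is.finite(w$raw_value) | w$raw_value <= 0
  if (any(bad_val)) {
    i <- which(bad_val)[1L]
    msgs <- c(msgs, sprintf(
      "raw_value must be positive and finite (log10 undefined); first offender plate %s row %d col %d assay %s",
      w$plate[i], w$well_row[i], w$well_col[i], w$assay[i]))
  }
  key <- paste(w$plate, w$well_row, w$well_col, w$assay, sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, sprintf("duplicate (plate, well, assay) record(s): e.g. %s",
                            gsub("\r", "/", key[duplicated(key)][1L])))
  cmp <- w$role == "COMPOUND"
  has_trt <- !is.na(w$treatment_id) & nzchar(w$treatment_id)
  has_dose <- !is.na(w$dose_uM)
  if (any(cmp & !(has_trt & has_dose)))
    msgs <- c(msgs, "COMPOUND wells must carry treatment_id and dose_uM")
  if (any(!cmp & (has_trt | has_dose)))
    msgs <- c(msgs, "control/no-cell wells must not carry treatment_id or dose_uM")
  if (any(has_dose & w$dose_uM < 0, na.rm = TRUE))
    msgs <- c(msgs, "dose_uM must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScreenDataset
#'
#' @param wells \code{data.frame} of well records; see
#'   \linkS4class{ScreenDataset} for required columns. Character-ish columns
#'   are coerced to character, coordinates to integer.
#' @param geometry Integer \code{c(rows, cols)} plate geometry.
#' @param provenance Optional list of metadata carried along the pipeline.
#' @return A validated \linkS4class{ScreenDataset}.
#' @examples
#' w <- data.frame(screen_id = "s", donor = "m1", plate = "P1",
#'                 well_row = 1L, well_col = 1L, role = "VEHICLE_A",
#'                 treatment_id = "", target_annotation = "", dose_uM = NA_real_,
#'                 assay = "ATP", raw_value = 1000)
#' ScreenDataset(w)
#' @export
ScreenDataset <- function(wells, geometry = c(16L, 24L), provenance = list()) {
  wells <- as.data.frame(wells)
  for (col in c("screen_id", "donor", "plate", "role", "treatment_id",
                "target_annotation", "assay"))
    if (col %in% names(wells)) wells[[col]] <- as.character(wells[[col]])
  for (col in c("well_row", "well_col"))
    if (col %in% names(wells)) wells[[col]] <- as.integer(wells[[col]])
  for (col in c("dose_uM", "raw_value"))
    if (col %in% names(wells)) wells[[col]] <- as.numeric(wells[[col]])
  if ("treatment_id" %in% names(wells))
    wells$treatment_id[is.na(wells$treatment_id)] <- ""
  if ("target_annotation" %in% names(wells))
    wells$target_annotation[is.na(wells$target_annotation)] <- ""
  rownames(wells) <- NULL
  new("ScreenDataset", wells = wells, geometry = as.integer(geometry),
      provenance = provenance)
}

#' PlateGrid: one plate x assay as a row-by-column matrix
#'
#' Matrix view of a single plate and assay used by the spatial LOESS
#' correction. Masked wells are \code{NA}.
#'
#' @slot plateId Plate identifier.
#' @slot assay Assay name.
#' @slot values Numeric matrix (rows x cols of the plate geometry).
#' @seealso [pivotToGrid()], [loessSurfaceCorrect()]
#' @export
setClass("PlateGrid",
  representation(plateId = "character", assay = "character",
                 values = "matrix"))

setValidity("PlateGrid", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("values must be non-empty")
  TRUE
})

#' Construct a PlateGrid
#' @param plateId Plate identifier.
#' @param assay Assay name.
#' @param values Numeric matrix of well values (NA = masked/missing).
#' @return A \linkS4class{PlateGrid}.
#' @export
PlateGrid <- function(plateId, assay, values) {
  new("PlateGrid", plateId = as.character(plateId),
      assay = as.character(assay), values = values)
}

#' DecisionParams: the SSMD decision design and its solved critical value
#'
#' Holds the replicate design (\code{n}), the SSMD effect bounds (\code{beta1}
#' for the false-negative level against at-least-strong effects, default 3;
#' \code{beta2} for the false-positive level against at-least-very-weak
#' effects, default 0.25), the target error levels, and -- after
#' [optimalCriticalValue()] -- the solved critical value \code{betaAlpha1}
#' with the achieved FPL and FNL. The derived constants \code{k = sqrt(1/n)}
#' and the UMVUE factor \code{c_n} are computed by [kFactor()] and
#' [umvueFactor()], never stored.
#'
#' @slot n Integer replicate count (>= 2).
#' @slot beta1 FNL effect bound.
#' @slot beta2 FPL effect bound.
#' @slot fpl Target false-positive level (NA when not constrained).
#' @slot fnl Target false-negative level (NA when not constrained).
#' @slot mode \code{"intersect_fpl_fnl"} or \code{"fpl_only"}.
#' @slot scale \code{"umvue"} (default; thresholds on the UMVUE SSMD scale of
#'   the replicate estimator) or \code{"raw"} (plain mean/SD scale).
#' @slot betaAlpha1 Solved critical value (NA until solved).
#' @slot achievedFPL,achievedFNL Error levels achieved at \code{betaAlpha1}.
#' @seealso [decisionParams()], [optimalCriticalValue()], [fplCurve()],
#'   [fnlCurve()]
#' @export
setClass("DecisionParams",
  representation(n = "integer", beta1 = "numeric", beta2 = "numeric",
                 fpl = "numeric", fnl = "numeric", mode = "character",
                 scale = "character", betaAlpha1 = "numeric",
                 achievedFPL = "numeric", achievedFNL = "numeric"))

setValidity("DecisionParams", function(object) {
  msgs <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
    msgs <- c(msgs, "n must be a single integer >= 2")
  if (!object@mode %in% c("intersect_fpl_fnl", "fpl_only"))
    msgs <- c(msgs, "mode must be 'intersect_fpl_fnl' or 'fpl_only'")
  if (!object@scale %in% c("umvue", "raw"))
    msgs <- c(msgs, "scale must be 'umvue' or 'raw'")
  if (object@mode == "intersect_fpl_fnl" &&
      !is.na(object@beta1) && !is.na(object@beta2) &&
      object@beta1 <= object@beta2)
    msgs <- c(msgs, "intersection mode requires beta1 > beta2")
  if (object@mode == "fpl_only" &&
      (is.na(object@fpl) || object@fpl <= 0 || object@fpl >= 1))
    msgs <- c(msgs, "fpl_only mode requires a target fpl in (0, 1)")
  if (!is.na(object@betaAlpha1) && object@betaAlpha1 <= 0)
    msgs <- c(msgs, "betaAlpha1 must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DecisionParams design
#'
#' @param n Number of replicates entering the SSMD (primary screen default 3
#'   donor replicates; validation screen uses 8 well replicates).
#' @param beta1 SSMD bound for the false-negative level ("at least strong
#'   effect"); default 3.
#' @param beta2 SSMD bound for the false-positive level ("at least very weak
#'   effect"); default 0.25.
#' @param fpl,fnl Target error levels; leave \code{NA} for the intersection
#'   mode, set \code{fpl} for \code{fpl_only}.
#' @param mode Solve for the FPL = FNL intersection (primary design) or for a
#'   fixed FPL with FNL unconstrained (validation design).
#' @param scale Scale on which \code{betaAlpha1} is reported; \code{"umvue"}
#'   matches the replicate SSMD estimator of [replicateSSMD()].
#' @return An unsolved \linkS4class{DecisionParams}.
#' @examples
#' decisionParams(n = 3)
#' decisionParams(n = 8, fpl = 0.05, mode = "fpl_only")
#' @export
decisionParams <- function(n, beta1 = 3, beta2 = 0.25, fpl = NA_real_,
                           fnl = NA_real_,
                           mode = c("intersect_fpl_fnl", "fpl_only"),
                           scale = c("umvue", "raw")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  new("DecisionParams", n = as.integer(n), beta1 = as.numeric(beta1),
      beta2 = as.numeric(beta2), fpl = as.numeric(fpl), fnl = as.numeric(fnl),
      mode = mode, scale = scale, betaAlpha1 = NA_real_,
      achievedFPL = NA_real_, achievedFNL = NA_real_)
}

#' QCReport: screen-level quality-control tables
#'
#' Pure reporting object produced by [screenQC()]; holds the control-well
#' contrast tests, donor-pair replicate correlations and per-plate
#' distribution summaries.
#'
#' @slot controlContrasts \code{data.frame}: contrast, assay, the two well
#'   sets, group means/ns, Welch t statistic and p value, availability flag.
#' @slot replicateCorrelations \code{data.frame}: assay, donor pair, Pearson
#'   r, number of matched groups, availability flag.
#' @slot distributionSummaries \code{data.frame}: plate, assay, n, mean, sd,
#'   skewness, fraction of wells below mean - 2 sd.
#' @export
setClass("QCReport",
  representation(controlContrasts = "data.frame",
                 replicateCorrelations = "data.frame",
                 distributionSummaries = "data.frame"))

setValidity("QCReport", function(object) {
  cc <- object@controlContrasts
  if (nrow(cc) && !all(c("set_x", "set_y") %in% names(cc)))
    return("every contrast must name its two well sets (set_x, set_y)")
  TRUE
})
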