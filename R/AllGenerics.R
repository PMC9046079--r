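#' Accessors for screen objects
#'
#' \code{wells()} returns the long-format well table of a
#' \linkS4class{ScreenDataset}; \code{geometry()} its plate geometry;
#' \code{provenance()} its metadata list; \code{plateIds()} the plate
#' identifiers present; \code{gridValues()} the value matrix of a
#' \linkS4class{PlateGrid}.
#'
#' @param x A \linkS4class{ScreenDataset} or \linkS4class{PlateGrid}.
#' @return \code{wells}: a \code{data.frame}; \code{geometry}: integer
#'   \code{c(rows, cols)}; \code{provenance}: a list; \code{plateIds}:
#'   character vector; \code{gridValues}: numeric matrix.
#' @name screen-accessors
#' @aliases wells geometry provenance plateIds gridValues
#' @examples
#' sim <- simulatePrimaryScreen(simulationConfig(seed = 1, donors = 2,
#'   platesPerDonor = 1, nCompounds = 20, nTargets = 10))
#' head(wells(sim$dataset))
#' geometry(sim$dataset)
#' plateIds(sim$dataset)
NULL

#' @rdname screen-accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname screen-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname screen-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname screen-accessors
#' @export
setGeneric("plateIds", function(x) standardGeneric("plateIds"))

#' @rdname screen-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname screen-accessors
#' @export
setMethod("wells", "ScreenDataset", function(x) x@wells)

#' @rdname screen-accessors
#' @export
setMethod("geometry", "ScreenDataset", function(x) x@geometry)

#' @rdname screen-accessors
#' @export
setMethod("provenance", "ScreenDataset", function(x) x@provenance)

#' @rdname screen-accessors
#' @export
setMethod("plateIds", "ScreenDataset",
          function(x) sort(unique(x@wells$plate)))

#' @rdname screen-accessors
#' @export
setMethod("gridValues", "PlateGrid", function(x) x@values)

setMethod("show", "ScreenDataset", function(object) {
  w <- object@wells
  cat("ScreenDataset:", nrow(w), "well-assay records\n")
  cat("  geometry:", object@geometry[1L], "x", object@geometry[2L], "\n")
  if (nrow(w)) {
    cat("  plates:", length(unique(w$plate)),
        " donors:", length(unique(w$donor)),
        " assays:", paste(sort(unique(w$assay)), collapse = ", "), "\n")
    cat("  roles:", paste(sprintf("%s=%d", names(table(w$role)),
                                  table(w$role)), collapse = " "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "PlateGrid", function(object) {
  v <- object@values
  cat("PlateGrid ", object@plateId, " / ", object@assay, ": ",
      nrow(v), "x", ncol(v), " (", sum(is.na(v)), " masked)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "DecisionParams", function(object) {
  cat("DecisionParams (", object@mode, ", ", object@scale, " scale)\n",
      sep = "")
  cat("  n =", object@n, " beta1 =", object@beta1, " beta2 =", object@beta2,
      "\n")
  if (!is.na(object@betaAlpha1)) {
    cat(sprintf("  betaAlpha1 = %.6f (FPL %.4f, FNL %.4f)\n",
                object@betaAlpha1, object@achievedFPL, object@achievedFNL))
  } else {
    cat("  betaAlpha1: not yet solved\n")
  }
  invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", nrow(object@controlContrasts), "control contrasts,",
      nrow(object@replicateCorrelations), "replicate correlations,",
      nrow(object@distributionSummaries), "plate distributions\n")
  invisible(NULL)
})

#' Extract QC tables from a QCReport
#'
#' @param x A \linkS4class{QCReport}.
#' @return A \code{data.frame} (see \linkS4class{QCReport} slot docs).
#' @name qc-accessors
#' @aliases controlContrasts replicateCorrelations distributionSummaries
NULL

#' @rdname qc-accessors
#' @export
setGeneric("controlContrasts", function(x) standardGeneric("controlContrasts"))

#' @rdname qc-accessors
#' @export
setGeneric("replicateCorrelations",
           function(x) standardGeneric("replicateCorrelations"))

#' @rdname qc-accessors
#' @export
setGeneric("distributionSummaries",
           function(x) standardGeneric("distributionSummaries"))

#' @rdname qc-accessors
#' @export
setMethod("controlContrasts", "QCReport", function(x) x@controlContrasts)

#' @rdname qc-accessors
#' @export
setMethod("replicateCorrelations", "QCReport",
          function(x) x@replicateCorrelations)

#' @rdname qc-accessors
#' @export
setMethod("distributionSummaries", "QCReport",
          function(x) x@distributionSummaries)

#' Solved critical value and achieved error levels
#'
#' @param x A solved \linkS4class{DecisionParams} (see
#'   [optimalCriticalValue()]).
#' @return \code{betaAlpha1}: the critical value; \code{achievedErrors}: named
#'   numeric \code{c(FPL = , FNL = )}.
#' @name decision-accessors
#' @aliases betaAlpha1 achievedErrors
NULL

#' @rdname decision-accessors
#' @export
setGeneric("betaAlpha1", function(x) standardGeneric("betaAlpha1"))

#' @rdname decision-accessors
#' @export
setGeneric("achievedErrors", function(x) standardGeneric("achievedErrors"))

#' @rdname decision-accessors
#' @export
setMethod("betaAlpha1", "DecisionParams", function(x) x@betaAlpha1)

#' @rdname decision-accessors
#' @export
setMethod("achievedErrors", "DecisionParams",
          function(x) c(FPL = x@achievedFPL, FNL = x@achievedFNL))
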