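# Stage wrapper: any failure is re-raised with the stage name so pipeline
# errors are attributable.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage %s] %s", name, conditionMessage(e)))
}

.resolveInput <- function(input, geometry) {
  if (is(input, "ScreenDataset")) return(list(dataset = input, truth = NULL))
  if (inherits(input, "simulationConfig"))
    return(simulatePrimaryScreen(input))
  if (is.character(input) && length(input) == 1L)
    return(list(dataset = readWellTable(input, geometry = geometry),
                truth = NULL))
  stopf("input must be a ScreenDataset, simulationConfig, or CSV path")
}

.writeArtifacts <- function(outDir, tables, jsons) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(outDir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  for (nm in names(jsons)) {
    p <- file.path(outDir, paste0(nm, ".json"))
    jsonlite::write_json(jsons[[nm]], p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths[nm] <- p
  }
  paths
}

.provenance <- function(paths, params) {
  list(package = "organoidScreen",
       version = as.character(utils::packageVersion("organoidScreen")),
       r_version = R.version.string,
       parameters = params,
       file_md5 = as.list(tools::md5sum(unname(paths))))
}

#' Run the complete primary-screen analysis
#'
#' End-to-end orchestration: load (or simulate) the well table, normalize
#' (log10, LOESS surface correction, plate-median fold change), score
#' (replicate SSMD with pooled variance, fold-change z-scores), solve the
#' decision design (FPL/FNL intersection), call dual-assay hits, pick the
#' optimal dose per hit treatment, deduplicate by annotated target, and run
#' screen QC. If \code{outDir} is given, every table is written as CSV and
#' the decision parameters and a provenance record (parameter echo, package
#' and R versions, MD5 of every artifact) as JSON. Re-running with an
#' identical input and parameters reproduces identical outputs.
#'
#' @param input A \linkS4class{ScreenDataset}, a [simulationConfig()] (the
#'   screen is simulated), or a well-table CSV path.
#' @param outDir Output directory, or \code{NULL} to skip writing.
#' @param span,degree LOESS parameters.
#' @param wI,w0 SSMD denominator weights.
#' @param beta1,beta2 Decision effect bounds (defaults 3 and 0.25).
#' @param zCut Refinement z cutoff (default 1.282).
#' @param replicateUnit Replicate unit for grouping (default donor).
#' @param geometry Plate geometry when reading from CSV.
#' @return Invisibly, a list: \code{dataset} (normalized), \code{scores},
#'   \code{decision} (\linkS4class{DecisionParams}), \code{hits},
#'   \code{optimalDoses}, \code{targetHits}, \code{qc}, \code{truth}
#'   (when simulated), \code{paths} (when written).
#' @examples
#' res <- runPrimaryAnalysis(simulationConfig(seed = 1, donors = 3,
#'   platesPerDonor = 1, nCompounds = 30, nTargets = 15))
#' res$decision
#' head(res$hits[res$hits$is_hit, ])
#' @export
runPrimaryAnalysis <- function(input, outDir = NULL, span = 1, degree = 2,
                               wI = 0.5, w0 = 0.5, beta1 = 3, beta2 = 0.25,
                               zCut = zGateCutoff(),
                               replicateUnit = "donor",
                               geometry = c(16L, 24L)) {
  loaded <- .stage("load", .resolveInput(input, geometry))
  norm <- .stage("normalize",
                 normalizeScreen(loaded$dataset, fcMode = "plate-median",
                                 span = span, degree = degree))
  scores <- .stage("score", scoreScreen(norm, replicateUnit = replicateUnit,
                                        wI = wI, w0 = w0))
  nRep <- as.integer(names(sort(table(scores$n[scores$status == "ok"]),
                                decreasing = TRUE))[1L])
  decision <- .stage("critical-value",
                     optimalCriticalValue(decisionParams(
                       n = nRep, beta1 = beta1, beta2 = beta2)))
  hits <- .stage("call-hits",
                 callPrimaryHits(scores, betaAlpha1 = betaAlpha1(decision),
                                 zCut = zCut))
  optimal <- .stage("optimal-dose",
                    selectOptimalDose(hits, scores, rank = "min-ssmd",
                                      hitColumn = "is_refined_hit"))
  targetHits <- .stage("dedupe-target", dedupeByTarget(optimal))
  qc <- .stage("qc", screenQC(norm))
  result <- list(dataset = norm, scores = scores, decision = decision,
                 hits = hits, optimalDoses = optimal,
                 targetHits = targetHits, qc = qc, truth = loaded$truth)
  if (!is.null(outDir)) {
    params <- list(mode = "primary", span = span, degree = degree, wI = wI,
                   w0 = w0, beta1 = beta1, beta2 = beta2, zCut = zCut,
                   replicateUnit = replicateUnit, n = nRep)
    tables <- list(normalized_wells = wells(norm), scores = scores,
                   hits = hits, optimal_doses = optimal,
                   target_hits = targetHits,
                   qc_control_contrasts = controlContrasts(qc),
                   qc_replicate_correlations = replicateCorrelations(qc),
                   qc_distributions = distributionSummaries(qc))
    jsons <- list(decision_params = list(
      n = decision@n, beta1 = decision@beta1, beta2 = decision@beta2,
      mode = decision@mode, scale = decision@scale,
      beta_alpha1 = betaAlpha1(decision),
      achieved_fpl = decision@achievedFPL,
      achieved_fnl = decision@achievedFNL))
    paths <- .stage("write", .writeArtifacts(outDir, tables, jsons))
    prov_path <- file.path(outDir, "provenance.json")
    jsonlite::write_json(.provenance(paths, params), prov_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$paths <- c(paths, provenance = prov_path)
  }
  invisible(result)
}

#' Run the complete validation-screen analysis
#'
#' As [runPrimaryAnalysis()] for the confirmatory screen: control-median
#' fold change (no LOESS), well-level replicates (n = 8 by default), the
#' FPL-only critical value (0.889 at n = 8, FPL 0.05), no z gate, and
#' mean-fold-change optimal-dose ranking.
#'
#' @param input A \linkS4class{ScreenDataset}, a [simulationConfig()]
#'   (requires \code{primaryHits}), or a CSV path.
#' @param primaryHits \code{data.frame(treatment_id, optimal_dose_uM)} of
#'   primary hits; required (and must be nonempty) when simulating, used for
#'   provenance otherwise.
#' @param outDir Output directory or \code{NULL}.
#' @param fpl Target false-positive level (default 0.05).
#' @param beta2 FPL effect bound (default 0.25).
#' @param wI,w0 SSMD denominator weights.
#' @param geometry Plate geometry when reading from CSV.
#' @return Invisibly, a list as [runPrimaryAnalysis()] (no z gate; dose
#'   ranking by mean LYZ fold change).
#' @export
runValidationAnalysis <- function(input, primaryHits = NULL, outDir = NULL,
                                  fpl = 0.05, beta2 = 0.25, wI = 0.5,
                                  w0 = 0.5, geometry = c(16L, 24L)) {
  loaded <- .stage("load", {
    if (inherits(input, "simulationConfig")) {
      if (is.null(primaryHits) || !nrow(primaryHits))
        stopf("primaryHits must be a nonempty data.frame when simulating")
      simulateValidationScreen(input, primaryHits)
    } else .resolveInput(input, geometry)
  })
  norm <- .stage("normalize",
                 normalizeScreen(loaded$dataset, fcMode = "control-median"))
  scores <- .stage("score", scoreScreen(norm, replicateUnit = "well",
                                        wI = wI, w0 = w0))
  nRep <- as.integer(names(sort(table(scores$n[scores$status == "ok"]),
                                decreasing = TRUE))[1L])
  decision <- .stage("critical-value",
                     optimalCriticalValue(decisionParams(
                       n = nRep, beta2 = beta2, fpl = fpl,
                       mode = "fpl_only")))
  hits <- .stage("call-hits",
                 callValidationHits(scores,
                                    betaAlpha1 = betaAlpha1(decision)))
  optimal <- .stage("optimal-dose",
                    selectOptimalDose(hits, scores, rank = "mean-fc",
                                      hitColumn = "is_hit"))
  qc <- .stage("qc", screenQC(norm))
  result <- list(dataset = norm, scores = scores, decision = decision,
                 hits = hits, optimalDoses = optimal, qc = qc,
                 truth = loaded$truth)
  if (!is.null(outDir)) {
    params <- list(mode = "validation", fpl = fpl, beta2 = beta2, wI = wI,
                   w0 = w0, n = nRep)
    tables <- list(normalized_wells = wells(norm), scores = scores,
                   hits = hits, optimal_doses = optimal,
                   qc_control_contrasts = controlContrasts(qc),
                   qc_replicate_correlations = replicateCorrelations(qc),
                   qc_distributions = distributionSummaries(qc))
    jsons <- list(decision_params = list(
      n = decision@n, beta2 = decision@beta2, fpl = decision@fpl,
      mode = decision@mode, scale = decision@scale,
      beta_alpha1 = betaAlpha1(decision),
      achieved_fpl = decision@achievedFPL,
      achieved_fnl = decision@achievedFNL))
    paths <- .stage("write", .writeArtifacts(outDir, tables, jsons))
    prov_path <- file.path(outDir, "provenance.json")
    jsonlite::write_json(.provenance(paths, params), prov_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$paths <- c(paths, provenance = prov_path)
  }
  invisible(result)
}
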