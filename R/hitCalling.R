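#' Call primary-screen hits from scored groups
#'
#' A primary hit is a treatment-dose whose replicate SSMD strictly exceeds
#' the optimal critical value in BOTH lysozyme assays (basal LYZ.NS and
#' stimulated LYZ.S), without regard to viability -- ATP never gates by
#' default, though its scores are always carried along. A refined hit
#' additionally sits in the top 10% of fold changes in both LYZ assays
#' (z strictly greater than \code{zCut}, default 1.282). Groups missing one
#' of the required assays are flagged incomplete rather than judged.
#'
#' @param scores Score table from [scoreScreen()].
#' @param betaAlpha1 SSMD critical value (solve with
#'   [optimalCriticalValue()]; the primary design gives 0.997).
#' @param zCut z-score cutoff for the refinement gate (default
#'   \code{zGateCutoff()} = 1.282).
#' @param assaysRequired Assays that must pass the gates (default the two
#'   LYZ assays).
#' @return \code{data.frame(treatment_id, target_annotation, dose_uM,
#'   passes_ssmd_LYZ.NS, passes_ssmd_LYZ.S, passes_z_LYZ.NS,
#'   passes_z_LYZ.S, is_hit, is_refined_hit, potency_score, status)}:
#'   \code{potency_score} is the conservative min over the required-assay
#'   SSMDs, the ranking used for optimal-dose selection.
#' @export
callPrimaryHits <- function(scores, betaAlpha1, zCut = zGateCutoff(),
                            assaysRequired = c("LYZ.NS", "LYZ.S")) {
  if (zCut <= 0) stopf("zCut must be > 0")
  .callHits(scores, betaAlpha1, zCut = zCut, assaysRequired = assaysRequired,
            useZGate = TRUE)
}

#' Call validation-screen hits
#'
#' As [callPrimaryHits()] but with the validation design's FPL-only critical
#' value (0.889 for n = 8, FPL 0.05) and no z gate: a primary hit is
#' validated when its SSMD strictly exceeds the critical value in both LYZ
#' assays.
#'
#' @inheritParams callPrimaryHits
#' @return As [callPrimaryHits()] (\code{is_refined_hit} equals
#'   \code{is_hit} since no z gate applies).
#' @export
callValidationHits <- function(scores, betaAlpha1,
                               assaysRequired = c("LYZ.NS", "LYZ.S")) {
  .callHits(scores, betaAlpha1, zCut = NA_real_,
            assaysRequired = assaysRequired, useZGate = FALSE)
}

.callHits <- function(scores, betaAlpha1, zCut, assaysRequired, useZGate) {
  if (!is.finite(betaAlpha1) || betaAlpha1 <= 0)
    stopf("betaAlpha1 must be a positive number (got %s)", betaAlpha1)
  need <- c("treatment_id", "dose_uM", "assay", "ssmd")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols))
    stopf("score table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (useZGate && !"z" %in% names(scores))
    stopf("score table lacks z column required for the refinement gate")
  key <- paste(scores$treatment_id, scores$dose_uM, sep = "\r")
  ukey <- unique(key)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  out <- data.frame(treatment_id = parts[, 1L],
                    dose_uM = as.numeric(parts[, 2L]),
                    stringsAsFactors = FALSE)
  if ("target_annotation" %in% names(scores))
    out$target_annotation <-
      scores$target_annotation[match(out$treatment_id, scores$treatment_id)]
  else out$target_annotation <- ""
  for (a in assaysRequired) {
    m <- match(paste(ukey, a, sep = "\r"), paste(key, scores$assay, sep = "\r"))
    out[[paste0("ssmd_", a)]] <- scores$ssmd[m]
    out[[paste0("passes_ssmd_", a)]] <-
      !is.na(scores$ssmd[m]) & scores$ssmd[m] > betaAlpha1
    if (useZGate) {
      out[[paste0("z_", a)]] <- scores$z[m]
      out[[paste0("passes_z_", a)]] <-
        !is.na(scores$z[m]) & scores$z[m] > zCut
    }
  }
  ssmd_cols <- paste0("ssmd_", assaysRequired)
  complete <- !Reduce(`|`, lapply(ssmd_cols, function(cc) is.na(out[[cc]])))
  out$status <- ifelse(complete, "ok", "incomplete")
  pass_ssmd <- Reduce(`&`, lapply(paste0("passes_ssmd_", assaysRequired),
                                  function(cc) out[[cc]]))
  out$is_hit <- complete & pass_ssmd
  if (useZGate) {
    pass_z <- Reduce(`&`, lapply(paste0("passes_z_", assaysRequired),
                                 function(cc) out[[cc]]))
    out$is_refined_hit <- out$is_hit & pass_z
  } else {
    out$is_refined_hit <- out$is_hit
  }
  out$potency_score <- do.call(pmin, c(lapply(ssmd_cols,
                                              function(cc) out[[cc]]),
                                       list(na.rm = FALSE)))
  out <- out[order(out$treatment_id, out$dose_uM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the optimal dose per hit treatment
#'
#' Among a treatment's hit doses, ranks doses either by the conservative
#' minimum of the two LYZ SSMDs (\code{"min-ssmd"}, the primary-screen rule)
#' or by the mean of the two LYZ mean fold changes (\code{"mean-fc"}, the
#' validation rule: the most potent dose relative to control). Exact ties
#' break toward the lower dose.
#'
#' @param hits Hit table from [callPrimaryHits()] / [callValidationHits()].
#' @param scores Score table (needed for \code{"mean-fc"} ranking).
#' @param rank \code{"min-ssmd"} or \code{"mean-fc"}.
#' @param hitColumn Which flag defines eligible doses (default
#'   \code{"is_hit"}).
#' @return One row per treatment with a hit: \code{treatment_id,
#'   target_annotation, dose_uM, potency_score}.
#' @export
selectOptimalDose <- function(hits, scores = NULL,
                              rank = c("min-ssmd", "mean-fc"),
                              hitColumn = "is_hit") {
  rank <- match.arg(rank)
  h <- hits[hits[[hitColumn]], , drop = FALSE]
  if (!nrow(h))
    return(data.frame(treatment_id = character(), target_annotation =
                        character(), dose_uM = numeric(),
                      potency_score = numeric(), stringsAsFactors = FALSE))
  if (rank == "mean-fc") {
    if (is.null(scores)) stopf("scores are required for mean-fc ranking")
    sk <- paste(scores$treatment_id, scores$dose_uM, scores$assay, sep = "\r")
    fc <- function(a) scores$d_bar[match(paste(h$treatment_id, h$dose_uM, a,
                                               sep = "\r"), sk)]
    h$potency_score <- (fc("LYZ.NS") + fc("LYZ.S")) / 2
  }
  picked <- lapply(split(h, h$treatment_id), function(d) {
    best <- max(d$potency_score)
    cand <- d[d$potency_score == best, , drop = FALSE]
    cand[which.min(cand$dose_uM), , drop = FALSE]
  })
  out <- do.call(rbind, picked)[, c("treatment_id", "target_annotation",
                                    "dose_uM", "potency_score")]
  out <- out[order(out$treatment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicate hits by annotated target
#'
#' For annotated targets with more than one hit treatment, keeps the most
#' potent treatment-dose (same potency ranking as the dose selection in
#' force); exact ties break deterministically by lexicographic treatment id.
#'
#' @param hits One-row-per-treatment table (e.g. [selectOptimalDose()]
#'   output) with a \code{potency_score} column.
#' @param annotation Named character vector mapping treatment_id to target;
#'   if \code{NULL}, the \code{target_annotation} column is used. Every hit
#'   treatment must be annotated.
#' @return One row per target.
#' @export
dedupeByTarget <- function(hits, annotation = NULL) {
  if (!nrow(hits)) return(hits)
  tgt <- if (is.null(annotation)) hits$target_annotation
         else unname(annotation[hits$treatment_id])
  missing_ann <- is.na(tgt) | !nzchar(tgt)
  if (any(missing_ann))
    stopf("missing target annotation for treatment(s): %s",
          paste(hits$treatment_id[missing_ann], collapse = ", "))
  hits$.target <- tgt
  picked <- lapply(split(hits, hits$.target), function(d) {
    d <- d[order(-d$potency_score, d$treatment_id), , drop = FALSE]
    d[1L, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out$.target <- NULL
  out <- out[order(out$treatment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
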