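#' UMVUE correction factor for the replicate SSMD
#'
#' The robust replicate SSMD estimator multiplies the mean-over-SD ratio by
#' \code{c_n = Gamma((n-1)/2) / Gamma((n-2)/2) * sqrt(2/(n-1))}, which makes
#' the estimate of the standardized mean difference exactly unbiased under
#' normality. Requires \code{n >= 3} (the factor degenerates to 0 at
#' \code{n = 2}).
#'
#' @param n Number of replicates.
#' @return The scalar factor \code{c_n}.
#' @examples
#' umvueFactor(3)  # 1/sqrt(pi)
#' @export
umvueFactor <- function(n) {
  n <- as.integer(n)
  if (any(n < 3L)) stopf("UMVUE factor requires n >= 3")
  exp(lgamma((n - 1) / 2) - lgamma((n - 2) / 2)) * sqrt(2 / (n - 1))
}

#' @rdname umvueFactor
#' @details \code{kFactor(n)} returns \code{sqrt(1/n)}, the standard error
#'   factor linking the mean/SD scale to the replicate design.
#' @export
kFactor <- function(n) sqrt(1 / as.integer(n))

#' Summarize replicate fold changes per treatment-dose-assay group
#'
#' Collapses normalized well fold changes to one summary per
#' (treatment, dose, assay) group: the replicate count \code{n}, the mean
#' \code{d_bar} and the sample variance \code{s2} of the per-replicate fold
#' changes. The replicate unit is the donor for the primary screen (each
#' donor contributes one fold change; wells from the same donor are averaged
#' first) or the well for the validation screen (8 well replicates). Groups
#' with fewer than 2 replicates are flagged \code{"too_few_replicates"} and
#' excluded from scoring, never silently dropped.
#'
#' @param dataset A normalized \linkS4class{ScreenDataset} (with
#'   \code{fold_change}).
#' @param replicateUnit \code{"donor"} or \code{"well"}.
#' @return \code{data.frame(treatment_id, target_annotation, dose_uM, assay,
#'   n, d_bar, s2, status)}.
#' @export
summarizeGroups <- function(dataset, replicateUnit = c("donor", "well")) {
  stopifnot(is(dataset, "ScreenDataset"))
  replicateUnit <- match.arg(replicateUnit)
  w <- wells(dataset)
  if (!"fold_change" %in% names(w))
    stopf("dataset has no fold_change column; run normalizeScreen() first")
  w <- w[w$role == "COMPOUND" & !is.na(w$fold_change), , drop = FALSE]
  if (!nrow(w)) stopf("no compound wells with fold changes")
  if (replicateUnit == "donor") {
    rep_key <- paste(w$treatment_id, w$dose_uM, w$assay, w$donor, sep = "\r")
    agg <- stats::aggregate(w$fold_change, by = list(key = rep_key), FUN = mean)
    parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
    reps <- data.frame(treatment_id = parts[, 1L],
                       dose_uM = as.numeric(parts[, 2L]),
                       assay = parts[, 3L], fc = agg$x,
                       stringsAsFactors = FALSE)
  } else {
    reps <- data.frame(treatment_id = w$treatment_id, dose_uM = w$dose_uM,
                       assay = w$assay, fc = w$fold_change,
                       stringsAsFactors = FALSE)
  }
  grp_key <- paste(reps$treatment_id, reps$dose_uM, reps$assay, sep = "\r")
  n <- tapply(reps$fc, grp_key, length)
  d_bar <- tapply(reps$fc, grp_key, mean)
  s2 <- tapply(reps$fc, grp_key, stats::var)
  keys <- names(n)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  ann <- w$target_annotation[match(parts[, 1L], w$treatment_id)]
  out <- data.frame(treatment_id = parts[, 1L],
                    target_annotation = ann,
                    dose_uM = as.numeric(parts[, 2L]),
                    assay = parts[, 3L],
                    n = as.integer(n), d_bar = as.numeric(d_bar),
                    s2 = as.numeric(s2),
                    status = ifelse(n >= 2L, "ok", "too_few_replicates"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$treatment_id, out$dose_uM, out$assay), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool per-group variances into the stabilizing adjustment s0^2
#'
#' The SSMD denominator shrinks each group's variance toward \code{s0^2}, the
#' median of all per-group sample variances, pooled per assay across the
#' whole screen, to stabilize the effect-size estimate when group variances
#' are noisy at small n.
#'
#' @param groups Output of [summarizeGroups()].
#' @return \code{data.frame(assay, s0_sq, n_groups_pooled)}.
#' @export
poolVariance <- function(groups) {
  ok <- groups[groups$status == "ok" & is.finite(groups$s2), , drop = FALSE]
  if (!nrow(ok)) stopf("no scoreable groups to pool variances from")
  s0 <- tapply(ok$s2, ok$assay, stats::median)
  data.frame(assay = names(s0), s0_sq = as.numeric(s0),
             n_groups_pooled = as.integer(table(ok$assay)[names(s0)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Robust replicate SSMD (UMVUE)
#'
#' The per-group effect-size statistic of the screen:
#' \code{ssmd = c_n * d_bar / sqrt(wI * s2 + w0 * s0_sq)}, with \code{c_n}
#' the unbiasedness factor of [umvueFactor()], \code{d_bar}/\code{s2} the
#' group's replicate mean and variance, and \code{s0_sq} the pooled median
#' variance of [poolVariance()]. Default weights are 0.5/0.5 (constrained to
#' sum to 1); \code{wI = 1} turns off the pooling shrinkage and yields the
#' pure UMVUE of the standardized mean difference.
#'
#' @param groups Output of [summarizeGroups()].
#' @param pool Output of [poolVariance()]; required unless \code{w0 = 0}.
#' @param wI,w0 Denominator weights for the group and pooled variances; must
#'   sum to 1.
#' @return \code{groups} with an \code{ssmd} column added; groups with a
#'   zero denominator are flagged \code{"zero_denominator"} with \code{NA}
#'   SSMD.
#' @examples
#' g <- data.frame(treatment_id = "t", target_annotation = "",
#'                 dose_uM = 1, assay = "LYZ.NS", n = 3L, d_bar = 0.4,
#'                 s2 = 0.04, status = "ok")
#' p <- data.frame(assay = "LYZ.NS", s0_sq = 0.04, n_groups_pooled = 1L)
#' replicateSSMD(g, p)$ssmd  # (1/sqrt(pi)) * 0.4 / 0.2
#' @export
replicateSSMD <- function(groups, pool = NULL, wI = 0.5, w0 = 0.5) {
  if (abs(wI + w0 - 1) > 1e-12) stopf("weights must satisfy wI + w0 = 1")
  if (w0 > 0 && is.null(pool)) stopf("pool is required when w0 > 0")
  s0 <- if (w0 > 0) pool$s0_sq[match(groups$assay, pool$assay)] else 0
  denom2 <- wI * groups$s2 + w0 * s0
  cn <- rep(NA_real_, nrow(groups))
  ok <- groups$status == "ok" & groups$n >= 3L
  cn[ok] <- umvueFactor(groups$n[ok])
  ssmd <- ifelse(ok & denom2 > 0, cn * groups$d_bar / sqrt(denom2), NA_real_)
  groups$ssmd <- ssmd
  groups$status[ok & !is.na(denom2) & denom2 <= 0] <- "zero_denominator"
  groups$status[groups$status == "ok" & groups$n < 3L] <- "too_few_replicates"
  groups
}

#' Fold-change z-scores per assay
#'
#' The biological-effect gate: each group's mean fold change divided by the
#' sample standard deviation of all group mean fold changes within the same
#' assay (the population of treatment-dose effects across the screen). A hit
#' refinement requires \code{z > 1.282}, the 90th percentile of the standard
#' normal.
#'
#' @param groups Output of [summarizeGroups()] (optionally already scored).
#' @return \code{groups} with a \code{z} column; if the population SD of an
#'   assay is zero its groups are flagged \code{"zscore_undefined"}.
#' @export
foldChangeZScores <- function(groups) {
  groups$z <- NA_real_
  for (a in unique(groups$assay)) {
    sel <- groups$assay == a & groups$status %in% c("ok")
    if (sum(sel) < 2L) {
      groups$status[groups$assay == a & groups$status == "ok"] <-
        "zscore_undefined"
      next
    }
    sd_pop <- stats::sd(groups$d_bar[sel])
    if (!is.finite(sd_pop) || sd_pop == 0) {
      groups$status[sel] <- "zscore_undefined"
      next
    }
    groups$z[groups$assay == a] <- groups$d_bar[groups$assay == a] / sd_pop
  }
  groups
}

#' Score a normalized screen: SSMD, mean fold change and z per group
#'
#' Convenience wrapper chaining [summarizeGroups()], [poolVariance()],
#' [replicateSSMD()] and [foldChangeZScores()], producing the finalized
#' statistics table used for hit identification.
#'
#' @param dataset A normalized \linkS4class{ScreenDataset}.
#' @param replicateUnit \code{"donor"} (primary) or \code{"well"}
#'   (validation).
#' @param wI,w0 SSMD denominator weights (see [replicateSSMD()]).
#' @return \code{data.frame(treatment_id, target_annotation, dose_uM, assay,
#'   n, d_bar, s2, ssmd, z, status)} -- \code{d_bar} is the group mean fold
#'   change.
#' @examples
#' sim <- simulatePrimaryScreen(simulationConfig(seed = 1, donors = 3,
#'   platesPerDonor = 1, nCompounds = 30, nTargets = 15))
#' scores <- scoreScreen(normalizeScreen(sim$dataset))
#' head(scores)
#' @export
scoreScreen <- function(dataset, replicateUnit = c("donor", "well"),
                        wI = 0.5, w0 = 0.5) {
  groups <- summarizeGroups(dataset, replicateUnit = replicateUnit)
  pool <- poolVariance(groups)
  groups <- replicateSSMD(groups, pool, wI = wI, w0 = w0)
  foldChangeZScores(groups)
}
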