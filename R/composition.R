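#' Abundance eligibility filter for enrichment testing
#'
#' A (cell type, stratum) pair is tested only when the type is represented in
#' BOTH conditions of that stratum: at least \code{minFraction} of cells
#' (fraction mode, default 0.5%, inclusive) or at least \code{minCells}
#' cells (count mode, default 10, inclusive).
#'
#' @param table \code{data.frame(condition, stratum-or-timepoint, cell_type,
#'   n_cells)}; the stratum column may be named \code{stratum} or
#'   \code{timepoint}.
#' @param mode \code{"fraction"} or \code{"count"}.
#' @param minFraction Minimum fraction per condition (fraction mode).
#' @param minCells Minimum cells per condition (count mode).
#' @return \code{data.frame(cell_type, stratum, eligible, reason)}.
#' @export
abundanceFilter <- function(table, mode = c("fraction", "count"),
                            minFraction = 0.005, minCells = 10L) {
  mode <- match.arg(mode)
  tab <- .asCompositionTable(table)
  conds <- sort(unique(tab$condition))
  if (length(conds) != 2L)
    stopf("composition table must have exactly 2 conditions (got %d)",
          length(conds))
  rows <- list()
  for (s in unique(tab$stratum)) {
    ts <- tab[tab$stratum == s, , drop = FALSE]
    totals <- tapply(ts$n_cells, ts$condition, sum)
    for (ct in unique(ts$cell_type)) {
      cnt <- vapply(conds, function(cd)
        sum(ts$n_cells[ts$condition == cd & ts$cell_type == ct]),
        numeric(1L))
      ok <- if (mode == "fraction") {
        all(totals[conds] > 0) && all(cnt / totals[conds] >= minFraction)
      } else {
        all(cnt >= minCells)
      }
      reason <- if (ok) "" else if (mode == "fraction")
        sprintf("below %.3g%% of cells in at least one condition",
                100 * minFraction)
      else sprintf("fewer than %d cells in at least one condition", minCells)
      rows[[length(rows) + 1L]] <-
        data.frame(cell_type = ct, stratum = s, eligible = ok,
                   reason = reason, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.asCompositionTable <- function(table) {
  tab <- as.data.frame(table)
  if (!"stratum" %in% names(tab) && "timepoint" %in% names(tab))
    tab$stratum <- tab$timepoint
  need <- c("condition", "stratum", "cell_type", "n_cells")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stopf("composition table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (any(tab$n_cells < 0) || any(tab$n_cells != round(tab$n_cells)))
    stopf("n_cells must be non-negative integers")
  tab
}

# Two-sided Fisher exact p for a 2x2 table by the small-p-values method:
# the sum of hypergeometric point probabilities not exceeding that of the
# observed table (with the customary 1 + 1e-7 relative slack against
# floating-point ties).
.fisherP2x2 <- function(a, b, c, d) {
  m <- a + b          # margin of the focal type
  n <- c + d
  k <- a + c          # treated-column margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher odds-ratio enrichment for one 2x2 table
#'
#' The core compositional statistic: counts \code{a} (type, treated),
#' \code{b} (rest, treated), \code{c} (type, control), \code{d} (rest,
#' control). The two-sided p value is the exact hypergeometric small-p
#' summation; the odds ratio is the sample cross-product \code{(a*d)/(b*c)}
#' with a Haldane--Anscombe +0.5 added to every cell only when some cell is
#' zero; the 95% CI is the Woolf log-normal interval
#' \code{exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))} on the
#' (possibly corrected) counts. A conditional-MLE odds ratio (the
#' [stats::fisher.test()] estimator) is available via
#' \code{orMethod = "cmle"}.
#'
#' @param a,b,c,d Non-negative integer counts of the (type, rest) x
#'   (treated, control) table.
#' @param conf Confidence level (default 0.95).
#' @param orMethod \code{"cross-product"} (default) or \code{"cmle"}.
#' @return One-row \code{data.frame(odds_ratio, ci_low, ci_high, p, tested,
#'   filter_reason)}.
#' @examples
#' fisherEnrichment(30, 70, 15, 85)
#' @export
fisherEnrichment <- function(a, b, c, d, conf = 0.95,
                             orMethod = c("cross-product", "cmle")) {
  orMethod <- match.arg(orMethod)
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stopf("counts must be non-negative integers")
  untested <- function(reason)
    data.frame(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_, tested = FALSE, filter_reason = reason,
               stringsAsFactors = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(untested("empty margin"))
  p <- .fisherP2x2(a, b, c, d)
  cc <- if (any(cnt == 0)) cnt + 0.5 else cnt
  if (orMethod == "cross-product") {
    or <- (cc[1L] * cc[4L]) / (cc[2L] * cc[3L])
  } else {
    or <- unname(stats::fisher.test(matrix(c(a, c, b, d), 2L))$estimate)
  }
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(sum(1 / cc))
  lor <- log((cc[1L] * cc[4L]) / (cc[2L] * cc[3L]))
  data.frame(odds_ratio = or, ci_low = exp(lor - zq * se),
             ci_high = exp(lor + zq * se), p = p, tested = TRUE,
             filter_reason = "", stringsAsFactors = FALSE)
}

#' Odds-ratio enrichment time course over a composition table
#'
#' For each stratum (timepoint or cluster) and eligible cell type, tests the
#' (type vs rest) x (treated vs control) 2x2 table with [fisherEnrichment()]
#' and adjusts the p values across all tested pairs by Benjamini--Hochberg
#' (default; Bonferroni available). Ineligible pairs are reported untested
#' with their filter reason.
#'
#' @param table Composition table (see [abundanceFilter()]).
#' @param mode,minFraction,minCells Passed to [abundanceFilter()].
#' @param fdr \code{"BH"} (default) or \code{"bonferroni"}.
#' @param orMethod Passed to [fisherEnrichment()].
#' @param treatedLabel Condition label treated as "treated" (default the
#'   lexicographically later of the two, so \code{control}/\code{treated}
#'   works out of the box).
#' @return \code{data.frame(cell_type, stratum, odds_ratio, ci_low, ci_high,
#'   p, q, tested, filter_reason)}.
#' @export
enrichmentTimecourse <- function(table, mode = c("fraction", "count"),
                                 minFraction = 0.005, minCells = 10L,
                                 fdr = c("BH", "bonferroni"),
                                 orMethod = c("cross-product", "cmle"),
                                 treatedLabel = NULL) {
  mode <- match.arg(mode)
  fdr <- match.arg(fdr)
  orMethod <- match.arg(orMethod)
  tab <- .asCompositionTable(table)
  conds <- sort(unique(tab$condition))
  if (is.null(treatedLabel)) treatedLabel <- conds[length(conds)]
  controlLabel <- setdiff(conds, treatedLabel)
  if (length(controlLabel) != 1L)
    stopf("cannot identify a single control condition")
  elig <- abundanceFilter(tab, mode = mode, minFraction = minFraction,
                          minCells = minCells)
  rows <- lapply(seq_len(nrow(elig)), function(i) {
    ct <- elig$cell_type[i]; s <- elig$stratum[i]
    base <- data.frame(cell_type = ct, stratum = s, stringsAsFactors = FALSE)
    if (!elig$eligible[i])
      return(cbind(base,
                   data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p = NA_real_,
                              tested = FALSE,
                              filter_reason = elig$reason[i],
                              stringsAsFactors = FALSE)))
    ts <- tab[tab$stratum == s, , drop = FALSE]
    cnt <- function(cd, type_in) sum(ts$n_cells[ts$condition == cd &
                                                  (ts$cell_type == ct) ==
                                                    type_in])
    cbind(base, fisherEnrichment(cnt(treatedLabel, TRUE),
                                 cnt(treatedLabel, FALSE),
                                 cnt(controlLabel, TRUE),
                                 cnt(controlLabel, FALSE),
                                 orMethod = orMethod))
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- out$tested
  if (any(tested)) out$q[tested] <- fdrAdjust(out$p[tested], method = fdr)
  out[c("cell_type", "stratum", "odds_ratio", "ci_low", "ci_high", "p", "q",
        "tested", "filter_reason")]
}

#' Adjust p values for multiple testing
#'
#' Benjamini--Hochberg step-up (default) or Bonferroni, via
#' [stats::p.adjust()]; output order matches input.
#'
#' @param p Numeric p values in [0, 1].
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return Adjusted q values.
#' @export
fdrAdjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Cohen's d with magnitude bins
#'
#' Standardized mean difference \code{(mean(x) - mean(y)) / s_pooled} with
#' the (n-1)-weighted pooled SD, binned by magnitude: negligible
#' (|d| <= 0.5), small (0.5--0.8), medium (0.8--1.2), large (1.2--2), very
#' large (> 2).
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @param label Optional label carried into the result.
#' @return \code{data.frame(label, cohens_d, magnitude_bin, status)}; a zero
#'   pooled SD yields \code{NA} with status \code{"zero_pooled_sd"}.
#' @export
cohensD <- function(x, y, label = "") {
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs n >= 2")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    return(data.frame(label = label, cohens_d = NA_real_,
                      magnitude_bin = NA_character_,
                      status = "zero_pooled_sd", stringsAsFactors = FALSE))
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  data.frame(label = label, cohens_d = d, magnitude_bin = effectSizeBin(d),
             status = "ok", stringsAsFactors = FALSE)
}

#' @rdname cohensD
#' @param d A Cohen's d value (binning uses |d|).
#' @export
effectSizeBin <- function(d) {
  ad <- abs(d)
  cut(ad, breaks = c(-Inf, 0.5, 0.8, 1.2, 2, Inf),
      labels = c("negligible", "small", "medium", "large", "very large"),
      right = TRUE) |> as.character()
}

#' Min-max scale scores to [0, 1]
#'
#' \code{(s - min) / (max - min)}; used to place module scores on a common
#' 0--1 range. Errors on constant input (scaling undefined).
#'
#' @param scores Numeric vector with \code{max > min}.
#' @return Scaled vector with min 0 and max 1.
#' @export
minmaxScale <- function(scores) {
  r <- range(scores, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1L] == r[2L])
    stopf("minmaxScale undefined for constant input")
  (scores - r[1L]) / (r[2L] - r[1L])
}

#' Percentile-exceedance fraction
#'
#' Computes the empirical (inverse-ECDF) \code{percentile} cutoff of the
#' reference counts -- the smallest observed value with at least that share
#' of the reference at or below it -- and the fraction of test counts
#' STRICTLY greater than the cutoff. With integer counts the cutoff is an
#' integer, matching per-crypt cell-count usage.
#'
#' @param referenceCounts Reference sample (e.g. vehicle-animal per-crypt
#'   counts); nonempty.
#' @param testCounts Test sample; nonempty.
#' @param percentile Percentile in [0, 100] (default 90).
#' @return List with \code{cutoff} and \code{fraction}.
#' @examples
#' exceedanceFraction(c(2,3,3,3,4,4,4,4,4,5), c(5,6,4,3,5))
#' @export
exceedanceFraction <- function(referenceCounts, testCounts, percentile = 90) {
  if (!length(referenceCounts) || !length(testCounts))
    stopf("reference and test counts must be nonempty")
  if (percentile < 0 || percentile > 100)
    stopf("percentile must be in [0, 100]")
  cutoff <- unname(stats::quantile(referenceCounts, percentile / 100,
                                   type = 1L))
  list(cutoff = cutoff, fraction = mean(testCounts > cutoff))
}
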