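#' Noncentral t cumulative distribution function
#'
#' Thin, named wrapper around [stats::pt()] so the decision-theory curves
#' document their distributional dependence in one place. Validated in the
#' package test suite against the integral representation
#' \code{E[pnorm(x * sqrt(V/df) - ncp)]} with \code{V ~ chi-square(df)}.
#'
#' @param x Quantile.
#' @param df Degrees of freedom (>= 1).
#' @param ncp Noncentrality parameter.
#' @return \code{P(T <= x)} for \code{T ~ t(df, ncp)}.
#' @export
noncentralTCDF <- function(x, df, ncp) {
  if (any(df < 1)) stopf("df must be >= 1")
  stats::pt(x, df = df, ncp = ncp)
}

# Threshold on the mean/SD scale implied by a critical value beta on the
# reporting scale. On the UMVUE scale the decision statistic carries the
# c_n factor, so the CDF argument is beta / (c_n * k); on the raw scale it
# is beta / k.
.thresholdArg <- function(beta, params) {
  n <- params@n
  k <- kFactor(n)
  if (params@scale == "umvue") beta / (umvueFactor(n) * k) else beta / k
}

#' False-positive and false-negative level curves of the SSMD gate
#'
#' For an upregulation decision that flags a group when its replicate SSMD
#' exceeds \code{beta}, the false-positive level against at-least-very-weak
#' true effects (bound \code{beta2}) is \code{FPL(beta) = 1 - F_t(df = n-1,
#' ncp = sqrt(n) * beta2)(beta / (c_n k))}, and the false-negative level
#' against at-least-strong effects (bound \code{beta1}) is
#' \code{FNL(beta) = F_t(df = n-1, ncp = sqrt(n) * beta1)(beta / (c_n k))}.
#' The \code{c_n} factor maps the threshold from the UMVUE reporting scale
#' of [replicateSSMD()] to the mean/SD scale of the t statistic; with
#' \code{scale = "raw"} it is omitted. FPL is strictly decreasing and FNL
#' strictly increasing in \code{beta}, so their intersection is unique.
#'
#' @param beta Candidate critical value(s) on the reporting scale.
#' @param params A \linkS4class{DecisionParams}.
#' @return The error level(s) in (0, 1).
#' @seealso [optimalCriticalValue()]
#' @examples
#' dp <- decisionParams(n = 3)
#' fplCurve(0.997, dp)
#' fnlCurve(0.997, dp)
#' @export
fplCurve <- function(beta, params) {
  1 - noncentralTCDF(.thresholdArg(beta, params), df = params@n - 1L,
                     ncp = sqrt(params@n) * params@beta2)
}

#' @rdname fplCurve
#' @export
fnlCurve <- function(beta, params) {
  noncentralTCDF(.thresholdArg(beta, params), df = params@n - 1L,
                 ncp = sqrt(params@n) * params@beta1)
}

#' Solve for the optimal SSMD critical value
#'
#' In \code{"intersect_fpl_fnl"} mode (primary-screen design) the critical
#' value balances the two error curves: \code{beta_alpha1} is the unique root
#' of \code{FNL(beta) = FPL(beta)} on \code{(0, upper]}, the threshold that
#' jointly minimizes the maximal error. In \code{"fpl_only"} mode
#' (validation-screen design) it solves \code{FPL(beta) = fpl} for the
#' requested false-positive level, with FNL unconstrained. Monotonicity of
#' both curves makes the root unique; it is found by bracketed root finding
#' to \code{tol} in beta, with an explicit error if the bracket shows no
#' sign change.
#'
#' @param params A \linkS4class{DecisionParams} (see [decisionParams()]).
#' @param upper Upper end of the search bracket (default 20).
#' @param tol Absolute tolerance on beta (default 1e-6).
#' @return \code{params} with \code{betaAlpha1}, \code{achievedFPL} and
#'   \code{achievedFNL} filled in.
#' @examples
#' ## primary design: n = 3 donor replicates, bounds 3 and 0.25
#' optimalCriticalValue(decisionParams(n = 3))
#' ## validation design: n = 8 wells, FPL 0.05 only
#' optimalCriticalValue(decisionParams(n = 8, fpl = 0.05, mode = "fpl_only"))
#' @export
optimalCriticalValue <- function(params, upper = 20, tol = 1e-6) {
  stopifnot(is(params, "DecisionParams"))
  lower <- tol
  if (params@mode == "intersect_fpl_fnl") {
    g <- function(b) fnlCurve(b, params) - fplCurve(b, params)
  } else {
    g <- function(b) fplCurve(b, params) - params@fpl
  }
  glo <- g(lower)
  ghi <- g(upper)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0)
    stopf(paste0("no sign change on bracket (%g, %g): g(lower) = %.6g, ",
                 "g(upper) = %.6g; widen the bracket or check the design"),
          lower, upper, glo, ghi)
  root <- stats::uniroot(g, lower = lower, upper = upper, tol = tol)$root
  params@betaAlpha1 <- root
  params@achievedFPL <- fplCurve(root, params)
  params@achievedFNL <- fnlCurve(root, params)
  validObject(params)
  params
}

#' The standard-normal quantile used for the top-fraction z gate
#'
#' The refinement gate keeps groups in the top \code{fraction} of an assumed
#' normal distribution of fold changes; for the default top 10% the cutoff is
#' \code{qnorm(0.9) = 1.282} (3 decimals).
#'
#' @param fraction Upper-tail fraction (default 0.10).
#' @return The z cutoff.
#' @examples
#' zGateCutoff()       # 1.2816
#' @export
zGateCutoff <- function(fraction = 0.10) stats::qnorm(1 - fraction)
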