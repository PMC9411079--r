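# Data Quality Score: map the propagated relative peak-area error through
# the Gaussian error function to a score in [0, 1].

# Gaussian error function erf(x) = 2/sqrt(pi) * integral_0^x exp(-t^2) dt,
# expressed through the normal CDF.
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Data Quality Score from the relative peak-area error
#'
#' `DQS = 1 - erf(dA / A)`, where `dA / A` is the relative standard error
#' of the fitted Gaussian peak area propagated from the regression
#' coefficient covariance. A relative error of 0 gives a DQS of 1 (perfect
#' agreement with the Gaussian model); the score decreases strictly and
#' approaches 0 as the relative error grows without bound.
#'
#' @param rel_err Non-negative relative area error(s); the absolute value
#'   is taken defensively. `NaN` is an error.
#' @return DQS value(s) in `[0, 1]`.
#' @examples
#' dqs_from_relative_error(0)     # 1
#' dqs_from_relative_error(0.05)  # ~0.9436
#' @export
dqs_from_relative_error <- function(rel_err) {
  if (any(is.nan(rel_err))) stop("rel_err is NaN")
  pmin(1, pmax(0, 1 - .erf(abs(rel_err))))
}

#' DQS category thresholds
#'
#' The four quality categories are bounded by the DQS values that
#' correspond to relative peak-area errors of 1%, 5% and 33% --- the
#' levels commonly used in significance testing. The thresholds are
#' computed from those three relative errors at call time.
#'
#' @return Named numeric vector `c(I = , II = , III = )`: the minimum DQS
#'   of categories I, II and III. Category IV is everything below.
#' @export
dqs_category_thresholds <- function() {
  c(I = 1 - .erf(0.01), II = 1 - .erf(0.05), III = 1 - .erf(0.33))
}

#' Assign DQS quality categories
#'
#' Category I holds centroids whose relative area error is at most 1%,
#' II at most 5%, III at most 33%, IV the rest. Boundaries are half-open
#' with the better category claiming the boundary value.
#'
#' @param dqs Numeric vector of DQS values in `[0, 1]`.
#' @return Character vector of categories `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
categorize <- function(dqs) {
  if (any(!is.finite(dqs)) || any(dqs < 0) || any(dqs > 1))
    stop("dqs values must lie in [0, 1]")
  thr <- dqs_category_thresholds()
  unname(ifelse(dqs >= thr[["I"]], "I",
                ifelse(dqs >= thr[["II"]], "II",
                       ifelse(dqs >= thr[["III"]], "III", "IV"))))
}

#' Score a fitted Gaussian peak
#'
#' Convenience wrapper: computes the relative area error `d_area / area`
#' of a `GaussianPeak`, its DQS and its category.
#'
#' @param peak A `GaussianPeak` from [backtransform()].
#' @return The peak with fields `rel_area_error`, `dqs` and `category`
#'   added (class `ScoredPeak`/`GaussianPeak`).
#' @export
score_peak <- function(peak) {
  if (inherits(peak, "RejectRecord")) return(peak)
  stopifnot(inherits(peak, "GaussianPeak"))
  peak$rel_area_error <- peak$d_area / peak$area
  peak$dqs <- dqs_from_relative_error(peak$rel_area_error)
  peak$category <- categorize(peak$dqs)
  class(peak) <- c("ScoredPeak", class(peak))
  peak
}
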