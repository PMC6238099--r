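#' @importFrom rlang .data %||%
#' @importFrom stats rpois rexp rgeom runif sd setNames
#' @importFrom utils head tail
NULL

# Default timezone for the Tanzanian deployment; all hour-of-day and
# calendar-month logic is local time.
M4RH_TZ <- "Africa/Dar_es_Salaam"

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, matching
#' the convention used for printed percentages (base [round()] rounds ties to
#' even). Only intended for non-negative rates.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # eps guard: values like 2.675 are stored fractionally below the tie
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count over a denominator
#'
#' `rate(n, d)` is `100 * n / d` rounded half-up to 2 decimals, the form every
#' printed indicator takes (e.g. `rate(188904, 409768)` is `46.10`, the overall
#' activation rate of the Tanzanian m4RH deployment).
#'
#' @param numerator,denominator non-negative counts; `denominator` must be
#'   positive.
#' @return percentage on the 0-100 scale, rounded to 2 decimals.
#' @export
#' @examples
#' rate(188904, 409768)
rate <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) {
    stop("rate() is undefined for a zero or negative denominator", call. = FALSE)
  }
  if (any(numerator < 0)) stop("numerator must be non-negative", call. = FALSE)
  round_half_up(100 * numerator / denominator, 2)
}

#' Churn rate between two funnel stages
#'
#' The share of users entering a stage that did not progress to the next:
#' `rate(entered - progressed, entered)`.
#'
#' @param entered users entering the stage.
#' @param progressed users reaching the next stage; must not exceed `entered`.
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' churn_rate(409768, 188904)  # first navigation step
#' churn_rate(188904, 169218)  # second step
churn_rate <- function(entered, progressed) {
  if (any(progressed > entered)) {
    stop("progressed exceeds entered: funnel counts are inconsistent", call. = FALSE)
  }
  if (any(progressed < 0)) stop("counts must be non-negative", call. = FALSE)
  rate(entered - progressed, entered)
}

# year-month key used for all calendar-month logic ("2014-03")
month_key <- function(ts) format(ts, "%Y-%m", tz = M4RH_TZ)
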