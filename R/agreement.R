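#' Bland-Altman agreement between two methods
#'
#' Computes the mean difference (bias) and 95% limits of agreement between a
#' reference method and a test method measured on the same scans.
#' Differences are \code{reference - test} (whole-lung minus extrapolated),
#' so a positive bias means the test method underestimates. The limits use
#' the classic 1.96 multiplier on the sample standard deviation (n - 1
#' denominator) without a small-sample correction.
#'
#' @param reference,test Equal-length numeric vectors (length >= 3) of the
#'   metric obtained by the reference and test methods.
#' @param metric Label for the compared metric.
#' @return An \linkS4class{AgreementResult}.
#' @examples
#' blandAltman(c(101, 202, 303), c(100, 200, 300), "V_total")
#' @export
blandAltman <- function(reference, test, metric = "value") {
  if (length(reference) != length(test))
    stop(sprintf("length mismatch: %d reference vs %d test values",
                 length(reference), length(test)))
  if (length(reference) < 3L)
    stop("limits of agreement need at least 3 pairs")
  if (anyNA(reference) || anyNA(test)) stop("missing values are not allowed")
  d <- reference - test
  bias <- mean(d)
  s <- stats::sd(d)
  new("AgreementResult", metric = as.character(metric),
      n = length(d), bias = bias, sdDiff = s,
      loaLower = bias - 1.96 * s, loaUpper = bias + 1.96 * s)
}

#' @describeIn AgreementResult the mean difference (reference - test).
#' @param x,object An \code{AgreementResult}.
#' @export
bias <- function(x) x@bias

#' @describeIn AgreementResult lower and upper 95% limits of agreement.
#' @export
limitsOfAgreement <- function(x) c(lower = x@loaLower, upper = x@loaUpper)

#' @describeIn AgreementResult half-width of the limits, 1.96 * sdDiff.
#' @export
loaHalfWidth <- function(x) 1.96 * x@sdDiff

#' Flatten an AgreementResult to a one-row data.frame
#'
#' @param x An \linkS4class{AgreementResult}.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.AgreementResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(metric = x@metric, n = x@n, bias = x@bias, sdDiff = x@sdDiff,
             loaLower = x@loaLower, loaUpper = x@loaUpper,
             row.names = row.names)
}

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult [%s], n = %d\n", object@metric, object@n))
  cat(sprintf("  bias %.4g, 95%% LOA (%.4g, %.4g), SD of differences %.4g\n",
              object@bias, object@loaLower, object@loaUpper, object@sdDiff))
})

#' Relative deviation between paired measurements
#'
#' Per-pair absolute percent deviation \code{100 |ref - test| / ref},
#' summarized the way agreement studies report it: median (minimum to
#' maximum).
#'
#' @param reference,test Equal-length numeric vectors; \code{reference} must
#'   be strictly positive.
#' @return Named numeric: \code{median}, \code{min}, \code{max} (percent).
#' @export
relativeDeviationSummary <- function(reference, test) {
  if (length(reference) != length(test))
    stop("length mismatch between reference and test")
  if (!length(reference)) stop("at least one pair is required")
  if (any(reference <= 0))
    stop("relative deviation undefined for non-positive reference values")
  dev <- 100 * abs(reference - test) / reference
  c(median = stats::median(dev), min = min(dev), max = max(dev))
}

#' Agreement on intra-individual changes between consecutive scans
#'
#' For paired consecutive CTs (e.g., before and after a recruitment
#' maneuver) the quantity of interest is the change between the two time
#' points. Per pair this computes \code{delta_whole = whole(t2) - whole(t1)}
#' and \code{delta_extra = extra(t2) - extra(t1)} and runs Bland-Altman on
#' the two sets of deltas.
#'
#' @param pairs A list; each element is a list with
#'   \linkS4class{LungSummary} elements \code{t1Whole}, \code{t1Extra},
#'   \code{t2Whole}, \code{t2Extra}.
#' @param metric Metric name as accepted by \code{\link{metricValue}}.
#' @return An \linkS4class{AgreementResult} for the deltas, labelled
#'   \code{"delta_<metric>"}.
#' @export
pairedDeltaAgreement <- function(pairs, metric = "V_total") {
  need <- c("t1Whole", "t1Extra", "t2Whole", "t2Extra")
  ok <- vapply(pairs, function(p) all(need %in% names(p)), TRUE)
  if (!all(ok))
    stop("every pair needs elements t1Whole, t1Extra, t2Whole, t2Extra")
  dWhole <- vapply(pairs, function(p)
    metricValue(p$t2Whole, metric) - metricValue(p$t1Whole, metric), 0)
  dExtra <- vapply(pairs, function(p)
    metricValue(p$t2Extra, metric) - metricValue(p$t1Extra, metric), 0)
  blandAltman(dWhole, dExtra, paste0("delta_", metric))
}
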