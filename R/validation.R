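#' @include AllClasses.R
NULL

#' Signed relative error in percent
#'
#' \code{(pred - ref) / ref * 100}. Vectorized; used for every
#' relative-change column in the endpoint tables.
#'
#' @param pred predicted (or derivative) value(s).
#' @param ref reference (experimental or parent) value(s); must be nonzero.
#' @return signed percent difference(s).
#' @examples
#' relativeError(1.623, 1.398)  # 16.09...
#' @export
relativeError <- function(pred, ref) {
  if (any(ref == 0)) stop("reference value must be nonzero", call. = FALSE)
  (pred - ref) / ref * 100
}

#' External validation: predictive r-squared
#'
#' \code{r2pred = 1 - PRESS/SD}. PRESS is the sum of squared deviations
#' between experimental and predicted values of the test compounds; SD is
#' the sum of squared deviations of the test experimental values from the
#' mean of the training-set experimental values.
#'
#' @param testExp experimental values of the test set.
#' @param testPred predicted values of the test set (same order).
#' @param trainExp experimental values of the training set (only the mean is
#'   used).
#' @param ids optional test-compound identifiers for the report table.
#' @return a \linkS4class{ValidationReport}.
#' @export
externalValidation <- function(testExp, testPred, trainExp, ids = NULL) {
  stopifnot(length(testExp) == length(testPred))
  if (!length(testExp) || !length(trainExp)) {
    stop("test and training sets must be non-empty", call. = FALSE)
  }
  press <- sum((testExp - testPred)^2)
  sd2 <- sum((testExp - mean(trainExp))^2)
  if (sd2 <= 0) {
    stop("degenerate test set: SD is zero (test values equal the training mean)",
         call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("test", seq_along(testExp))
  tab <- data.frame(
    id = ids, experimental = testExp, predicted = testPred,
    relativeErrorPct = relativeError(testPred, testExp),
    stringsAsFactors = FALSE
  )
  new("ValidationReport", press = press, sd = sd2,
      r2pred = 1 - press / sd2, table = tab)
}

#' Export a validation report as CSV and/or JSON
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param csv,json optional output paths.
#' @return invisibly, a list representation of the report.
#' @export
exportValidation <- function(report, csv = NULL, json = NULL) {
  stopifnot(is(report, "ValidationReport"))
  rep <- list(r2pred = report@r2pred, PRESS = report@press, SD = report@sd,
              table = report@table)
  if (!is.null(csv)) {
    utils::write.csv(report@table, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA), json)
  }
  invisible(rep)
}
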