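#' Spike-response curve of predicted versus true mixing fractions
#'
#' Ordinary least squares of predicted fractions on spiked (true) fractions
#' across a dilution series. A slope of 1 with intercept 0 is the ideal
#' response; shallower slopes mean the assay under-reports composition
#' changes.
#'
#' @param spiked Numeric vector of true spiked fractions (>= 3 distinct
#'   values).
#' @param predicted Numeric vector of predicted fractions, same length.
#' @return List with `slope`, `intercept`, `r_squared`, `fitted`.
#' @export
spike_response <- function(spiked, predicted) {
  stopifnot(length(spiked) == length(predicted))
  if (length(unique(spiked)) < 3L)
    stopf("spike response needs >= 3 distinct spiked fractions")
  fit <- stats::lm(predicted ~ spiked)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = r_squared(predicted, stats::fitted(fit)),
       fitted = unname(stats::fitted(fit)))
}

#' Limit of detection from a spike-response curve
#'
#' The analytical sensitivity is the spike-response slope normalized by the
#' maximum (across mixing ratios) standard deviation of the predicted
#' fraction over replicate sets; the limit of detection is its inverse,
#' `sd_max / slope` -- the smallest composition difference distinguishable
#' from replicate noise. Fractions are in [0, 1] units; multiply by 100 for
#' percent.
#'
#' @param slope Spike-response slope (> 0).
#' @param sd_max Maximum replicate SD of the predicted fraction.
#' @return LOD in fraction units.
#' @export
limit_of_detection <- function(slope, sd_max) {
  if (!is.finite(slope) || slope <= 0)
    stopf("LOD undefined: slope must be positive")
  if (sd_max < 0) stopf("sd_max must be nonnegative")
  sd_max / slope
}

#' Replicated spike experiment summary
#'
#' Convenience wrapper: takes a matrix of predicted fractions (replicate
#' sets in rows, mixing ratios in columns) and the spiked ratios, fits the
#' spike response on the per-ratio means, and returns slope, the maximum
#' replicate SD and the limit of detection.
#'
#' @param spiked Numeric vector of spiked fractions (one per column).
#' @param predicted_matrix Replicates x ratios matrix of predicted
#'   fractions.
#' @return List with `slope`, `intercept`, `sd_max`, `lod`.
#' @export
spike_experiment <- function(spiked, predicted_matrix) {
  predicted_matrix <- as.matrix(predicted_matrix)
  stopifnot(ncol(predicted_matrix) == length(spiked))
  means <- colMeans(predicted_matrix)
  sds <- apply(predicted_matrix, 2L, stats::sd)
  resp <- spike_response(spiked, means)
  sd_max <- max(sds)
  list(slope = resp$slope, intercept = resp$intercept, sd_max = sd_max,
       lod = limit_of_detection(resp$slope, sd_max))
}
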