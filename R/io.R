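CANONICAL_COLUMNS <- c("event_id", "A", "C1", "D1", "D2", "D3", "D4",
                       "T1", "T2", "S1", "S2", "M1", "M2", "M3", "M4", "AR1")

#' Read and write feature tables
#'
#' Feature tables are CSV files with the canonical header
#' `event_id,A,C1,D1,D2,D3,D4,T1,T2,S1,S2,M1,M2,M3,M4,AR1[,label]`
#' (units: `A` in micrometres, `T1` in microseconds, `T2` in inverse
#' microseconds, everything else dimensionless). Unknown extra columns are
#' preserved; a missing mandatory column raises a schema error naming it.
#' Numeric round trips are lossless to 1e-12 relative.
#'
#' @param path File path.
#' @return `read_feature_table`: a data frame in canonical column order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  validate_feature_table(tab)
  extra <- setdiff(colnames(tab), CANONICAL_COLUMNS)
  tab[, c(CANONICAL_COLUMNS, extra), drop = FALSE]
}

#' @rdname read_feature_table
#' @param table Feature table (data frame) with the canonical columns.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  num <- vapply(table, is.numeric, NA)
  out <- table
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_feature_table <- function(tab) {
  missing <- setdiff(CANONICAL_COLUMNS, colnames(tab))
  if (length(missing))
    stopf("feature table schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  invisible(tab)
}

#' Write and read cell events as multi-page TIFF plus JSON sidecar
#'
#' Each event becomes `<event_id>.tif` (one 16-bit grayscale page per
#' frame) and `<event_id>.json` carrying `event_id`, `frame_interval_us`,
#' `pixel_size_um`, `junction_arrival_index`, `junction_exit_index` and the
#' ground-truth profile when present.
#'
#' @param events List of `cell_event` objects.
#' @param dir Output directory (created if needed).
#' @return `write_events`: the directory, invisibly.
#' @export
write_events <- function(events, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ev in events) {
    stopifnot(inherits(ev, "cell_event"))
    tiff::writeTIFF(ev$frames, file.path(dir, paste0(ev$event_id, ".tif")),
                    bits.per.sample = 16L)
    meta <- list(event_id = ev$event_id,
                 frame_interval_us = ev$frame_interval,
                 pixel_size_um = ev$pixel_size,
                 junction_arrival_index = ev$junction_arrival_index,
                 junction_exit_index = ev$junction_exit_index)
    if (!is.null(ev$ground_truth))
      meta$ground_truth <- as.list(ev$ground_truth)
    jsonlite::write_json(meta, file.path(dir, paste0(ev$event_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_events
#' @return `read_events`: a list of `cell_event` objects, ordered by
#'   event id.
#' @export
read_events <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(sidecars)) stopf("no event sidecars found in %s", dir)
  lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    tif <- file.path(dir, paste0(meta$event_id, ".tif"))
    if (!file.exists(tif)) stopf("missing frame stack: %s", tif)
    frames <- tiff::readTIFF(tif, all = TRUE)
    gt <- if (!is.null(meta$ground_truth)) unlist(meta$ground_truth)
    structure(list(event_id = meta$event_id, frames = frames,
                   frame_interval = meta$frame_interval_us,
                   pixel_size = meta$pixel_size_um,
                   junction_arrival_index = meta$junction_arrival_index,
                   junction_exit_index = meta$junction_exit_index,
                   ground_truth = gt),
              class = "cell_event")
  })
}

#' Serialize a classifier bundle to JSON and back
#'
#' Stores the standardization statistics, kernel specification, support
#' vectors and dual coefficients, class names, selected features, CV
#' accuracy and seed in a single JSON file. A reloaded bundle predicts via
#' the package's own one-vs-one decision function and agrees exactly with
#' the in-memory model.
#'
#' @param bundle A `classifier_bundle`.
#' @param path JSON file path.
#' @export
write_classifier <- function(bundle, path) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  m <- bundle$model
  obj <- list(
    format = "defcyto_classifier_v1",
    kernel = bundle$kernel, gamma = bundle$gamma,
    classes = bundle$classes, features = bundle$features,
    cv_accuracy = bundle$cv_accuracy, folds = bundle$folds,
    seed = bundle$seed,
    transform = list(center = as.list(bundle$transform$center),
                     scale = as.list(bundle$transform$scale)),
    svm = list(SV = apply(m$SV, 1L, identity, simplify = FALSE),
               coefs = apply(m$coefs, 1L, identity, simplify = FALSE),
               rho = m$rho, nSV = m$nSV, labels = m$labels,
               levels = m$levels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @return `read_classifier`: a `classifier_bundle_json` usable with
#'   [classify()] and [predict_fractions()].
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "defcyto_classifier_v1"))
    stopf("not a defcyto classifier file: %s", path)
  center <- unlist(obj$transform$center)
  st <- structure(list(center = center,
                       scale = unlist(obj$transform$scale),
                       features = obj$features),
                  class = "standardized_table")
  sv <- obj$svm$SV
  if (is.list(sv)) sv <- do.call(rbind, lapply(sv, unlist))
  coefs <- obj$svm$coefs
  if (is.list(coefs)) coefs <- do.call(rbind, lapply(coefs, unlist))
  if (!is.matrix(coefs)) coefs <- matrix(coefs, ncol = 1L)
  structure(list(transform = st, kernel = obj$kernel, gamma = obj$gamma,
                 classes = obj$classes, features = obj$features,
                 cv_accuracy = obj$cv_accuracy, folds = obj$folds,
                 seed = obj$seed,
                 sv = sv, coefs = coefs, rho = obj$svm$rho,
                 nSV = obj$svm$nSV, labels = obj$svm$labels,
                 levels = obj$svm$levels),
            class = c("classifier_bundle_json", "classifier_bundle"))
}

# One-vs-one decision function replicating libsvm voting for a bundle
# reloaded from JSON.
predict_from_json_bundle <- function(bundle, z) {
  k <- length(bundle$levels)
  nsv <- bundle$nSV
  start <- cumsum(c(0L, nsv))
  kern <- function() {
    if (bundle$kernel == "gaussian") {
      d2 <- outer(rowSums(z^2), rowSums(bundle$sv^2), `+`) -
        2 * z %*% t(bundle$sv)
      exp(-bundle$gamma * d2)
    } else z %*% t(bundle$sv)
  }
  K <- kern()
  votes <- matrix(0L, nrow(z), k)
  pair <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pair <- pair + 1L
    si <- (start[i] + 1L):start[i + 1L]
    sj <- (start[j] + 1L):start[j + 1L]
    dec <- K[, si, drop = FALSE] %*% bundle$coefs[si, j - 1L] +
      K[, sj, drop = FALSE] %*% bundle$coefs[sj, i] -
      bundle$rho[pair]
    win <- ifelse(dec > 0, i, j)
    votes[cbind(seq_len(nrow(z)), win)] <-
      votes[cbind(seq_len(nrow(z)), win)] + 1L
  }
  lab <- bundle$labels[max.col(votes, ties.method = "first")]
  factor(bundle$levels[lab], levels = bundle$classes)
}
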