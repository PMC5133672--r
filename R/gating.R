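#' Gate specifications
#'
#' Flow-cytometry-style gates in the (size, deformability) subspace:
#' \describe{
#'   \item{size}{cells with initial diameter `A` strictly below a threshold
#'     (default 15 micrometres).}
#'   \item{diagonal}{cells with deformability `D3` strictly above a
#'     threshold (default 1.4) and `A` strictly below the size threshold
#'     (default 15 micrometres).}
#'   \item{quantile}{a Mahalanobis ellipse fitted to a reference population
#'     so that a set fraction of it is contained (see
#'     [fit_quantile_gate()]).}
#' }
#'
#' @param a_max Size threshold on `A` (micrometres), strict inequality.
#' @param d3_min Deformability threshold on `D3`, strict inequality.
#' @return An object of class `gate_spec`.
#' @export
gate_size <- function(a_max = 15) {
  stopifnot(is.finite(a_max))
  structure(list(kind = "size", a_max = a_max), class = "gate_spec")
}

#' @rdname gate_size
#' @export
gate_diagonal <- function(d3_min = 1.4, a_max = 15) {
  stopifnot(is.finite(d3_min), is.finite(a_max))
  structure(list(kind = "diagonal", d3_min = d3_min, a_max = a_max),
            class = "gate_spec")
}

#' Fit a quantile (reference-population) gate
#'
#' Fits a Mahalanobis ellipse on a reference population (e.g. a pure
#' undifferentiated "day 0" sample): the centre is the feature mean, the
#' shape is the feature covariance, and the radius is the empirical
#' `containment` quantile of the reference points' Mahalanobis distances,
#' chosen so that exactly `ceiling(containment * n)` reference points fall
#' inside or on the boundary. With the default containment of 0.75 the gate
#' contains 75% of the reference population by construction.
#'
#' @param reference Feature table with at least 20 rows.
#' @param features Character pair of gating features (default `c("A",
#'   "D3")`).
#' @param containment Target contained fraction in (0, 1].
#' @return A `gate_spec` of kind `"quantile"` with fields `features`,
#'   `center`, `shape` (covariance), `radius`, `containment`. A singular
#'   covariance falls back to an axis-aligned box at the per-feature
#'   `containment` quantiles, with a warning.
#' @export
fit_quantile_gate <- function(reference, features = c("A", "D3"),
                              containment = 0.75) {
  x <- feature_matrix(reference, features)
  n <- nrow(x)
  if (n < 20L) stopf("quantile gate needs a reference of >= 20 rows")
  if (containment <= 0 || containment > 1)
    stopf("containment must be in (0, 1]")
  ctr <- colMeans(x)
  S <- stats::cov(x)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || min(eigen(S, symmetric = TRUE,
                       only.values = TRUE)$values) < 1e-12) {
    warnf("singular reference covariance; falling back to a quantile box")
    lo <- apply(x, 2L, stats::quantile, probs = (1 - containment) / 2)
    hi <- apply(x, 2L, stats::quantile, probs = 1 - (1 - containment) / 2)
    return(structure(list(kind = "box", features = features,
                          lower = lo, upper = hi,
                          containment = containment),
                     class = "gate_spec"))
  }
  d <- sqrt(stats::mahalanobis(x, ctr, S))
  radius <- sort(d)[ceiling(containment * n)]
  structure(list(kind = "quantile", features = features, center = ctr,
                 shape = S, radius = radius, containment = containment),
            class = "gate_spec")
}

#' Apply a gate to a feature table
#'
#' @param table Feature table containing the gate's columns.
#' @param gate A `gate_spec`.
#' @return A list: `mask` (logical per row) and `fraction` (gated / n).
#' @export
apply_gate <- function(table, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  mask <- switch(gate$kind,
    size = {
      a <- gate_column(table, "A")
      a < gate$a_max
    },
    diagonal = {
      a <- gate_column(table, "A")
      d3 <- gate_column(table, "D3")
      d3 > gate$d3_min & a < gate$a_max
    },
    quantile = {
      x <- feature_matrix(table, gate$features)
      sqrt(stats::mahalanobis(x, gate$center, gate$shape)) <= gate$radius
    },
    box = {
      x <- feature_matrix(table, gate$features)
      apply(sweep(x, 2L, gate$lower, `>=`) &
              sweep(x, 2L, gate$upper, `<=`), 1L, all)
    },
    stopf("unknown gate kind '%s'", gate$kind))
  list(mask = mask, fraction = mean(mask))
}

gate_column <- function(table, col) {
  if (!col %in% colnames(table)) stopf("missing column '%s'", col)
  table[[col]]
}
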