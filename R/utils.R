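# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage seed from a global seed
#'
#' Randomized pipeline stages each use a seed derived deterministically from
#' the global run seed and the stage name, so that re-running a configuration
#' reproduces every artifact while stages remain decoupled.
#'
#' @param global_seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(global_seed) * 10007 + h * 257) %% (2^31 - 1))
}

r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < .Machine$double.eps) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

# Polygon geometry via the shoelace / Green's-theorem formulas.
# `poly` is an n x 2 matrix of (x, y) vertices; closure is implicit.
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1L), , drop = FALSE] - poly
  sum(sqrt(rowSums(d^2)))
}

# Exact area, centroid and normalized second central moments of a polygon.
# Returns list(area, centroid, mu) with mu the 2x2 covariance-like tensor
# (second moments of area divided by area, about the centroid).
polygon_moments <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100)
    stopf("degenerate polygon: zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12         # integral of x^2 dA
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  mu <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                 ixy / a - cx * cy, iyy / a - cy^2), 2L, 2L)
  list(area = abs(a), centroid = c(cx, cy), mu = mu)
}

# Best-permutation agreement between two label vectors (small k only).
match_label_agreement <- function(pred, truth) {
  pl <- sort(unique(pred)); tl <- sort(unique(truth))
  if (length(pl) > 6L) stopf("label matching supports at most 6 classes")
  perms <- permutations_of(tl)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    mapped <- perms[i, match(pred, pl)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- permutations_of(v[-i])
    out <- rbind(out, cbind(rep(v[i], nrow(sub)), sub))
  }
  out
}
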