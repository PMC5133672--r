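#' Specify a feature-space cell population
#'
#' A synthetic population is a truncated multivariate Gaussian over the 15
#' canonical biophysical parameters, standing in for the measured feature
#' table of one cell class (e.g. pluripotent vs differentiated cells).
#' Default truncation bounds enforce the physical ranges: positive diameter,
#' deformability at least 1, nonnegative times, rates and counts.
#'
#' @param class_name Label attached to every generated row.
#' @param mean_vector Named numeric vector of the 15 parameter means
#'   (names must be `DC_PARAMETERS`).
#' @param covariance 15 x 15 symmetric positive semi-definite matrix.
#' @param truncation_bounds Optional 15 x 2 matrix (`lower`, `upper`) of
#'   per-parameter physical bounds; defaults to the canonical ranges.
#' @param n_cells Number of rows to draw.
#' @param rng_seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(class_name, mean_vector, covariance,
                            truncation_bounds = NULL,
                            n_cells = 1000L, rng_seed = 1L) {
  p <- length(DC_PARAMETERS)
  if (length(mean_vector) != p)
    stopf("mean_vector must have %d entries", p)
  if (is.null(names(mean_vector))) names(mean_vector) <- DC_PARAMETERS
  if (!identical(names(mean_vector), DC_PARAMETERS))
    stopf("mean_vector names must match DC_PARAMETERS in order")
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stopf("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stopf("covariance must be positive semi-definite")
  if (is.null(truncation_bounds)) truncation_bounds <- default_bounds()
  stopifnot(nrow(truncation_bounds) == p, ncol(truncation_bounds) == 2L)
  structure(list(class_name = class_name,
                 mean_vector = mean_vector,
                 covariance = covariance,
                 truncation_bounds = truncation_bounds,
                 n_cells = as.integer(n_cells),
                 rng_seed = as.integer(rng_seed)),
            class = "population_spec")
}

default_bounds <- function() {
  lo <- c(A = 1e-6, C1 = 0, D1 = 1, D2 = 1, D3 = 1, D4 = 1, T1 = 0, T2 = 0,
          S1 = 0, S2 = -Inf, M1 = 0, M2 = 0, M3 = 0, M4 = 0, AR1 = 1e-6)
  cbind(lower = lo, upper = rep(Inf, length(lo)))
}

# Rejection-sampled truncated multivariate normal draws.
rtmvnorm <- function(n, mean, sigma, lower, upper, max_tries = 1000L) {
  p <- length(mean)
  out <- matrix(NA_real_, 0L, p)
  tries <- 0L
  while (nrow(out) < n && tries < max_tries) {
    m <- max(n - nrow(out), 64L)
    draw <- MASS::mvrnorm(m, mu = mean, Sigma = sigma)
    if (m == 1L) draw <- matrix(draw, 1L)
    keep <- rowSums(sweep(draw, 2L, lower, `<`)) == 0 &
      rowSums(sweep(draw, 2L, upper, `>`)) == 0
    out <- rbind(out, draw[keep, , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(out) < n)
    stopf("truncation bounds reject nearly all mass; check the spec")
  out[seq_len(n), , drop = FALSE]
}

#' Draw a feature table from a population specification
#'
#' @param spec A [population_spec()].
#' @return A data frame with columns `event_id`, the 15 parameters and
#'   `label`; `spec$n_cells` rows (possibly zero).
#' @export
generate_feature_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  p <- length(DC_PARAMETERS)
  if (spec$n_cells == 0L) {
    tab <- as.data.frame(matrix(numeric(0), 0L, p,
                                dimnames = list(NULL, DC_PARAMETERS)))
    return(cbind(data.frame(event_id = character(0)), tab,
                 data.frame(label = character(0))))
  }
  draws <- withr::with_seed(spec$rng_seed,
    rtmvnorm(spec$n_cells, spec$mean_vector, spec$covariance,
             spec$truncation_bounds[, 1L], spec$truncation_bounds[, 2L]))
  colnames(draws) <- DC_PARAMETERS
  cbind(data.frame(event_id = sprintf("%s_%05d", spec$class_name,
                                      seq_len(spec$n_cells))),
        as.data.frame(draws),
        data.frame(label = rep(spec$class_name, spec$n_cells)))
}

# Largest-remainder allocation: integer counts summing to n_total whose
# proportions are as close as possible to `fractions`.
largest_remainder <- function(fractions, n_total) {
  raw <- fractions * n_total
  base <- floor(raw)
  rem <- n_total - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a spiked mixture of populations with exact composition
#'
#' Emulates spike-in experiments in which two or more cell classes are mixed
#' at controlled ratios. Per-class counts are the exact largest-remainder
#' allocation of `fractions * n_total` (not a multinomial draw), so the true
#' mixing ratio of the output is known to within rounding; rows are shuffled
#' under the seed and the true label column is retained.
#'
#' @param specs List of [population_spec()] objects (one per class).
#' @param fractions Nonnegative mixing proportions summing to 1.
#' @param n_total Total number of rows.
#' @param seed Integer seed for the per-class draws and the shuffle.
#' @return A feature table with a `label` column of true classes; the exact
#'   class counts are attached as attribute `class_counts`.
#' @export
generate_spiked_mixture <- function(specs, fractions, n_total, seed = 1L) {
  stopifnot(length(specs) == length(fractions))
  if (any(fractions < 0)) stopf("fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  counts <- largest_remainder(fractions, n_total)
  parts <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    s$n_cells <- counts[i]
    s$rng_seed <- as.integer((seed * 131 + i * 7919) %% (2^31 - 1))
    generate_feature_population(s)
  })
  tab <- do.call(rbind, parts)
  perm <- withr::with_seed(as.integer(seed), sample.int(nrow(tab)))
  tab <- tab[perm, , drop = FALSE]
  rownames(tab) <- NULL
  names(counts) <- vapply(specs, `[[`, "", "class_name")
  attr(tab, "class_counts") <- counts
  tab
}

#' Well-separated multi-class benchmark populations
#'
#' Builds a list of [population_spec()]s whose classes differ in the first
#' `n_informative` canonical parameters by `separation` pooled standard
#' deviations per adjacent class pair (informative parameters: A, D2, D3,
#' T1, S1, M1), while the remaining parameters are identically distributed
#' across classes (pure noise for any classifier). Used to exercise
#' clustering, classification, feature elimination and mixture
#' deconvolution under controlled class structure.
#'
#' @param n_classes Number of classes (2 to 6).
#' @param n_cells Cells per class.
#' @param separation Between-adjacent-class mean difference in SD units for
#'   each informative parameter.
#' @param seed Base seed; class i uses `seed + i`.
#' @return List of `population_spec` objects named `class1`, `class2`, ...
#' @export
benchmark_population_specs <- function(n_classes = 3L, n_cells = 1000L,
                                       separation = 3, seed = 1L) {
  stopifnot(n_classes >= 2L, n_classes <= 6L)
  informative <- c("A", "D2", "D3", "T1", "S1", "M1")
  base <- c(A = 12, C1 = 0.97, D1 = 1.2, D2 = 1.2, D3 = 1.3, D4 = 1.15,
            T1 = 3, T2 = 0.2, S1 = 0.15, S2 = 0.05, M1 = 0.012, M2 = 10,
            M3 = 0.02, M4 = 10, AR1 = 1)
  sd <- c(A = 0.8, C1 = 0.01, D1 = 0.05, D2 = 0.08, D3 = 0.1, D4 = 0.05,
          T1 = 0.5, T2 = 0.05, S1 = 0.04, S2 = 0.02, M1 = 0.004, M2 = 2,
          M3 = 0.006, M4 = 2, AR1 = 0.02)
  base <- base[DC_PARAMETERS]; sd <- sd[DC_PARAMETERS]
  lapply(seq_len(n_classes), function(i) {
    mu <- base
    mu[informative] <- mu[informative] +
      (i - 1L) * separation * sd[informative]
    population_spec(paste0("class", i), mu, diag(sd^2),
                    n_cells = n_cells,
                    rng_seed = as.integer(seed + i))
  })
}
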