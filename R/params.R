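#' Parameter set for a hierarchically organized tissue
#'
#' Builds and validates the full parameter set of the multi-compartment model
#' of cell differentiation with neutral mutations. Non-stem compartments are
#' indexed `1..n_compartments` (compartment 1 receives the founder clone;
#' the last compartment holds mature cells). Stem cells are not modelled
#' dynamically: the founder clone is placed in compartment
#' `founder_compartment` at time zero and no further influx occurs.
#'
#' A dividing cell in compartment `i` carrying `k` mutations differentiates
#' with probability `epsilon[i, k]` (both daughters move to compartment
#' `i + 1`), mutates with probability `u` (one cell with `k + 1` mutations
#' replaces it), or self-renews with probability `1 - epsilon - u` (two cells
#' remain in compartment `i`). The combined departure probability
#' `alpha = epsilon + u` controls the regime: `alpha > 1/2` yields a transient
#' clonal wave travelling down the hierarchy, `alpha < 1/2` unbounded
#' accumulation.
#'
#' @param n_compartments Number of non-stem compartments (haematopoietic
#'   reference: 31).
#' @param gamma Per-compartment proliferation growth factor; proliferation
#'   rates follow `r_i = gamma^i * r0`.
#' @param r0 Stem-cell proliferation rate in divisions per model time unit.
#'   One model time unit is one stem-cell division; with `r0 = 1/400` there
#'   are 400 stem-cell divisions (time units) per year.
#' @param u Mutation probability per cell division.
#' @param epsilon Differentiation probability. Either a single scalar
#'   (broadcast to all compartments and mutation counts) or a matrix with
#'   `n_compartments` rows and `k_max + 1` columns giving `epsilon[i, k]`
#'   for mutation counts `k = 0..k_max`.
#' @param n0 Founder cell count placed in `founder_compartment` at time 0.
#' @param founder_compartment Compartment index of the founder clone.
#' @param k_max Mutation-count truncation for numerical work. Class `k_max`
#'   collects no further mutation outflow, so occupancy there measures
#'   truncation leakage.
#'
#' @return An object of class `hierarchy_params`: a list with the validated
#'   inputs plus `rates` (the proliferation-rate schedule), `alpha` (the
#'   `epsilon + u` table), and `regime` (`"wave"` if all `alpha > 1/2`,
#'   otherwise `"accumulation"`).
#' @examples
#' hp <- hierarchy_params()            # haematopoietic defaults
#' hp$rates[1]                          # 1.26/400
#' hierarchy_params(epsilon = 0.4)$regime
#' @seealso [preset_params()], [rate_schedule()]
#' @export
hierarchy_params <- function(n_compartments = 31, gamma = 1.26, r0 = 1 / 400,
                             u = 1e-6, epsilon = 0.85, n0 = 1,
                             founder_compartment = 1, k_max = 5) {
  if (length(n_compartments) != 1L || n_compartments < 1 ||
      n_compartments != round(n_compartments))
    stop("n_compartments must be a positive integer")
  if (k_max < 0 || k_max != round(k_max)) stop("invalid truncation: k_max must be a non-negative integer")
  if (u < 0 || u >= 1) stop("mutation probability u must satisfy 0 <= u < 1")
  if (n0 < 1) stop("founder cell count n0 must be at least 1")
  if (founder_compartment < 1 || founder_compartment > n_compartments ||
      founder_compartment != round(founder_compartment))
    stop("founder_compartment out of range")

  eps <- build_epsilon_table(epsilon, n_compartments, k_max)
  if (any(eps <= 0)) stop("invalid rate: differentiation probabilities must be positive")
  if (any(eps + u > 1 + 1e-12)) stop("probabilities exceed one: epsilon + u > 1")

  params <- structure(list(
    n_compartments = as.integer(n_compartments),
    gamma = gamma, r0 = r0, u = u,
    epsilon = eps,
    epsilon_scalar = if (is.matrix(epsilon)) NA_real_ else epsilon,
    n0 = n0,
    founder_compartment = as.integer(founder_compartment),
    k_max = as.integer(k_max),
    rates = rate_schedule(gamma, r0, n_compartments),
    alpha = eps + u
  ), class = "hierarchy_params")
  params$regime <- if (any(params$alpha <= 0.5)) "accumulation" else "wave"
  params
}

# scalar -> constant table; matrix checked for shape
build_epsilon_table <- function(epsilon, n_compartments, k_max) {
  if (is.matrix(epsilon)) {
    if (nrow(epsilon) != n_compartments || ncol(epsilon) != k_max + 1)
      stop("invalid epsilon table: need n_compartments rows and k_max + 1 columns")
    eps <- epsilon
  } else {
    if (length(epsilon) != 1L || !is.numeric(epsilon))
      stop("invalid epsilon table: supply a scalar or a matrix")
    eps <- matrix(epsilon, n_compartments, k_max + 1)
  }
  dimnames(eps) <- list(compartment = NULL, k = 0:k_max)
  eps
}

#' Proliferation-rate schedule
#'
#' Per-compartment division rates `r_i = gamma^i * r0` for the non-stem
#' compartments `i = 1..n_compartments`. Rates increase geometrically with
#' compartment number when `gamma > 1`, reflecting the faster turnover of
#' more committed progenitors.
#'
#' @inheritParams hierarchy_params
#' @return Numeric vector of length `n_compartments`.
#' @examples
#' rate_schedule(1.26, 1 / 400, 3)
#' @export
rate_schedule <- function(gamma, r0, n_compartments) {
  if (gamma <= 0 || r0 <= 0 || n_compartments < 1)
    stop("invalid rate: gamma, r0 must be positive and n_compartments >= 1")
  gamma^seq_len(n_compartments) * r0
}

#' Validate a parameter set
#'
#' Re-checks all invariants of a [hierarchy_params()] object (probability
#' bounds, positive rates, truncation) and returns it. Useful after manual
#' modification of a parameter object.
#'
#' @param params A `hierarchy_params` object.
#' @return The validated object (invisibly identical to the input).
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "hierarchy_params"))
  with(params, {
    hierarchy_params(n_compartments, gamma, r0, u,
                     if (is.na(epsilon_scalar)) epsilon else epsilon_scalar,
                     n0, founder_compartment, k_max)
  })
}

#' Preset parameter sets
#'
#' `"haematopoiesis"` is the human blood-formation reference hierarchy:
#' 31 compartments, differentiation probability 0.85, rate growth factor
#' 1.26, mutation probability 1e-6 and stem-cell rate 1/400 per time unit
#' (one stem-cell division per time unit, about 400 per year).
#' `"test-small"` is a 5-compartment hierarchy with the same differentiation
#' probability but an inflated mutation probability (1e-3), small enough for
#' fast stochastic ensembles while remaining in the wave regime.
#'
#' @param name One of `"haematopoiesis"`, `"test-small"`.
#' @param ... Overrides passed on to [hierarchy_params()].
#' @return A `hierarchy_params` object.
#' @examples
#' preset_params("haematopoiesis")$n_compartments
#' @export
preset_params <- function(name = c("haematopoiesis", "test-small"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    "haematopoiesis" = list(n_compartments = 31, gamma = 1.26, r0 = 1 / 400,
                            u = 1e-6, epsilon = 0.85, n0 = 1, k_max = 5),
    "test-small" = list(n_compartments = 5, gamma = 1.26, r0 = 1 / 400,
                        u = 1e-3, epsilon = 0.85, n0 = 1, k_max = 3))
  args <- utils::modifyList(defaults, list(...))
  do.call(hierarchy_params, args)
}

#' @export
print.hierarchy_params <- function(x, ...) {
  cat("Hierarchical tissue parameters\n")
  cat(sprintf("  compartments: %d (founder in %d, n0 = %g)\n",
              x$n_compartments, x$founder_compartment, x$n0))
  eps_desc <- if (!is.na(x$epsilon_scalar)) sprintf("%g (constant)", x$epsilon_scalar)
              else "per-(compartment, k) table"
  cat(sprintf("  epsilon: %s, u: %g, k_max: %d\n", eps_desc, x$u, x$k_max))
  cat(sprintf("  rates: r_i = %g^i * %g  (r_1 = %g, r_%d = %g)\n",
              x$gamma, x$r0, x$rates[1], x$n_compartments,
              x$rates[x$n_compartments]))
  cat(sprintf("  regime: %s (alpha %s 1/2)\n", x$regime,
              if (x$regime == "wave") ">" else "<="))
  invisible(x)
}

# epsilon / alpha lookup with k clamped at k_max (classes beyond the
# truncation inherit the last column)
eps_at <- function(params, i, k) params$epsilon[i, pmin(k, params$k_max) + 1L]
alpha_at <- function(params, i, k) params$alpha[i, pmin(k, params$k_max) + 1L]

# TRUE when epsilon (hence alpha) is one constant across compartments and
# mutation counts -- the neutral case with the closed-form solutions
is_neutral <- function(params) {
  !is.na(params$epsilon_scalar) || length(unique(as.vector(params$epsilon))) == 1L
}

# constant epsilon of a neutral parameter set
neutral_epsilon <- function(params) {
  if (!is_neutral(params)) stop("parameter set is not neutral (epsilon varies)")
  if (!is.na(params$epsilon_scalar)) params$epsilon_scalar else params$epsilon[1, 1]
}

#' Convert between model time and calendar time
#'
#' Model time is counted in stem-cell divisions; with the haematopoietic
#' stem-cell rate `r0 = 1/400` per time unit, 400 time units make one year.
#'
#' @param t Model time (in time units).
#' @param months Calendar time in months.
#' @param units_per_year Stem-cell divisions per year (default 400).
#' @return The converted time.
#' @export
model_time_to_months <- function(t, units_per_year = 400) t / units_per_year * 12

#' @rdname model_time_to_months
#' @export
months_to_model_time <- function(months, units_per_year = 400) months / 12 * units_per_year
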