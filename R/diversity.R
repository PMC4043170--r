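#' Expected clonal diversity of multi-mutant cells
#'
#' Expected number of distinct mutations represented by clones of cells
#' carrying `k_plus_1` mutations in compartment `i`, for the clonal progeny
#' of a single founder cell, under the infinite-sites assumption (every
#' mutation event is unique). The statistic accumulates, over compartments
#' `j` up to `i`, the mutation probability times the reproductive capacity
#' of the `k_plus_1`-mutant class:
#' \deqn{D_i^{k+1} = u \sum_{j=1}^{i} W_j^{k+1}.}
#' Diversity grows towards the mature compartments, falls steeply with the
#' differentiation probability (about one order of magnitude per 0.03 of
#' `epsilon` under the haematopoietic parametrization) and carries a
#' `u^(k+2)` suppression in the mutation probability.
#'
#' @param params A [hierarchy_params()] object; `epsilon` must be positive.
#' @param i Compartment in which clones are counted.
#' @param k_plus_1 Mutation count of the clones counted (default 1: single
#'   mutations).
#' @return Expected number of distinct mutations (0 when `u = 0`).
#' @examples
#' expected_diversity(hierarchy_params(), 31)       # approx 30
#' expected_diversity(hierarchy_params(epsilon = 0.75), 31)  # approx 28000
#' @export
expected_diversity <- function(params, i, k_plus_1 = 1) {
  diversity_with_exclusions(params, i, integer(0), k_plus_1)
}

#' Expected diversity with late-compartment contributions removed
#'
#' Same count as [expected_diversity()] but with the contributions of the
#' compartments in `exclude` removed from the sum: clones whose counted
#' contribution arises in an excluded compartment are not counted, while
#' contributions accumulated upstream still are. Used to discard the
#' expected-to-be-tiny clones produced during the last differentiation
#' steps when comparing with sequencing detection limits.
#'
#' @inheritParams expected_diversity
#' @param exclude Integer vector of compartments whose contributions are
#'   dropped (subset of `1..i`).
#' @return Expected number of distinct mutations.
#' @examples
#' hp <- hierarchy_params(epsilon = 0.78)
#' diversity_with_exclusions(hp, 31, exclude = c(30, 31))
#' @export
diversity_with_exclusions <- function(params, i, exclude = integer(0),
                                      k_plus_1 = 1) {
  stopifnot(inherits(params, "hierarchy_params"))
  if (any(params$epsilon <= 0)) stop("expected diversity requires epsilon > 0")
  if (k_plus_1 < 1 || k_plus_1 > params$k_max)
    stop("k_plus_1 must lie in 1..k_max")
  if (length(exclude) && (any(exclude < 1) || any(exclude > i)))
    stop("excluded compartments must lie in 1..i")
  if (params$u == 0) return(0)
  f <- params$founder_compartment
  js <- setdiff(f:i, as.integer(exclude))
  if (!length(js)) return(0)
  if (is_neutral(params)) {
    lw <- vapply(js, function(j) capacity_neutral(params, j, k_plus_1, log = TRUE),
                 numeric(1))
    mx <- max(lw)
    params$u * exp(mx) * sum(exp(lw - mx))
  } else {
    ct <- capacity_table(params)
    if (any(ct$divergent[js, k_plus_1 + 1]))
      stop("divergent capacity (alpha <= 1/2) in the requested range")
    params$u * sum(ct$W[js, k_plus_1 + 1])
  }
}

#' Linear error propagation of the expected diversity
#'
#' First-order sensitivity of [expected_diversity()] to the uncertainties
#' of the mutation probability and the differentiation probability:
#' \deqn{\Delta D = |\partial D/\partial u| \Delta u +
#'                 |\partial D/\partial \epsilon| \Delta \epsilon,}
#' with analytic partial derivatives of the closed form. The two
#' contributions are reported separately; each is linear in its input
#' uncertainty. The strong `epsilon` dependence of the diversity makes the
#' `Delta epsilon` term dominate at the haematopoietic parameter point.
#'
#' @inheritParams expected_diversity
#' @param delta_u Uncertainty of the mutation probability (>= 0).
#' @param delta_eps Uncertainty of the differentiation probability (>= 0).
#' @return Object of class `error_budget`: list with `delta_total`,
#'   `contribution_u`, `contribution_eps`, the partials `dD_du`, `dD_deps`,
#'   and the inputs.
#' @examples
#' diversity_error_budget(hierarchy_params(), 31, 1e-7, 0.01)
#' @export
diversity_error_budget <- function(params, i, delta_u, delta_eps, k_plus_1 = 1) {
  stopifnot(inherits(params, "hierarchy_params"), delta_u >= 0, delta_eps >= 0)
  eps <- neutral_epsilon(params)
  u <- params$u
  f <- params$founder_compartment
  m <- k_plus_1
  al <- eps + u; y <- 2 * al - 1
  A <- 2 * eps / y
  n <- i - f + 1
  d <- seq_len(n)  # depth of compartment j = f..i
  wgt <- choose(d - 1 + m, m) * A^(d - 1)
  S <- sum(wgt)
  Sp <- sum(choose(d - 1 + m, m) * (d - 1) * A^(d - 2))  # dS/dA
  # D = u^(m+1) * alpha / y^(m+1) * S(A)
  D <- u^(m + 1) * al / y^(m + 1) * S
  dlnD_du <- (m + 1) / u + 1 / al - 2 * (m + 1) / y + (Sp / S) * (-2 * A / y)
  dlnD_de <- 1 / al - 2 * (m + 1) / y + (Sp / S) * (2 / y) * (1 - A)
  dD_du <- D * dlnD_du
  dD_de <- D * dlnD_de
  cu <- abs(dD_du) * delta_u
  ce <- abs(dD_de) * delta_eps
  structure(list(diversity = D, delta_total = cu + ce,
                 contribution_u = cu, contribution_eps = ce,
                 dD_du = dD_du, dD_deps = dD_de,
                 delta_u = delta_u, delta_eps = delta_eps),
            class = "error_budget")
}

#' @export
print.error_budget <- function(x, ...) {
  cat(sprintf("diversity %.4g; Delta D = %.4g (u-term %.4g, eps-term %.4g)\n",
              x$diversity, x$delta_total, x$contribution_u, x$contribution_eps))
  invisible(x)
}

# ---- childhood-ALL case study -----------------------------------------

#' Steady-state reference population of the unperturbed hierarchy
#'
#' Healthy background population against which a mutant clone's burden is
#' measured. The hierarchy is fed by `n_stem` stem cells dividing at rate
#' `r0` (with the haematopoietic defaults: one stem-cell division per time
#' unit), exporting `2 * epsilon * r0 * n_stem` cells per time unit into
#' compartment 1; each downstream compartment balances influx against net
#' loss, giving `N_1 = 2 eps r0 n_stem / ((2 alpha - 1) r_1)` and the
#' geometric growth `N_(i+1) = N_i * (2 eps / (2 alpha - 1)) / gamma`.
#'
#' @param params Healthy [hierarchy_params()] (haematopoietic defaults).
#' @param n_stem Number of stem cells feeding the hierarchy.
#' @param compartment Compartment whose steady-state size is returned
#'   (default: the last, mature compartment).
#' @return Expected steady-state cell count.
#' @examples
#' reference_population(hierarchy_params())  # about 2.7e11 mature cells
#' @export
reference_population <- function(params, n_stem = 400,
                                 compartment = params$n_compartments) {
  stopifnot(inherits(params, "hierarchy_params"))
  eps <- neutral_epsilon(params)
  al <- eps + params$u
  if (al <= 0.5) stop("no steady state: accumulation regime")
  A <- 2 * eps / (2 * al - 1)
  N1 <- 2 * eps * params$r0 * n_stem / ((2 * al - 1) * params$rates[1])
  N1 * (A / params$gamma)^(compartment - 1)
}

#' Constraint box of the tumour-burden case study
#'
#' Bundles the observational constraints used to infer the differentiation
#' probability of a mutant clone: founder cell count, the plausible range
#' of the cancer-cell fraction at diagnosis, and the diagnosis time window.
#'
#' @param founder_count Mutant founder cells placed in compartment 1.
#' @param burden_range Length-2 fraction range of cancer cells at diagnosis.
#' @param window_months Length-2 diagnosis window in months after the
#'   founder lesion.
#' @param n_stem Stem cells feeding the healthy reference hierarchy.
#' @return Object of class `burden_constraints`.
#' @export
burden_constraints <- function(founder_count = 100,
                               burden_range = c(0.10, 0.75),
                               window_months = c(48, 77),
                               n_stem = 400) {
  stopifnot(length(burden_range) == 2, all(burden_range > 0),
            all(burden_range <= 1), diff(burden_range) >= 0,
            length(window_months) == 2, all(window_months > 0),
            diff(window_months) >= 0, founder_count >= 1)
  structure(list(founder_count = founder_count, burden_range = burden_range,
                 window_months = window_months, n_stem = n_stem),
            class = "burden_constraints")
}

# total mutant cells (all mutation counts) in the mature compartment at time t;
# summing the class equations over k cancels the mutation fluxes, so the total
# follows the unmutated closed form with u = 0
mutant_population <- function(params, epsilon_mutant, n0, t) {
  hp <- hierarchy_params(n_compartments = params$n_compartments,
                         gamma = params$gamma, r0 = params$r0, u = 0,
                         epsilon = epsilon_mutant, n0 = n0,
                         founder_compartment = params$founder_compartment,
                         k_max = 0)
  closed_form_unmutated(hp, params$n_compartments, t)
}

# cancer-cell fraction in the mature compartment: mutant / (healthy + mutant)
mutant_burden_fraction <- function(params, epsilon_mutant, n0, t, reference) {
  Nm <- mutant_population(params, epsilon_mutant, n0, t)
  Nm / (reference + Nm)
}

#' Time for a mutant clone to reach a tumour burden
#'
#' First time (reported in months) at which the clone founded by
#' `constraints$founder_count` cells with differentiation probability
#' `epsilon_mutant` makes up the fraction `burden` of the mature
#' compartment, against the healthy steady-state reference. The clonal wave
#' is transient, so a burden that exceeds the wave's peak fraction is
#' flagged unreachable (`NA` with attribute `reason`).
#'
#' @param params Healthy parameter set (defines the hierarchy and the
#'   reference population).
#' @param epsilon_mutant Differentiation probability of the mutant clone.
#' @param constraints A [burden_constraints()] object.
#' @param burden Burden fraction to reach; defaults to the lower end of the
#'   constraint range.
#' @return Time in months, or `NA` if the burden is never reached.
#' @examples
#' time_to_burden(hierarchy_params(), 0.80, burden_constraints())
#' @export
time_to_burden <- function(params, epsilon_mutant, constraints,
                           burden = constraints$burden_range[1]) {
  stopifnot(inherits(constraints, "burden_constraints"))
  ref <- reference_population(params, n_stem = constraints$n_stem)
  f <- function(t) mutant_burden_fraction(params, epsilon_mutant,
                                          constraints$founder_count, t, ref)
  al_m <- epsilon_mutant + 0  # mutant clone evolves without further mutation here
  if (al_m <= 0.5) stop("accumulation regime: use alpha > 1/2 for the mutant clone")
  # wave peak occurs within a few multiples of the slowest compartment's
  # residence time
  t_hi <- min(1e8, max(1e4, 100 / ((2 * al_m - 1) * params$rates[1])))
  pk <- stats::optimize(function(t) -f(t), c(1e-3, t_hi), tol = 1e-3)
  fmax <- -pk$objective
  if (fmax < burden) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("unreachable: peak burden %.3g < %.3g",
                                   fmax, burden)
    return(out)
  }
  root <- tryCatch(
    stats::uniroot(function(t) f(t) - burden, c(1e-3, pk$minimum),
                   tol = 1e-6)$root,
    error = function(e) pk$minimum)  # burden met only at the peak itself
  model_time_to_months(root, 1 / params$r0)
}

#' Infer the mutant differentiation probability from tumour burden
#'
#' Inverts the clonal-wave forward map against the observed constraint box:
#' the lower endpoint is the differentiation probability whose clone reaches
#' the upper burden limit at the earliest diagnosis time, the upper endpoint
#' the one reaching the lower burden limit at the latest diagnosis time
#' (smaller `epsilon` means more self-renewal, hence a larger, earlier
#' clone). Bisection to an `epsilon` tolerance of 1e-4.
#'
#' @inheritParams time_to_burden
#' @return Object of class `epsilon_interval`: list with `epsilon_range`,
#'   the generating `(burden, months)` pairs, and the constraints.
#' @examples
#' \donttest{
#' estimate_epsilon_from_burden(hierarchy_params(), burden_constraints())
#' }
#' @export
estimate_epsilon_from_burden <- function(params, constraints) {
  stopifnot(inherits(constraints, "burden_constraints"))
  eps_h <- neutral_epsilon(params)
  solve_eps <- function(burden, months) {
    g <- function(e) {
      tt <- time_to_burden(params, e, constraints, burden)
      if (is.na(tt)) return(1e6)  # unreachable: clone too small
      tt - months
    }
    # time to burden is U-shaped in epsilon (slow growth near 1/2, vanishing
    # clone near 1); the observationally relevant solution is the one closest
    # to the healthy value, on the increasing branch: walk down from the top
    # until the load is reached early enough, then bisect
    hi <- 1 - params$u - 1e-6
    e <- hi
    repeat {
      if (e <= 0.5 + params$u + 0.01)
        stop("infeasible constraints: no epsilon in (1/2, 1] reaches the ",
             "burden in the window")
      if (g(e) < 0) break
      e <- e - 0.005
    }
    stats::uniroot(g, c(e, min(e + 0.005, hi)), tol = 1e-4)$root
  }
  e_lo <- solve_eps(constraints$burden_range[2], constraints$window_months[1])
  e_hi <- solve_eps(constraints$burden_range[1], constraints$window_months[2])
  structure(list(epsilon_range = c(e_lo, e_hi),
                 at = list(lower = c(burden = constraints$burden_range[2],
                                     months = constraints$window_months[1]),
                           upper = c(burden = constraints$burden_range[1],
                                     months = constraints$window_months[2])),
                 constraints = constraints, epsilon_healthy = eps_h),
            class = "epsilon_interval")
}

#' @export
print.epsilon_interval <- function(x, ...) {
  cat(sprintf("inferred differentiation probability: [%.4f, %.4f] (healthy %.2f)\n",
              x$epsilon_range[1], x$epsilon_range[2], x$epsilon_healthy))
  invisible(x)
}

#' Childhood-ALL case-study pipeline
#'
#' Runs the complete §-style case study: inverts the differentiation
#' probability of the mutant clone from the burden constraint box, computes
#' the time to reach the load at both interval endpoints, and predicts the
#' range of distinct (passenger) mutations expected in the mature
#' compartment, with and without the contributions of the last
#' differentiation steps.
#'
#' @inheritParams time_to_burden
#' @param u_mutant Mutation probability used for the diversity predictions.
#' @param exclude Late compartments dropped in the reduced diversity range.
#' @return List with `epsilon_interval`, `months_to_load`,
#'   `diversity_range`, `diversity_range_excluded`.
#' @export
all_case_study <- function(params = hierarchy_params(),
                           constraints = burden_constraints(),
                           u_mutant = 1e-6,
                           exclude = c(30, 31)) {
  inv <- estimate_epsilon_from_burden(params, constraints)
  er <- inv$epsilon_range
  months <- c(time_to_burden(params, er[1], constraints,
                             constraints$burden_range[2]),
              time_to_burden(params, er[2], constraints,
                             constraints$burden_range[1]))
  n <- params$n_compartments
  div_at <- function(e, excl = integer(0)) {
    hp <- hierarchy_params(n_compartments = n, gamma = params$gamma,
                           r0 = params$r0, u = u_mutant, epsilon = e,
                           n0 = 1, k_max = params$k_max)
    diversity_with_exclusions(hp, n, excl)
  }
  # larger epsilon -> smaller clone -> fewer distinct mutations
  list(epsilon_interval = inv,
       months_to_load = months,
       diversity_range = c(div_at(er[2]), div_at(er[1])),
       diversity_range_excluded = c(div_at(er[2], exclude), div_at(er[1], exclude)))
}
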