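#' Time derivative of the expected occupancy grid
#'
#' Assembles the right-hand side of the coupled linear system for the
#' expected number `N[i, k]` of cells in compartment `i` carrying `k`
#' mutations. Class `(i, k)` gains cells by differentiation influx from
#' upstream (`2 * epsilon[i-1, k] * r[i-1] * N[i-1, k]`; two daughters per
#' differentiating division), by mutation of `(i, k-1)` cells
#' (`u * r[i] * N[i, k-1]`) and by self-renewal
#' (`(1 - epsilon - u) * r[i] * N[i, k]`), and loses the dividing cell at
#' every division, so the net local rate is `(1 - 2 * (epsilon + u)) * r[i]`.
#' Mutations out of the truncation class `k_max` leave the tracked system;
#' keep `k_max` generous and monitor the mass in the last class.
#'
#' @param state Numeric matrix of occupancies with `n_compartments` rows and
#'   `k_max + 1` columns.
#' @param params A [hierarchy_params()] object.
#' @return Matrix of the same shape with time derivatives.
#' @examples
#' hp <- hierarchy_params(n_compartments = 2, k_max = 1, u = 0, epsilon = 0.85)
#' s <- matrix(0, 2, 2); s[1, 1] <- 1
#' flow_rates(s, hp)[1, 1] / hp$rates[1]  # net per-capita rate 1 - 2 * alpha
#' @export
flow_rates <- function(state, params) {
  n <- params$n_compartments; K <- params$k_max
  if (!is.matrix(state) || nrow(state) != n || ncol(state) != K + 1)
    stop("dimension mismatch: state must be n_compartments x (k_max + 1)")
  r <- params$rates; u <- params$u; eps <- params$epsilon
  d <- state * (1 - 2 * (eps + u)) * r            # self-renewal gain minus all losses
  if (n > 1) {
    influx <- 2 * eps[-n, , drop = FALSE] * r[-n] * state[-n, , drop = FALSE]
    d[-1, ] <- d[-1, ] + influx
  }
  if (K > 0)
    d[, -1] <- d[, -1] + u * r * state[, -(K + 1), drop = FALSE]
  dimnames(d) <- NULL
  d
}

#' Integrate the expected clonal dynamics
#'
#' Numerically solves the coupled linear system for the expected occupancy
#' of every (compartment, mutation count) class, starting from `n0` founder
#' cells without mutations in the founder compartment. Serves as the
#' independent oracle for all closed-form solutions.
#'
#' @param params A [hierarchy_params()] object.
#' @param times Increasing vector of time points starting at 0.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `trajectory_grid` object: list with `times`, `counts` (array of
#'   dimension time x compartment x mutation count) and `params`.
#' @examples
#' hp <- preset_params("test-small")
#' tg <- integrate_dynamics(hp, seq(0, 500, by = 50))
#' tg$counts[1, 1, "0"]  # initial condition n0
#' @export
integrate_dynamics <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "hierarchy_params"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must start at 0 and increase strictly")
  n <- params$n_compartments; K <- params$k_max
  y0 <- matrix(0, n, K + 1)
  y0[params$founder_compartment, 1] <- params$n0
  rhs <- function(t, y, p) {
    list(as.vector(flow_rates(matrix(y, n, K + 1), params)))
  }
  sol <- deSolve::ode(y = as.vector(y0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("ODE solver failed; see deSolve diagnostics")
  counts <- array(sol[, -1], dim = c(length(times), n, K + 1),
                  dimnames = list(NULL, compartment = NULL, k = 0:K))
  structure(list(times = times, counts = counts, params = params),
            class = "trajectory_grid")
}

#' @export
print.trajectory_grid <- function(x, ...) {
  cat(sprintf("trajectory_grid: %d time points, %d compartments, k = 0..%d\n",
              length(x$times), dim(x$counts)[2], dim(x$counts)[3] - 1))
  invisible(x)
}

#' @export
as.data.frame.trajectory_grid <- function(x, ...) {
  d <- dim(x$counts)
  data.frame(
    time = rep(x$times, times = d[2] * d[3]),
    compartment = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    k = rep(0:(d[3] - 1), each = d[1] * d[2]),
    count = as.vector(x$counts))
}

# ---- closed forms ------------------------------------------------------

# Decay/growth exponents a_j = (1 - 2 alpha) r_j of the linear cascade.
# The closed forms are Bateman-type sums over exp(a_j t) and require the
# a_j (equivalently the r_j) to be pairwise distinct.
wave_exponents <- function(params) {
  eps <- neutral_epsilon(params)
  (1 - 2 * (eps + params$u)) * params$rates
}

check_distinct_rates <- function(params) {
  r <- params$rates
  if (length(r) > 1 && min(abs(diff(r)) / r[-1]) < 1e-9)
    stop("degenerate rates: closed forms divide by rate differences; ",
         "use integrate_dynamics() for gamma = 1")
}

# Exponential-polynomial coefficients of the closed-form solution:
# N_i^k(t) = n0 * sum_{j,m} M[[i]][[k+1]][j, m+1] * t^m * exp(a_j t).
# Built by solving the cascade recursively with exact integration of
# t^m exp(a s) sources; repeated exponents (mutation within one compartment)
# raise the polynomial degree, which is how the combinatoric coefficients
# for any number of mutations are generated.
wave_coefficients <- function(params, i_max, k_need) {
  f <- params$founder_compartment
  a <- wave_exponents(params)
  eps <- neutral_epsilon(params)
  b <- 2 * eps * params$rates
  u <- params$u
  n <- params$n_compartments
  M <- vector("list", i_max)
  for (i in seq_len(i_max)) M[[i]] <- vector("list", k_need + 1)
  for (k in 0:k_need) {
    for (i in f:i_max) {
      if (i == f && k == 0) {
        cm <- matrix(0, n, 1); cm[f, 1] <- 1
        M[[i]][[1]] <- cm
        next
      }
      src <- matrix(0, n, k + 1)  # degree of class-k solutions is at most k
      if (i > f) {
        up <- M[[i - 1]][[k + 1]]
        src[, seq_len(ncol(up))] <- src[, seq_len(ncol(up))] + b[i - 1] * up
      }
      if (k > 0) {
        mu <- M[[i]][[k]]
        src[, seq_len(ncol(mu))] <- src[, seq_len(ncol(mu))] + u * params$rates[i] * mu
      }
      cm <- matrix(0, n, k + 1)
      for (j in f:i) {
        for (m in 0:(ncol(src) - 1)) {
          s <- src[j, m + 1]
          if (s == 0) next
          if (j == i) {
            cm[i, m + 2] <- cm[i, m + 2] + s / (m + 1)
          } else {
            d <- a[j] - a[i]
            for (q in 0:m)
              cm[j, m - q + 1] <- cm[j, m - q + 1] +
                s * (-1)^q * prod(seq_len(m)[seq_len(q) + m - q]) / d^(q + 1)
            cm[i, 1] <- cm[i, 1] - s * (-1)^m * factorial(m) / d^(m + 1)
          }
        }
      }
      M[[i]][[k + 1]] <- cm
    }
  }
  list(M = M, a = a)
}

eval_exp_poly <- function(cm, a, t) {
  out <- numeric(length(t))
  for (j in which(rowSums(cm != 0) > 0)) {
    pj <- numeric(length(t))
    for (m in which(cm[j, ] != 0)) pj <- pj + cm[j, m] * t^(m - 1)
    out <- out + pj * exp(a[j] * t)
  }
  out
}

#' Closed-form clonal wave of unmutated cells
#'
#' Expected number of cells without mutations in compartment `i` at time
#' `t`, from the Bateman-type solution of the linear cascade. Products over
#' compartments are accumulated in log space so the 31-compartment
#' haematopoietic hierarchy evaluates without overflow.
#'
#' @param params Neutral [hierarchy_params()] (constant differentiation
#'   probability); rates must be pairwise distinct (`gamma != 1`).
#' @param i Compartment index.
#' @param t Time (vectorized).
#' @return Expected cell count (same length as `t`).
#' @examples
#' hp <- hierarchy_params(n0 = 1000)
#' closed_form_unmutated(hp, 1, 0)  # n0
#' @export
closed_form_unmutated <- function(params, i, t) {
  stopifnot(inherits(params, "hierarchy_params"))
  check_distinct_rates(params)
  f <- params$founder_compartment
  if (i < f) return(rep(0, length(t)))
  a <- wave_exponents(params)
  eps <- neutral_epsilon(params)
  if (i == f) return(params$n0 * exp(a[f] * t))
  jj <- f:i
  log_b <- sum(log(2 * eps * params$rates[f:(i - 1)]))
  out <- numeric(length(t))
  # signed log-space accumulation of sum_j exp(a_j t) / prod_{l != j} (a_l - a_j)
  lw <- sgn <- numeric(length(jj))
  for (idx in seq_along(jj)) {
    j <- jj[idx]
    dl <- a[j] - a[setdiff(jj, j)]
    lw[idx] <- log_b - sum(log(abs(dl)))
    sgn[idx] <- prod(sign(dl))
  }
  for (ti in seq_along(t)) {
    le <- lw + a[jj] * t[ti]
    mx <- max(le)
    out[ti] <- sum(sgn * exp(le - mx)) * exp(mx)
  }
  params$n0 * out
}

#' Closed-form clonal wave of multi-mutant cells
#'
#' Expected number of cells carrying `k` mutations in compartment `i` at
#' time `t`, for neutral parameters. The combinatoric coefficients of the
#' printed small-`k` solutions are generated for arbitrary `k` by the same
#' recursive construction (mutation within a compartment re-uses that
#' compartment's exponent and raises the polynomial degree in `t`).
#'
#' @inheritParams closed_form_unmutated
#' @param k Mutation count (`0 <= k <= k_max`).
#' @return Expected cell count (same length as `t`).
#' @examples
#' hp <- preset_params("test-small")
#' closed_form_multimutant(hp, 2, 1, 400)
#' @export
closed_form_multimutant <- function(params, i, k, t) {
  stopifnot(inherits(params, "hierarchy_params"))
  if (k > params$k_max) stop("k exceeds k_max truncation")
  if (k < 0) stop("k must be non-negative")
  check_distinct_rates(params)
  f <- params$founder_compartment
  if (i < f) return(rep(0, length(t)))
  if (params$u == 0 && k >= 1) return(rep(0, length(t)))
  if (k == 0) return(closed_form_unmutated(params, i, t))
  wc <- wave_coefficients(params, i, k)
  params$n0 * eval_exp_poly(wc$M[[i]][[k + 1]], wc$a, t)
}

#' Peak of the clonal wave in the founder compartment
#'
#' Time and height of the maximum of the expected `k`-mutant cell count in
#' the founder compartment, where the solution is
#' `n0 * (u * r * t)^k / k! * exp((1 - 2 * alpha) * r * t)`. The peak time
#' `k / ((2 * alpha - 1) * r)` grows linearly in `k`; the peak height
#' carries the `u^k` suppression. Both the exact maximum and its Stirling
#' approximation `n0 * (u / (2 * alpha - 1))^k / sqrt(2 * pi * k)` are
#' returned.
#'
#' @inheritParams closed_form_unmutated
#' @param k Mutation count.
#' @return A list of class `peak_summary` with `k`, `t_peak`, `n_peak`
#'   (exact) and `n_peak_stirling`.
#' @export
peak_summary <- function(params, k) {
  stopifnot(inherits(params, "hierarchy_params"))
  if (params$regime != "wave") stop("no finite peak: accumulation regime (alpha <= 1/2)")
  eps <- neutral_epsilon(params)
  alpha <- eps + params$u
  r <- params$rates[params$founder_compartment]
  if (k == 0) {
    out <- list(k = 0, t_peak = 0, n_peak = params$n0, n_peak_stirling = NA_real_)
  } else {
    t_peak <- k / ((2 * alpha - 1) * r)
    n_peak <- params$n0 * (params$u / (2 * alpha - 1))^k * k^k * exp(-k) / factorial(k)
    n_st <- params$n0 * (params$u / (2 * alpha - 1))^k / sqrt(2 * pi * k)
    out <- list(k = k, t_peak = t_peak, n_peak = n_peak, n_peak_stirling = n_st)
  }
  structure(out, class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("wave peak (k = %d): t = %g, count = %g (Stirling approx %g)\n",
              x$k, x$t_peak, x$n_peak, x$n_peak_stirling))
  invisible(x)
}

# definite integral of t^m exp(a t) on [0, T] (a != 0); T = Inf allowed for a < 0
int_power_exp <- function(m, a, T) {
  if (a == 0) return(T^(m + 1) / (m + 1))
  if (is.infinite(T)) {
    if (a > 0) return(Inf)
    return(factorial(m) / (-a)^(m + 1))
  }
  q <- 0:m
  e <- exp(a * T)
  sum((-1)^q * factorial(m) / factorial(m - q) * T^(m - q) / a^(q + 1)) * e -
    (-1)^m * factorial(m) / a^(m + 1)
}

#' Cumulative cell production of a class
#'
#' Number of cells of the founder lineage in compartment `i` carrying `k`
#' mutations produced up to time `t`, counted at departure (each cell leaves
#' its class exactly once, by differentiation or mutation), i.e.
#' `alpha * r_i * integral of N_i^k`. As `t` grows this approaches the
#' reproductive capacity [capacity_neutral()] in the wave regime and is
#' flagged infinite in the accumulation regime.
#'
#' @inheritParams closed_form_multimutant
#' @param t Time horizon; `Inf` gives the total production.
#' @return Produced-cell count (same length as `t`).
#' @examples
#' hp <- preset_params("test-small")
#' cumulative_count(hp, 2, 0, Inf)
#' @export
cumulative_count <- function(params, i, k, t) {
  stopifnot(inherits(params, "hierarchy_params"))
  check_distinct_rates(params)
  eps <- neutral_epsilon(params)
  alpha <- eps + params$u
  f <- params$founder_compartment
  if (i < f || (params$u == 0 && k >= 1)) return(rep(0, length(t)))
  wc <- wave_coefficients(params, i, k)
  cm <- wc$M[[i]][[k + 1]]
  out <- numeric(length(t))
  for (ti in seq_along(t)) {
    acc <- 0
    for (j in which(rowSums(cm != 0) > 0))
      for (m in which(cm[j, ] != 0))
        acc <- acc + cm[j, m] * int_power_exp(m - 1, wc$a[j], t[ti])
    out[ti] <- acc
  }
  params$n0 * alpha * params$rates[i] * out
}
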