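#' Reproductive capacity of a single cell in its own compartment
#'
#' Expected total number of offspring cells, counted at departure, that a
#' single cell produces within its compartment before its lineage has left
#' (by differentiation or mutation). A cell leaves after exactly `l`
#' divisions with probability `(eps + u) * (1 - eps - u)^(l - 1)`, by which
#' time the local population has doubled `l - 1` times, so the capacity is
#' the geometric sum `sum_l 2^(l-1) * (eps + u) * (1 - eps - u)^(l - 1) =
#' (eps + u) / (2 * (eps + u) - 1)`. For `eps + u <= 1/2` the sum diverges:
#' offspring are produced faster than the compartment is vacated.
#'
#' @param epsilon Differentiation probability.
#' @param u Mutation probability per division.
#' @return The capacity; `Inf` when `epsilon + u <= 1/2`.
#' @examples
#' founder_capacity(0.85, 0)  # 0.85 / 0.70
#' founder_capacity(0.4, 0)   # Inf: accumulation regime
#' @export
founder_capacity <- function(epsilon, u = 0) {
  alpha <- epsilon + u
  if (alpha <= 0 || alpha > 1) stop("epsilon + u must lie in (0, 1]")
  if (alpha <= 0.5) return(Inf)
  alpha / (2 * alpha - 1)
}

#' Reproductive-capacity table for arbitrary parameters
#'
#' Fills the table `W[i, k]` of expected total progeny (counted at
#' departure) of one founder cell, for every compartment `i` and mutation
#' count `k`, by the double recursion: cells enter class `(i, k)` by
#' differentiation from `(i-1, k)` (two daughters per differentiating
#' departure) or by mutation from `(i, k-1)` (one cell per mutating
#' departure), and each entering cell is amplified by the within-compartment
#' capacity `alpha / (2 * alpha - 1)` of its class:
#' \deqn{W_i^k = \left[\frac{2\epsilon_{i-1}^k}{\alpha_{i-1}^k} W_{i-1}^k +
#'   \frac{u}{\alpha_i^{k-1}} W_i^{k-1}\right]
#'   \frac{\alpha_i^k}{2\alpha_i^k - 1}.}
#' The recursion allows any per-(compartment, mutation count) table of
#' differentiation probabilities. Entries whose own class, or any class they
#' draw from, has `alpha <= 1/2` are flagged divergent and propagate the
#' flag downstream.
#'
#' Entries are accumulated in log space, so the 31-compartment hierarchy
#' (capacities of order `1e12`) evaluates exactly.
#'
#' @param params A [hierarchy_params()] object.
#' @return Object of class `capacity_table`: list with matrix `W`
#'   (compartment x mutation count, `NA` rows upstream of the founder),
#'   logical matrix `divergent`, and `params`.
#' @examples
#' ct <- capacity_table(preset_params("test-small"))
#' ct$W[1, "0"]  # founder_capacity(0.85, 1e-3)
#' @export
capacity_table <- function(params) {
  stopifnot(inherits(params, "hierarchy_params"))
  n <- params$n_compartments; K <- params$k_max
  f <- params$founder_compartment
  u <- params$u
  logW <- matrix(-Inf, n, K + 1, dimnames = list(compartment = NULL, k = 0:K))
  div <- matrix(FALSE, n, K + 1, dimnames = dimnames(logW))
  for (k in 0:K) {
    for (i in f:n) {
      al <- alpha_at(params, i, k)
      terms <- numeric(0); bad <- FALSE
      if (i == f && k == 0) {
        terms <- 0  # log(1): the founder cell itself enters the class
      } else {
        if (i > f) {
          al_up <- alpha_at(params, i - 1, k)
          terms <- c(terms, log(2 * eps_at(params, i - 1, k) / al_up) + logW[i - 1, k + 1])
          bad <- bad || div[i - 1, k + 1]
        }
        if (k > 0 && u > 0) {
          al_mut <- alpha_at(params, i, k - 1)
          terms <- c(terms, log(u / al_mut) + logW[i, k])
          bad <- bad || div[i, k]
        }
      }
      if (al <= 0.5) bad <- TRUE
      div[i, k + 1] <- bad
      if (!bad && length(terms)) {
        mx <- max(terms)
        logW[i, k + 1] <- if (is.finite(mx)) mx + log(sum(exp(terms - mx))) +
          log(al / (2 * al - 1)) else -Inf
      }
    }
  }
  W <- exp(logW)
  W[div] <- Inf
  if (f > 1) W[seq_len(f - 1), ] <- NA_real_
  structure(list(W = W, log_W = logW, divergent = div, params = params),
            class = "capacity_table")
}

#' @export
print.capacity_table <- function(x, ...) {
  n <- nrow(x$W)
  cat(sprintf("capacity_table: %d compartments, k = 0..%d\n", n, ncol(x$W) - 1))
  if (any(x$divergent)) cat(sprintf("  %d divergent entries (alpha <= 1/2)\n",
                                    sum(x$divergent)))
  cat(sprintf("  W[last, 0] = %g\n", x$W[n, 1]))
  invisible(x)
}

#' Closed-form reproductive capacity for neutral mutations
#'
#' For constant differentiation probability and mutation rate the capacity
#' recursion solves in closed form:
#' \deqn{W_i^k = \frac{\alpha}{2\alpha - 1}
#'   \left(\frac{2\epsilon}{2\alpha-1}\right)^{i-f}
#'   \left(\frac{u}{2\alpha-1}\right)^{k} \binom{i - f + k}{k},}
#' with `f` the founder compartment and `alpha = epsilon + u`: every path of
#' `i - f` differentiation steps and `k` mutation steps contributes the same
#' product of per-step amplifications, and the binomial counts the path
#' orderings. Multi-mutants carry the `u^k` suppression; the capacity is
#' independent of the proliferation rates (`gamma`, `r0`).
#'
#' @param params Neutral [hierarchy_params()].
#' @param i Compartment index (at or downstream of the founder).
#' @param k Mutation count.
#' @param log Return the natural logarithm (useful at 31 compartments).
#' @return Capacity value (or its log); `Inf` when `alpha <= 1/2`.
#' @examples
#' capacity_neutral(hierarchy_params(), 31, 0)  # about 3.7e11 cells
#' @export
capacity_neutral <- function(params, i, k, log = FALSE) {
  stopifnot(inherits(params, "hierarchy_params"))
  eps <- neutral_epsilon(params)
  alpha <- eps + params$u
  f <- params$founder_compartment
  if (i < f) stop("compartment upstream of the founder")
  if (alpha <= 0.5) return(Inf)
  if (k > 0 && params$u == 0) return(if (log) -Inf else 0)
  lw <- log(alpha / (2 * alpha - 1)) +
    (i - f) * log(2 * eps / (2 * alpha - 1)) +
    (if (k > 0) k * log(params$u / (2 * alpha - 1)) else 0) +
    lchoose(i - f + k, k)
  if (log) lw else exp(lw)
}

#' Suppression and amplification ratios of the capacity table
#'
#' The mutation-load ratio `W_i^k / W_i^(k-1) = u / (2 alpha - 1) *
#' (i - f + k) / k` grows with compartment number but flattens in `k`, and
#' is constant (equal to `u / (2 alpha - 1)`) at the founder compartment.
#' The compartment-growth ratio `W_(i+1)^k / W_i^k = 2 eps / (2 alpha - 1) *
#' (i - f + 1 + k) / (i - f + 1)` is constant for unmutated cells and its
#' `k`-dependence is suppressed by the accumulated compartment depth.
#'
#' @inheritParams capacity_neutral
#' @return Named list with `mutation_load_ratio` and `compartment_growth_ratio`.
#' @export
hierarchy_ratios <- function(params, i, k) {
  stopifnot(inherits(params, "hierarchy_params"))
  eps <- neutral_epsilon(params)
  alpha <- eps + params$u
  f <- params$founder_compartment
  if (alpha <= 0.5) stop("ratios undefined in the accumulation regime")
  if (i < f) stop("compartment upstream of the founder")
  depth <- i - f + 1  # founder compartment has depth 1
  mut <- if (k == 0) NA_real_ else
    params$u / (2 * alpha - 1) * (depth - 1 + k) / k
  grow <- 2 * eps / (2 * alpha - 1) * (depth + k) / depth
  list(mutation_load_ratio = mut, compartment_growth_ratio = grow)
}
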