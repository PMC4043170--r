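# small fixtures shared across the suite

tiny_params <- function(eps = 0.85, u = 1e-3, n = 4, k_max = 3, n0 = 1, ...) {
  hierarchy_params(n_compartments = n, epsilon = eps, u = u, n0 = n0,
                   k_max = k_max, ...)
}

# ODE oracle evaluated at a few times for one class
ode_counts <- function(params, i, k, times) {
  tg <- integrate_dynamics(params, c(0, times), rtol = 1e-11, atol = 1e-14)
  tg$counts[-1, i, k + 1]
}

# expected number of distinct k-fold mutation events founded in compartments
# up to i (clone-founding oracle for the stochastic census): u * divisions of
# (k-1)-mutant cells = (u / alpha) * sum_j W_j^(k-1)
expected_foundings <- function(params, i, k) {
  al <- neutral_alpha(params)
  (params$u / al) *
    sum(vapply(params$founder_compartment:i,
               function(j) capacity_neutral(params, j, k - 1), numeric(1)))
}

neutral_alpha <- function(params) params$epsilon[1, 1] + params$u
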