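test_that("flow rates assemble the per-class gains and losses", {
  # isolated compartment: net per-capita rate (1 - 2 eps - 2 u) * r
  hp <- hierarchy_params(n_compartments = 2, k_max = 1, u = 0, epsilon = 0.85,
                         r0 = 1 / 1.26)  # r_1 = 1
  s <- matrix(0, 2, 2); s[1, 1] <- 1
  expect_equal(flow_rates(s, hp)[1, 1], -0.7)
  # upstream feed: two daughters per differentiating division
  expect_equal(flow_rates(s, hp)[2, 1], 2 * 0.85 * 1 * 1)
  # no mutation: the k >= 1 classes stay decoupled at zero
  expect_equal(flow_rates(s, hp)[, 2], c(0, 0))
  expect_error(flow_rates(matrix(0, 3, 3), hp), "dimension mismatch")
})

test_that("integration starts from the founder initial condition and stays non-negative", {
  hp <- tiny_params(n0 = 7)
  tg <- integrate_dynamics(hp, seq(0, 1000, by = 250))
  ic <- tg$counts[1, , ]
  expect_equal(unname(ic[1, 1]), 7)
  expect_equal(sum(ic), 7)
  expect_true(all(tg$counts > -1e-8))
  expect_error(integrate_dynamics(hp, c(1, 2)), "start at 0")
})

test_that("closed forms agree with the ODE oracle across the parameter matrix", {
  times <- c(100, 400, 1200, 3000)
  for (eps in c(0.6, 0.75, 0.85)) {
    for (u in c(0, 1e-3, 1e-2)) {
      hp <- hierarchy_params(n_compartments = 5, epsilon = eps, u = u, k_max = 3)
      tg <- integrate_dynamics(hp, c(0, times), rtol = 1e-11, atol = 1e-14)
      for (i in 1:5) for (k in 0:3) {
        cf <- closed_form_multimutant(hp, i, k, times)
        od <- tg$counts[-1, i, k + 1]
        sel <- od > 1e-6
        if (any(sel))
          expect_lt(max(abs(cf[sel] - od[sel]) / od[sel]), 1e-6,
                    label = sprintf("rel err (eps=%g u=%g i=%d k=%d)", eps, u, i, k))
        if (u == 0 && k >= 1) expect_equal(cf, rep(0, length(times)))
      }
    }
  }
})

test_that("closed forms reduce correctly at the boundaries", {
  hp <- tiny_params()
  expect_equal(closed_form_unmutated(hp, 1, 0), 1)         # initial condition
  # single-compartment solution n0 exp((1 - 2 alpha) r t)
  a <- (1 - 2 * 0.851) * hp$rates[1]
  expect_equal(closed_form_unmutated(hp, 1, c(50, 500)), exp(a * c(50, 500)))
  expect_equal(closed_form_multimutant(hp, 3, 0, c(10, 100)),
               closed_form_unmutated(hp, 3, c(10, 100)))
  expect_error(closed_form_multimutant(hp, 2, 9, 1), "k_max")
  expect_error(closed_form_unmutated(hierarchy_params(gamma = 1, n_compartments = 3), 2, 1),
               "degenerate rates")
})

test_that("solutions scale linearly in the founder count and vanish in the wave regime", {
  t <- c(200, 800, 2500)
  one <- closed_form_unmutated(tiny_params(n0 = 1), 4, t)
  many <- closed_form_unmutated(tiny_params(n0 = 250), 4, t)
  expect_equal(many, 250 * one)
  # wave regime: late-time decay to zero
  expect_lt(closed_form_unmutated(tiny_params(), 4, 5e4), 1e-12)
  # accumulation regime: founder compartment grows without bound
  acc <- hierarchy_params(epsilon = 0.4, u = 0, n_compartments = 3, k_max = 0)
  expect_gt(closed_form_unmutated(acc, 1, 4000), 2 * closed_form_unmutated(acc, 1, 2000))
})

test_that("the 31-compartment haematopoietic wave evaluates stably", {
  hp <- hierarchy_params(n0 = 1000, k_max = 1)
  tg <- integrate_dynamics(hp, c(0, 2000, 6000), rtol = 1e-10, atol = 1e-8)
  for (tt in c(2000, 6000)) {
    cf <- closed_form_unmutated(hp, 31, tt)
    od <- tg$counts[match(tt, tg$times), 31, 1]
    expect_lt(abs(cf - od) / od, 1e-6)
  }
})

test_that("wave peaks are equally spaced in k and suppressed by u per extra mutation", {
  hp <- tiny_params(u = 1e-3)
  p0 <- peak_summary(hp, 0); p1 <- peak_summary(hp, 1)
  p2 <- peak_summary(hp, 2); p3 <- peak_summary(hp, 3)
  expect_equal(p0$t_peak, 0); expect_equal(p0$n_peak, hp$n0)
  expect_equal(p2$t_peak - p1$t_peak, p1$t_peak - p0$t_peak)
  expect_equal(p3$t_peak - p2$t_peak, p2$t_peak - p1$t_peak)
  expect_true(p1$n_peak > p2$n_peak && p2$n_peak > p3$n_peak)
  # peak ratio scales linearly with u
  r1 <- peak_summary(tiny_params(u = 1e-3), 2)$n_peak /
        peak_summary(tiny_params(u = 1e-3), 1)$n_peak
  r2 <- peak_summary(tiny_params(u = 1e-4), 2)$n_peak /
        peak_summary(tiny_params(u = 1e-4), 1)$n_peak
  expect_equal(r1 / r2, 10, tolerance = 0.01)
  # formula peak within 2% of the grid-search maximum of the closed form
  tt <- seq(1, 4000, by = 1)
  n1 <- closed_form_multimutant(hp, 1, 1, tt)
  expect_lt(abs(p1$t_peak - tt[which.max(n1)]) / p1$t_peak, 0.02)
  expect_equal(max(n1), p1$n_peak, tolerance = 1e-4)
  expect_equal(p1$n_peak, p1$n_peak_stirling, tolerance = 0.1)
  expect_error(peak_summary(hierarchy_params(epsilon = 0.4, u = 0), 1), "no finite peak")
})

test_that("cumulative production is monotone and converges to the reproductive capacity", {
  hp <- tiny_params(u = 1e-2, eps = 0.7)
  expect_equal(cumulative_count(hp, 2, 0, 0), 0)
  tt <- c(100, 500, 2000, 8000, Inf)
  for (i in 1:4) for (k in 0:2) {
    cc <- cumulative_count(hp, i, k, tt)
    expect_true(all(diff(cc) >= -1e-10))
    expect_equal(cc[length(tt)], capacity_neutral(hp, i, k), tolerance = 1e-4)
  }
  # divergence in the accumulation regime is flagged infinite
  acc <- hierarchy_params(epsilon = 0.4, u = 0, n_compartments = 2, k_max = 0)
  expect_identical(cumulative_count(acc, 1, 0, Inf), Inf)
})
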