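test_that("forced outcomes and determinism hold exactly", {
  hp <- hierarchy_params(n_compartments = 2, epsilon = 1, u = 0, n0 = 1, k_max = 0)
  run <- gillespie_run(hp, Inf, seed = 7)
  # founder differentiates once, two daughters appear in compartment 2 and
  # then leave the system
  expect_identical(run$events$outcome[1], "differentiate")
  expect_identical(run$events$compartment, c(1L, 2L, 2L))
  expect_true(run$extinct)
  expect_identical(gillespie_run(preset_params("test-small"), Inf, seed = 42)$events,
                   gillespie_run(preset_params("test-small"), Inf, seed = 42)$events)
})

test_that("division outcomes occur at the configured probabilities", {
  hp <- tiny_params(eps = 0.75, u = 0.05, n = 3, k_max = 6, n0 = 30)
  ev <- do.call(rbind, lapply(1:40, function(s)
    gillespie_run(hp, Inf, seed = s, max_cells = 5e4)$events))
  expect_gt(nrow(ev), 1e4)
  obs <- table(factor(ev$outcome, c("differentiate", "self-renew", "mutate")))
  gof <- chisq.test(obs, p = c(0.75, 0.20, 0.05))
  expect_gt(gof$p.value, 0.001)
})

test_that("every event changes the population by 0 or +1 except at the exits", {
  run <- gillespie_run(preset_params("test-small"), Inf, seed = 11)
  n <- run$params$n_compartments
  delta <- ifelse(run$events$outcome == "self-renew", 1L,
           ifelse(run$events$outcome == "mutate", 0L,
           ifelse(run$events$compartment < n, 1L, -1L)))
  inner <- run$events$compartment < n | run$events$outcome != "differentiate"
  expect_true(all(delta[inner] %in% c(0L, 1L)))
  # the reconstructed population returns to zero at extinction
  expect_identical(run$params$n0 + sum(delta) - run$leaked, 0)
})

test_that("wave-regime runs go extinct", {
  ext <- vapply(1:100, function(s)
    gillespie_run(preset_params("test-small"), t_end = 5e4, seed = s)$extinct,
    logical(1))
  expect_gte(mean(ext), 0.99)
})

test_that("ensemble means track the deterministic solution", {
  hp <- preset_params("test-small")
  tg <- c(100, 400, 900, 1600)
  ens <- replicate_ensemble(hp, 400, tg, seed = 77)
  ode <- integrate_dynamics(hp, c(0, tg))
  z_max <- 0
  for (ti in seq_along(tg)) for (i in 1:5) {
    m <- ens$mean[ti, i, 1]; se <- ens$se[ti, i, 1]
    expc <- ode$counts[ti + 1, i, 1]
    if (se > 0) z_max <- max(z_max, abs(m - expc) / se)
    else expect_lt(abs(m - expc), 0.05)
  }
  expect_lt(z_max, 3.5)
  # a forced cascade (eps = 1, u = 0) has deterministic outcomes: after the
  # wave has passed, every replicate is empty and the variance is exactly zero
  det <- hierarchy_params(n_compartments = 2, epsilon = 1, u = 0, n0 = 3, k_max = 0)
  e2 <- replicate_ensemble(det, 5, c(1e5), seed = 1)
  expect_equal(max(e2$sd), 0)
  expect_equal(max(e2$mean), 0)
  # standard errors shrink with the number of replicates
  small <- replicate_ensemble(hp, 50, 400, seed = 3)
  expect_lt(mean(ens$se[2, , 1]), mean(small$se[1, , 1]))
})

test_that("the clone census counts unique mutation events seen downstream", {
  hp <- preset_params("test-small")
  # no mutation, no mutant clones
  run0 <- gillespie_run(hierarchy_params(n_compartments = 3, u = 0, k_max = 1),
                        Inf, seed = 5)
  expect_length(clone_census(run0, 3)$clones, 0)
  # clone ids are unique, one per mutation event
  runs <- lapply(1:200, function(s) gillespie_run(hp, Inf, seed = s))
  for (run in runs[1:10]) {
    expect_false(anyDuplicated(run$clones$id) > 0)
    expect_identical(nrow(run$clones), sum(run$events$outcome == "mutate") - run$leaked)
  }
  # ensemble-mean distinct single-mutant clones in the last compartment match
  # the clone-founding expectation u/alpha * sum_j W_j^0
  n1 <- vapply(runs, function(r) {
    cen <- clone_census(r, 5)
    sum(cen$clones[cen$k == 1L])
  }, numeric(1))
  expc <- expected_foundings(hp, 5, 1)
  se <- sd(n1) / sqrt(length(n1))
  expect_lt(abs(mean(n1) - expc), 3 * se + 1e-12)
})

test_that("lineage export produces parseable newick forests", {
  expect_identical(export_lineage_newick(data.frame(id = integer(0),
    parent = integer(0), birth_time = numeric(0), origin_compartment = integer(0),
    k = integer(0))), "(founder);")
  chain <- data.frame(id = c(1L, 2L), parent = c(0L, 1L),
                      birth_time = c(5, 9), origin_compartment = c(1L, 2L),
                      k = c(1L, 2L))
  nw <- export_lineage_newick(chain)
  expect_match(nw, "^\\(\\(c2_i2_t9:4\\)c1_i1_t5:5\\)founder;$")
  skip_if_not_installed("ape")
  # parse-back recovers the parent relation on a simulated clone table
  run <- gillespie_run(tiny_params(u = 0.05, n = 3, k_max = 6, n0 = 10), Inf,
                       seed = 3, max_cells = 5e4)
  skip_if(nrow(run$clones) < 2)
  tr <- ape::read.tree(text = export_lineage_newick(run$clones))
  labs <- c(tr$tip.label, tr$node.label)
  ids <- suppressWarnings(as.integer(sub("^c(\\d+)_.*$", "\\1", labs)))
  expect_setequal(stats::na.omit(ids), run$clones$id)
  # every child label's parent edge leads to its recorded parent clone
  for (e in seq_len(nrow(tr$edge))) {
    to <- labs[tr$edge[e, 2]]; from <- labs[tr$edge[e, 1]]
    to_id <- suppressWarnings(as.integer(sub("^c(\\d+)_.*$", "\\1", to)))
    if (is.na(to_id)) next
    par_rec <- run$clones$parent[match(to_id, run$clones$id)]
    from_id <- suppressWarnings(as.integer(sub("^c(\\d+)_.*$", "\\1", from)))
    expect_identical(ifelse(is.na(from_id), 0L, from_id), par_rec)
  }
  expect_error(export_lineage_newick(data.frame(id = c(1L, 2L), parent = c(2L, 1L),
    birth_time = c(1, 2), origin_compartment = c(1L, 1L), k = c(1L, 2L))),
    "cyclic|integrity")
})
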