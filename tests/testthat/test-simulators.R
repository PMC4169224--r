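test_that("direct-method draws follow the exponential/categorical law", {
  expect_equal(direct_step(c(5, 0, 0, 0, 0))$reaction_index, 1L)
  expect_error(direct_step(numeric(5)), "exhausted")

  set.seed(42)
  n <- 1e5
  waits <- vapply(seq_len(n), function(i) direct_step(c(4, 6))$waiting_time, 0)
  # exponential with a0 = 10: mean 0.1, sd 0.1
  expect_lt(abs(mean(waits) - 0.1), 3 * 0.1 / sqrt(n))

  set.seed(43)
  idx <- vapply(seq_len(n), function(i)
    direct_step(rep(1, 5))$reaction_index, 0L)
  counts <- tabulate(idx, nbins = 5)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("tau-leap firings are Poisson with mean a*tau and conserve mass", {
  fx <- make_fixture("isomerization", N0 = 50, k_AB = 0.5, k_BA = 0.5)
  st <- c(A = 20, B = 30)
  a <- propensity_vector(fx$network, st)$a   # (10, 15)

  set.seed(44)
  n <- 1e5
  k1 <- vapply(seq_len(n), function(i)
    tau_leap_step(st, fx$network, a, tau = 0.4)$k[1], 0)
  # Poisson mean a1 * tau = 4, variance 4
  expect_lt(abs(mean(k1) - 4), 3 * sqrt(4 / n))

  set.seed(45)
  for (rep in 1:50) {
    out <- tau_leap_step(st, fx$network, a, tau = 0.4)
    expect_equal(sum(out$state), sum(st), tolerance = 1e-9)
    expect_true(all(out$state >= 0))
  }

  out <- tau_leap_step(st, fx$network, c(AtoB = 0, BtoA = 0), tau = 1)
  expect_equal(out$state, st)
  expect_equal(out$clamps, 0L)
})

test_that("a methanogenesis firing moves the published fractions", {
  nu4 <- ad_net$stoich[, "r4"]
  moved <- nu4[nu4 != 0]
  expect_equal(moved, c(acetate = -1, methane = 0.95, acetate_degraders = 0.05))
  expect_equal(sum(nu4), 0, tolerance = 1e-12)
})

test_that("clamping at depletion keeps states non-negative and mass closed", {
  # aggressive leap on a near-empty pure-death system forces overshoot
  fx <- make_fixture("pure_death", N0 = 3.5, c = 2)
  set.seed(46)
  clamped <- 0L
  for (rep in 1:200) {
    a <- propensity_vector(fx$network, c(A = 3.5))$a
    out <- tau_leap_step(c(A = 3.5), fx$network, a, tau = 1)
    expect_gte(out$state[["A"]], 0)
    clamped <- clamped + out$clamps
  }
  expect_gt(clamped, 0L)

  # in the closed digestion network the clamp never destroys mass
  cfg <- sim_config("tauleap", tau = 2, t_end = 40, record_dt = 2,
                    seed = 46, omega = 1)
  tr <- simulate_network(ad_net, ad_initial_state(1), cfg)
  tot <- rowSums(tr$state)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  expect_true(all(tr$state >= 0))
})

test_that("simulation is deterministic given a seed and idles once exhausted", {
  cfg <- sim_config("direct", t_end = 10, record_dt = 1, seed = 99, omega = 1)
  t1 <- simulate_network(ad_net, ad_initial_state(1), cfg)
  t2 <- simulate_network(ad_net, ad_initial_state(1), cfg)
  expect_identical(t1$state, t2$state)
  expect_identical(t1$events, t2$events)

  # no catalysts: every propensity 0, state frozen at the initial value
  init <- stats::setNames(numeric(11), ad_net$species$name)
  init["glucose"] <- 500
  for (m in c("direct", "tauleap", "ode")) {
    tr <- simulate_network(ad_net, init,
                           sim_config(m, tau = 0.5, t_end = 5, record_dt = 1,
                                      seed = 1, omega = 1))
    expect_true(all(abs(tr$state - rep(init, each = 6)) < 1e-8),
                label = paste("constant trajectory under", m))
  }

  # absorbed system: pure death hits 0 and the remaining grid repeats it
  fx <- make_fixture("pure_death", N0 = 5, c = 5)
  tr <- simulate_network(fx$network, fx$init,
                         sim_config("direct", t_end = 100, record_dt = 10,
                                    seed = 3))
  expect_equal(unname(tr$state[11, "A"]), 0)
  expect_equal(unname(tr$events[["death"]]), 5)

  expect_error(sim_config("leapfrog"), "unknown method")
})

test_that("the ensemble mean of a linear death process matches the closed form", {
  fx <- make_fixture("pure_death", N0 = 100, c = 0.1)
  finals <- replicate_finals(fx, "A", n = 500, t_end = 10, seed = 42L)
  p <- exp(-1)                               # survival probability at t = 10
  se_mean <- sqrt(100 * p * (1 - p)) / sqrt(500)
  expect_lt(abs(mean(finals) - 100 * p), 3 * se_mean)

  # simulate_ensemble reproduces the same replicate stream
  cfg <- sim_config("direct", t_end = 10, record_dt = 10, seed = 42L,
                    replicates = 500)
  ens <- simulate_ensemble(fx$network, fx$init, cfg)
  expect_equal(unname(ens$mean[2, "A"]), mean(finals), tolerance = 1e-12)
  expect_equal(unname(ens$variance[2, "A"]), var(finals), tolerance = 1e-12)

  cfg1 <- sim_config("direct", t_end = 10, record_dt = 10, seed = 42L)
  single <- simulate_network(fx$network, fx$init, cfg1)
  one <- simulate_ensemble(fx$network, fx$init,
                           sim_config("direct", t_end = 10, record_dt = 10,
                                      seed = 42L, replicates = 1))
  expect_equal(one$mean, single$state)       # replicate 1 uses the base seed
  expect_true(all(one$variance == 0))
})

test_that("the ODE reference conserves mass and respects absorbed dynamics", {
  cfg <- sim_config("ode", t_end = 30, record_dt = 1, omega = 5)
  tr <- integrate_ode(ad_net, ad_initial_state(5), cfg)
  tot <- rowSums(tr$state)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  expect_equal(tr$clamps, 0L)
  expect_true(all(tr$events == 0))
  expect_true(all(diff(tr$state[, "methane"]) >= -1e-8))
  expect_true(all(diff(tr$state[, "glucose"]) <= 1e-8))
})

test_that("the stochastic mean approaches the deterministic limit as the system grows", {
  init_conc <- c(glucose = 500, sugar_degraders = 100, butyrate_degraders = 100,
                 propionate_degraders = 100, acetate_degraders = 100,
                 hydrogen_degraders = 100)
  dev <- vapply(c(1, 10, 50), function(om) {
    init <- concentration_to_particles(init_conc, om, ad_net)
    cfg <- sim_config("direct", t_end = 2, record_dt = 0.5, seed = 42L,
                      replicates = 8, omega = om)
    ens <- simulate_ensemble(ad_net, init, cfg)
    ref <- integrate_ode(ad_net, init,
                         sim_config("ode", t_end = 2, record_dt = 0.5,
                                    omega = om))
    compare_to_ode(ens, ref)$overall_nrmsd
  }, 0)
  expect_true(all(diff(dev) < 0))
})
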