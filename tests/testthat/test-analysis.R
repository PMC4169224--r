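test_that("ensemble/ODE comparison recovers exact and shifted deviations", {
  cfg <- sim_config("ode", t_end = 5, record_dt = 1, omega = 1)
  ref <- integrate_ode(ad_net, ad_initial_state(1), cfg)
  fake <- structure(list(times = ref$times, mean = ref$state,
                         variance = ref$state * 0, n = 10,
                         method = "tauleap",
                         cfg = sim_config("tauleap", tau = 0.4, t_end = 5,
                                          record_dt = 1, omega = 1)),
                    class = "ad_ensemble")
  cmp <- compare_to_ode(fake, ref)
  expect_true(all(cmp$by_species$rmsd == 0))

  shifted <- fake
  shifted$mean <- ref$state + 2.5
  cmp <- compare_to_ode(shifted, ref)
  expect_true(all(abs(cmp$by_species$rmsd - 2.5) < 1e-12))
  # zero-range species (none consumed here? methane grows) -> normalization
  expect_true(all(is.na(cmp$by_species$nrmsd) |
                  cmp$by_species$nrmsd >= 0))

  bad <- fake
  bad$times <- fake$times + 0.5
  expect_error(compare_to_ode(bad, ref), "grids")
})

test_that("steady state is detected from per-step relative change", {
  flat <- structure(list(times = 0:10,
                         state = matrix(5, 11, 2,
                                        dimnames = list(NULL, c("A", "B")))),
                    class = "ad_trajectory")
  expect_equal(steady_state_time(flat, 1e-4), 0)

  growing <- structure(list(times = 0:10,
                            state = cbind(A = (0:10)^1.0, B = rep(1, 11))),
                       class = "ad_trajectory")
  expect_true(is.na(steady_state_time(growing, 1e-4)))

  cfg <- sim_config("ode", t_end = 80, record_dt = 1, omega = 5)
  tr <- integrate_ode(ad_net, ad_initial_state(5), cfg)
  ts <- steady_state_time(tr, 1e-4)
  expect_false(is.na(ts))
  at_ss <- tr$state[match(ts, tr$times), "glucose"]
  expect_lt(at_ss, 0.01 * tr$state[1, "glucose"])
})

test_that("cascade accounting reproduces the hand-propagated totals", {
  casc <- cascade_totals(ad_net, 1)
  # hand arithmetic on the published fractions
  expect_equal(casc$formed[["butyrate"]], 0.117, tolerance = 1e-9)
  expect_equal(casc$formed[["propionate"]], 0.243, tolerance = 1e-9)
  expect_equal(casc$formed[["acetate"]],
               0.369 + 0.752 * 0.117 + 0.5472 * 0.243, tolerance = 1e-9)
  expect_equal(casc$formed[["hydrogen"]],
               0.171 + 0.188 * 0.117 + 0.4128 * 0.243, tolerance = 1e-9)
  expect_equal(casc$formed[["methane"]],
               0.95 * casc$formed[["acetate"]] + 0.94 * casc$formed[["hydrogen"]],
               tolerance = 1e-9)
  # every intermediate fully consumed; mass ends in methane + biomass
  expect_equal(sum(casc$residual), 1, tolerance = 1e-9)
  inter <- c("glucose", "butyrate", "propionate", "acetate", "hydrogen")
  expect_true(all(abs(casc$residual[inter]) < 1e-12))

  empty <- cascade_totals(ad_net, 0)
  expect_true(all(empty$formed == 0))

  cyclic <- reaction_network(
    c("A", "B"),
    list(reaction("f", "A", NA, 1, 1, c(B = 1), kinetics = "linear"),
         reaction("b", "B", NA, 1, 1, c(A = 1), kinetics = "linear")))
  expect_error(cascade_totals(cyclic, 1, input = "A"), "cyclic")
})

test_that("methane splits 64-70% acetoclastic at complete conversion", {
  att <- attribute_methane(cascade_totals(ad_net, 1), ad_net)
  expect_equal(att$acetoclastic_percent, 67.02704, tolerance = 1e-6)
  expect_gte(att$acetoclastic_percent, 64)
  expect_lte(att$acetoclastic_percent, 70)
  expect_equal(att$methane_from_acetate, 0.95 * 0.5899536, tolerance = 1e-9)
  expect_equal(att$methane_from_hydrogen, 0.94 * 0.2933064, tolerance = 1e-9)
})

test_that("attribution handles single-route and methane-free trajectories", {
  traj <- structure(list(events = c(r1 = 0, r2 = 0, r3 = 0, r4 = 50, r5 = 0)),
                    class = "ad_trajectory")
  expect_equal(attribute_methane(traj, ad_net)$acetoclastic_percent, 100)
  traj$events <- c(r1 = 0, r2 = 0, r3 = 0, r4 = 0, r5 = 80)
  expect_equal(attribute_methane(traj, ad_net)$acetoclastic_percent, 0)
  traj$events <- c(r1 = 3, r2 = 0, r3 = 0, r4 = 0, r5 = 0)
  expect_true(is.na(attribute_methane(traj, ad_net)$acetoclastic_percent))
})

test_that("dynamic attribution agrees with the stoichiometric cascade", {
  casc_pct <- attribute_methane(cascade_totals(ad_net, 1),
                                ad_net)$acetoclastic_percent
  # deterministic full conversion: extents recovered by mass accounting
  ode <- integrate_ode(ad_net, ad_initial_state(5),
                       sim_config("ode", t_end = 60, record_dt = 1, omega = 5))
  ode_pct <- attribute_methane(ode, ad_net)$acetoclastic_percent
  expect_lt(abs(ode_pct - casc_pct), 0.01 * casc_pct)

  # stochastic full conversion: realised firing totals
  tr <- simulate_network(ad_net, ad_initial_state(5),
                         sim_config("direct", t_end = 80, record_dt = 10,
                                    seed = 42, omega = 5))
  sto_pct <- attribute_methane(tr, ad_net)$acetoclastic_percent
  expect_lt(abs(sto_pct - casc_pct), 0.02 * casc_pct)
})

test_that("two-state exchange relaxes to its binomial stationary mean", {
  fx <- make_fixture("isomerization", N0 = 50, k_AB = 1, k_BA = 1)
  finals <- replicate_finals(fx, "A", n = 200, t_end = 10, seed = 42L)
  p <- 1 / 2                                # k_BA / (k_AB + k_BA)
  se <- sqrt(50 * p * (1 - p) / 200)
  expect_lt(abs(mean(finals) - 50 * p), 3 * se)
})
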