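# stepping scheme contract: deterministic order, noise statistics, delays,
# reproducibility

test_that("initial-history policies fill lags as documented", {
  st <- network_state(matrix(-1, 1, 3), matrix(-2 / 3, 1, 3))
  h <- make_initial_history(st)
  expect_equal(h$v0, st$v)
  expect_equal(h$v_start, st$v)
  hp0 <- make_initial_history(st, "perturbed", offset = 0)
  expect_equal(hp0$v_start, h$v_start)
  hp <- make_initial_history(st, "perturbed", offset = 0.25)
  expect_equal(hp$v_start, st$v + 0.25)
  expect_equal(hp$v0, st$v)
  expect_equal(history_depth(25, 0.01), 2500L)
})

test_that("quiescent equilibrium is preserved at sigma = 0", {
  lay <- elec_layer(kappa = 0, N = 5)
  sim <- simulate_network(lay, sim_config(dt = 0.01, t_end = 50,
                                          record_stride = 100))
  expect_equal(nrow(sim$spikes), 0)
  expect_true(all(abs(sim$final$v + 1) < 1e-8))
  expect_true(all(abs(sim$final$w + 2 / 3) < 1e-8))
})

test_that("compiled integrator matches the R reference drift path with delays", {
  dt <- 0.05; nsteps <- 300
  lay <- elec_layer(kappa = 1, tau = 1, N = 5)
  fp <- fixed_point(lay)
  init <- network_state(matrix(fp$v, 1, 5), matrix(fp$w, 1, 5))
  ref <- ref_integrate(lay, dt, nsteps, init, perturb = 0.5)
  sim <- simulate_network(lay, sim_config(dt = dt, t_end = nsteps * dt,
                                          record_stride = 1),
                          history_policy = "perturbed", perturb_offset = 0.5)
  got <- matrix(sim$trace$v, ncol = 5)  # time-major, one column per neuron
  expect_equal(max(abs(got - ref[, 1, ])), 0, tolerance = 1e-12)

  # multiplexed chemical variant
  l1 <- chem_layer(kappa = 0.3, tau = 0.5, N = 5)
  l2 <- chem_layer(kappa = 0.6, tau = 0.25, N = 5)
  sp <- multiplex_spec(l1, l2, m_type = "chemical_excitatory",
                       kappa_m = 0.4, tau_m = 0.5)
  fp1 <- fixed_point(l1); fp2 <- fixed_point(l2)
  init2 <- network_state(rbind(rep(fp1$v, 5), rep(fp2$v, 5)),
                         rbind(rep(fp1$w, 5), rep(fp2$w, 5)))
  ref2 <- ref_integrate(sp, dt, nsteps, init2, perturb = 0.5)
  sim2 <- simulate_network(sp, sim_config(dt = dt, t_end = nsteps * dt,
                                          record_stride = 1),
                           init = init2, history_policy = "perturbed",
                           perturb_offset = 0.5)
  for (l in 1:2) {
    got_l <- matrix(sim2$trace$v[sim2$trace$layer == l], ncol = 5)
    expect_equal(max(abs(got_l - ref2[, l, ])), 0, tolerance = 1e-12)
  }
})

test_that("deterministic part converges at fourth order on a smooth span", {
  one <- function(dt) {
    lay <- layer_spec(n_neurons = 3, kappa = 0,
                      neuron = neuron_params(beta = 0.7))
    cfg <- sim_config(dt = dt, t_end = 10, record_stride = round(1 / dt))
    sim <- simulate_network(lay, cfg, history_policy = "perturbed",
                            perturb_offset = 0.5)
    sim$trace$v[sim$trace$neuron == 1 & sim$trace$time == 10]
  }
  ref <- one(0.00125)
  e1 <- abs(one(0.02) - ref)
  e2 <- abs(one(0.01) - ref)
  expect_gt(log2(e1 / e2), 3.5)
  expect_lt(log2(e1 / e2), 4.5)
})

test_that("noise increments have the Ornstein-Uhlenbeck stationary variance", {
  dt <- 0.01; sigma <- 0.5; nsteps <- 1e6
  ou <- sisrmux:::sim_ou_cpp(1, sigma, dt, nsteps, 42, 0.1)
  target <- sigma^2 * dt / (1 - exp(-2 * dt))  # exact for e^{-dt} decay
  n_eff <- 0.9 * nsteps * dt / 2               # correlation time ~ 1
  se <- target * sqrt(2 / n_eff)
  expect_lt(abs(ou$var - target), 3 * se)
  expect_lt(abs(ou$mean), 3 * sqrt(target / n_eff))
})

test_that("oscillatory regime below the Hopf value spikes linearly in time", {
  lay <- layer_spec(n_neurons = 3, kappa = 0,
                    neuron = neuron_params(beta = 0.7))
  run <- function(t_end) {
    sim <- simulate_network(lay, sim_config(dt = 0.05, t_end = t_end),
                            history_policy = "perturbed", perturb_offset = 0.5)
    sum(sim$spikes$neuron == 1)
  }
  n1 <- run(20000); n2 <- run(40000)
  expect_gt(n1, 2)                      # sustained limit cycle
  expect_equal(n2 / n1, 2, tolerance = 0.25)
})

test_that("identical seeds reproduce spike trains bit-for-bit", {
  lay <- elec_layer(kappa = 0.1, tau = 1, sigma = 1e-2)
  cfg <- sim_config(dt = 0.05, t_end = 20000, t_transient = 500, seed = 9)
  s1 <- simulate_network(lay, cfg)
  s2 <- simulate_network(lay, cfg)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- simulate_network(lay, cfg, seed = 10)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("orbits stay bounded near |v| = 2 across the study noise range", {
  lay <- elec_layer(kappa = 0.1, tau = 1, sigma = 0.1)
  cfg <- sim_config(dt = 0.05, t_end = 20000, record_stride = 20)
  sim <- simulate_network(lay, cfg)
  expect_lt(max(abs(sim$trace$v)), 2.0 + 0.2)
})

test_that("a diverging state aborts with a diagnostic naming the neuron", {
  lay <- elec_layer(kappa = 0, N = 3)
  bad <- network_state(matrix(1e80, 1, 3), matrix(0, 1, 3))
  expect_error(
    simulate_network(lay, sim_config(dt = 0.05, t_end = 10), init = bad),
    "non-finite state .* neuron")
})
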