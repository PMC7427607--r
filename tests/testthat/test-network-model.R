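# coupling terms and drift of the multiplex ring network

test_that("ring neighbourhoods wrap modulo N and respect the self-term flag", {
  expect_equal(ring_neighbors(0, 1, 25), c(24L, 1L))
  expect_equal(ring_neighbors(0, 1, 25, include_self = TRUE), c(24L, 0L, 1L))
  nb <- ring_neighbors(2, 8, 25)
  expect_length(nb, 16)
  expect_setequal(nb, c(19:24, 0:1, 3:10))
  expect_error(ring_neighbors(0, 13, 25), "range too large")
})

test_that("sigmoid gate has midpoint 1/2, saturates, and is increasing", {
  ch <- chemical_synapse_params()
  expect_equal(sigmoid_gate(ch$theta_syn, ch), 0.5)
  expect_equal(sigmoid_gate(1e3, ch), 1)
  expect_equal(sigmoid_gate(-1e3, ch), 0)
  expect_equal(sigmoid_gate(0, ch), 1 / (1 + exp(-2.5)), tolerance = 1e-12)
  v <- seq(-2, 2, length.out = 100)
  expect_true(all(diff(sigmoid_gate(v, ch)) > 0))
})

test_that("electrical coupling is diffusive: vanishes at homogeneity and kappa = 0", {
  expect_equal(electrical_coupling(-1, c(-1, -1), kappa = 0.7, range_n = 1), 0)
  expect_equal(electrical_coupling(0.3, c(0.5, 0.1), kappa = 0, range_n = 1), 0)
  expect_equal(electrical_coupling(0, c(1, -1), kappa = 0.5, range_n = 1), 0)
  expect_equal(electrical_coupling(0, c(1, 1), kappa = 0.5, range_n = 1), 0.5)
})

test_that("chemical coupling matches its closed form and null cases", {
  ch <- chemical_synapse_params()
  expect_equal(chemical_coupling(-1, c(-1, -1), 0, 1, ch), 0)
  expect_equal(chemical_coupling(ch$v_syn, c(0, 0), 1, 1, ch), 0)
  got <- chemical_coupling(-1, c(-1, -1), 1, 1, ch)
  expect_equal(got, 2 / (1 + exp(7.5)), tolerance = 1e-12)
  expect_equal(got, 1.106e-3, tolerance = 1e-3)
})

test_that("multiplex coupling handles all synapse types", {
  l <- elec_layer(N = 5)
  sp_e <- multiplex_spec(l, l, m_type = "electrical", kappa_m = 0.4)
  expect_equal(multiplex_coupling(-1, -1, sp_e), 0)
  sp_0 <- multiplex_spec(l, l, m_type = "chemical_excitatory", kappa_m = 0)
  expect_equal(multiplex_coupling(-1, 1, sp_0), 0)
  sp_n <- multiplex_spec(l, l, m_type = "none")
  expect_equal(multiplex_coupling(-1, 1, sp_n), 0)
  sp_c <- multiplex_spec(l, l, m_type = "chemical_excitatory", kappa_m = 0.4)
  expect_equal(multiplex_coupling(-1, 1, sp_c), 0.8 / (1 + exp(-12.5)),
               tolerance = 1e-12)
  expect_equal(multiplex_coupling(-1, 1, sp_c), 0.799997, tolerance = 1e-5)
})

test_that("drift vanishes at the uncoupled fixed point and exposes the w clock", {
  lay <- elec_layer(N = 3)
  st <- network_state(matrix(-1, 1, 3), matrix(-2 / 3, 1, 3))
  d <- drift(st, list(v_intra = st$v), lay)
  expect_equal(d$dv, matrix(0, 1, 3), tolerance = 1e-12)
  expect_equal(d$dw, matrix(0, 1, 3), tolerance = 1e-12)
  # dw/dt = eps * alpha at the origin
  st0 <- network_state(matrix(0, 1, 3), matrix(0, 1, 3))
  d0 <- drift(st0, list(v_intra = st0$v), lay)
  expect_equal(d0$dw[1, 1], 5e-4 * 0.5)
})

test_that("homogeneity null: every electrical term is zero at a common state", {
  lay <- elec_layer(kappa = 1.3, tau = 5, N = 7)
  sp <- multiplex_spec(lay, lay, m_type = "electrical", kappa_m = 0.8,
                       tau_m = 3)
  for (vc in c(-1.2, 0.4, 1.7)) {
    st <- network_state(matrix(vc, 2, 7), matrix(0.1, 2, 7))
    # delayed values equal to the common state, any lag
    d <- drift(st, list(v_intra = st$v, v_mux = st$v), sp)
    base <- vc - vc^3 / 3 - 0.1
    expect_equal(d$dv, matrix(base, 2, 7), tolerance = 1e-12)
  }
})

test_that("chemical drift contribution is bounded and polarity-antisymmetric", {
  lay <- chem_layer(kappa = 0.6, N = 25)
  ch <- lay$chem
  set.seed(1)
  for (rep in 1:20) {
    v <- stats::runif(25, -2, 2)
    vd <- stats::runif(25, -2, 2)
    st <- network_state(matrix(v, 1, 25), matrix(0, 1, 25))
    d <- drift(st, list(v_intra = matrix(vd, 1, 25)), lay)
    base <- v - v^3 / 3
    cterm <- d$dv[1, ] - base
    expect_true(all(abs(cterm) <= lay$kappa * max(abs(v - ch$v_syn)) + 1e-12))
  }
  # inhibitory vs excitatory multiplexing differ by an exact sign flip
  l <- chem_layer(kappa = 0, N = 5)
  sp_i <- multiplex_spec(l, l, m_type = "chemical_inhibitory", kappa_m = 0.5,
                         tau_m = 1)
  sp_x <- multiplex_spec(l, l, m_type = "chemical_excitatory", kappa_m = 0.5,
                         tau_m = 1)
  st <- network_state(matrix(stats::runif(10, -2, 2), 2, 5),
                      matrix(0, 2, 5))
  vd <- matrix(stats::runif(10, -2, 2), 2, 5)
  di <- drift(st, list(v_intra = st$v, v_mux = vd), sp_i)
  dx <- drift(st, list(v_intra = st$v, v_mux = vd), sp_x)
  base <- st$v - st$v^3 / 3 - st$w
  expect_equal(di$dv - base, -(dx$dv - base), tolerance = 1e-12)
})

test_that("drift rejects missing delayed values", {
  lay <- elec_layer(kappa = 1, tau = 2, N = 5)
  sp <- multiplex_spec(lay, lay, m_type = "electrical", kappa_m = 1, tau_m = 1)
  st <- network_state(matrix(-1, 2, 5), matrix(-2 / 3, 2, 5))
  expect_error(drift(st, list(), sp), "v_intra")
  expect_error(drift(st, list(v_intra = st$v), sp), "v_mux")
})

test_that("spec constructors enforce their invariants", {
  expect_error(layer_spec(synapse = "electrical", range_n = 2), "local")
  expect_error(layer_spec(kappa = -1))
  expect_error(neuron_params(epsilon = 0))
  expect_error(neuron_params(alpha = 1.5))
  l1 <- elec_layer(N = 10); l2 <- elec_layer(N = 12)
  expect_error(multiplex_spec(l1, l2), "n_neurons")
})
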