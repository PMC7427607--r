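# shared fixtures and a slow R reference integrator used to cross-check the
# compiled path on short spans

elec_layer <- function(kappa = 0, tau = 0, sigma = 0, N = 25, ...) {
  layer_spec(n_neurons = N, synapse = "electrical", kappa = kappa, tau = tau,
             sigma = sigma, ...)
}

chem_layer <- function(kappa = 0, tau = 0, sigma = 0, N = 25, ...) {
  layer_spec(n_neurons = N, synapse = "chemical_inhibitory", kappa = kappa,
             tau = tau, sigma = sigma,
             range_n = min(8L, (N - 1L) %/% 2L), ...)
}

# RK4 reference built on the package's own drift(), with the history kept as
# a plain matrix of time slices; independent of the C++ stepping code.
# Row layout of the history matrix: column (l - 1) * N + i holds v_{l,i}.
ref_integrate <- function(spec, dt, nsteps, init, perturb = 0) {
  if (inherits(spec, "layer_spec")) {
    layers <- list(spec); m_lag <- 0L; m_type <- "none"
  } else {
    layers <- list(spec$layer1, spec$layer2)
    m_lag <- round(spec$tau_m / dt); m_type <- spec$m_type
  }
  nl <- length(layers)
  N <- layers[[1]]$n_neurons
  lags <- vapply(layers, function(l) round(l$tau / dt), 0)
  depth <- max(c(lags, m_lag)) + 2
  flat <- function(m) as.vector(t(m))
  unflat <- function(x) matrix(x, nl, N, byrow = TRUE)
  H <- matrix(rep(flat(init$v), each = depth), depth, nl * N)
  v <- init$v + perturb
  w <- init$w
  H[depth, ] <- flat(v)
  out <- array(NA_real_, c(nsteps + 1, nl, N))
  out[1, , ] <- v
  delayed_at <- function(c_off, sv) {
    vi <- matrix(0, nl, N)
    for (l in seq_len(nl)) {
      if (lags[l] == 0) vi[l, ] <- sv[l, ]
      else {
        a <- unflat(H[depth - lags[l], ])[l, ]
        b <- unflat(H[depth - lags[l] + 1, ])[l, ]
        vi[l, ] <- (1 - c_off) * a + c_off * b
      }
    }
    vm <- NULL
    if (m_type != "none") {
      vm <- matrix(0, nl, N)
      for (l in seq_len(nl)) {
        if (m_lag == 0) vm[l, ] <- sv[l, ]
        else {
          a <- unflat(H[depth - m_lag, ])[l, ]
          b <- unflat(H[depth - m_lag + 1, ])[l, ]
          vm[l, ] <- (1 - c_off) * a + c_off * b
        }
      }
    }
    list(v_intra = vi, v_mux = vm)
  }
  for (s in seq_len(nsteps)) {
    f <- function(sv, sw, c_off)
      drift(network_state(sv, sw), delayed_at(c_off, sv), spec)
    k1 <- f(v, w, 0)
    k2 <- f(v + dt / 2 * k1$dv, w + dt / 2 * k1$dw, 0.5)
    k3 <- f(v + dt / 2 * k2$dv, w + dt / 2 * k2$dw, 0.5)
    k4 <- f(v + dt * k3$dv, w + dt * k3$dw, 1)
    v <- v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    w <- w + dt / 6 * (k1$dw + 2 * k2$dw + 2 * k3$dw + k4$dw)
    H <- rbind(H[-1, , drop = FALSE], flat(v))
    out[s + 1, , ] <- v
  }
  out
}
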