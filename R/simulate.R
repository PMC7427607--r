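#' Integrate the stochastic delayed network
#'
#' Runs one realization of the multiplex (or isolated-layer) FitzHugh-Nagumo
#' network. The deterministic part is integrated with classical 4th-order
#' Runge-Kutta (delayed arguments read from a history buffer on the `dt` grid,
#' linearly interpolated at half stages); Gaussian noise of amplitude
#' `sigma_l` enters additively per neuron per step with variance
#' `sigma^2 * dt`, with independent Wiener increments across neurons. Delays
#' are snapped to the nearest multiple of `dt`. Spikes are detected online
#' with Schmitt-trigger semantics ([detect_spikes()] applies the same rule to
#' stored traces), so long horizons do not require storing the trace.
#'
#' By default all neurons start at the deterministic uncoupled fixed point
#' with constant history; coherent spiking then arises only through noise
#' (the regime of self-induced stochastic resonance) or, for excitability
#' probes, through the `"perturbed"` history policy.
#'
#' @param spec A [multiplex_spec()] or [layer_spec()] (isolated layer).
#' @param config A [sim_config()].
#' @param init Optional [network_state()]; default: the homogeneous fixed
#'   point of each layer.
#' @param history_policy `"constant"` or `"perturbed"` (see
#'   [make_initial_history()]).
#' @param perturb_offset Offset used by the perturbed policy.
#' @param up_threshold,rearm_threshold Spike-detector thresholds.
#' @param seed Seed for this realization; defaults to `config$seed`.
#' @return An object of class `"sisr_sim"`: list with `spikes` (tibble:
#'   `layer`, `neuron`, `time`), `trace` (tibble `time, layer, neuron, v, w`
#'   if `record_stride > 0`, else `NULL`), `final` state, plus the spec,
#'   config and seed that produced it.
#' @examples
#' lay <- layer_spec(n_neurons = 5, kappa = 0, sigma = 0)
#' sim <- simulate_network(lay, sim_config(dt = 0.01, t_end = 5))
#' nrow(sim$spikes)  # 0: quiescent at the fixed point without noise
#' @export
simulate_network <- function(spec, config, init = NULL,
                             history_policy = c("constant", "perturbed"),
                             perturb_offset = 0.5,
                             up_threshold = 1.0, rearm_threshold = -1.0,
                             seed = NULL) {
  history_policy <- match.arg(history_policy)
  if (inherits(spec, "layer_spec")) {
    layers <- list(spec)
    m_type <- "none"; kappa_m <- 0; tau_m <- 0
    chem_m <- spec$chem
  } else {
    stopifnot(inherits(spec, "multiplex_spec"))
    layers <- list(spec$layer1, spec$layer2)
    m_type <- spec$m_type; kappa_m <- spec$kappa_m; tau_m <- spec$tau_m
    chem_m <- spec$chem
  }
  n_layers <- length(layers)
  N <- layers[[1]]$n_neurons
  np <- layers[[1]]$neuron
  dt <- config$dt

  if (is.null(init)) {
    v0 <- matrix(0, n_layers, N); w0 <- matrix(0, n_layers, N)
    for (l in seq_len(n_layers)) {
      fp <- fixed_point(layers[[l]])
      v0[l, ] <- fp$v; w0[l, ] <- fp$w
    }
    init <- network_state(v0, w0)
  }
  hist <- make_initial_history(init, history_policy, perturb_offset)

  lag <- vapply(layers, function(l) round(l$tau / dt), 0)
  m_lag <- round(tau_m / dt)
  m_code <- match(m_type, c("none", "electrical", "chemical_inhibitory",
                            "chemical_excitatory")) - 1L
  if (is.null(seed)) seed <- config$seed
  n_steps <- round(config$t_end / dt)

  res <- sim_multiplex_cpp(
    n_layers, N,
    vapply(layers, function(l) if (l$synapse == "electrical") 0L else 1L, 0L),
    vapply(layers, function(l) l$kappa, 0),
    as.integer(lag),
    vapply(layers, function(l) l$range_n, 0L),
    vapply(layers, function(l) l$sigma, 0),
    m_code, kappa_m, as.integer(m_lag),
    np$alpha, np$beta, np$epsilon,
    chem_m$lambda, chem_m$theta_syn, chem_m$v_syn,
    dt, n_steps, config$t_transient,
    hist$v0, hist$w0, hist$v_start,
    seed, up_threshold, rearm_threshold, config$record_stride,
    as.integer(isTRUE(layers[[1]]$include_self)))

  if (res$blow_step >= 0)
    stop(sprintf(
      "non-finite state at step %d (t = %.2f), layer %d, neuron %d",
      res$blow_step, res$blow_step * dt, res$blow_layer, res$blow_neuron),
      call. = FALSE)

  spikes <- purrr::map_dfr(seq_len(n_layers), function(l) {
    sp <- res$spikes[[l]]
    tibble::tibble(
      layer = l,
      neuron = rep.int(seq_len(N), lengths(sp)),
      time = unlist(sp, use.names = FALSE) %||% numeric(0))
  })
  trace <- NULL
  if (config$record_stride > 0) {
    trace <- purrr::map_dfr(seq_len(n_layers), function(l) {
      mv <- res$rec_v[[l]]; mw <- res$rec_w[[l]]
      tibble::tibble(
        time = rep(res$rec_time, times = N),
        layer = l,
        neuron = rep(seq_len(N), each = length(res$rec_time)),
        v = as.vector(mv), w = as.vector(mw))
    })
  }
  structure(list(spikes = spikes, trace = trace,
                 final = network_state(res$v_final, res$w_final),
                 spec = spec, config = config, seed = seed),
            class = "sisr_sim")
}

#' @export
print.sisr_sim <- function(x, ...) {
  cat(sprintf("<sisr_sim> %d spikes over T=%g (seed %s)\n",
              nrow(x$spikes), x$config$t_end, format(x$seed)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
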