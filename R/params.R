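#' Neuron parameters of the FitzHugh-Nagumo model
#'
#' The two-variable slow-fast neuron: fast membrane potential `v` with cubic
#' nonlinearity, slow linear recovery `w`, and timescale separation `epsilon`.
#' The recovery equation is `dw/dt = epsilon * (v + alpha - beta * w)`.
#' `beta` is the Hopf-bifurcation (excitability) parameter: the neuron is
#' excitable for `beta > hopf_beta(epsilon, alpha)` and oscillatory otherwise.
#'
#' @param alpha Offset in the recovery dynamics, in (0, 1).
#' @param beta Excitability parameter, > 0.
#' @param epsilon Timescale-separation ratio, 0 < epsilon << 1.
#' @return An object of class `"neuron_params"`.
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(alpha = 0.5, beta = 0.75, epsilon = 5e-4) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            is.numeric(beta), length(beta) == 1, beta > 0,
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "neuron_params")
}

#' Chemical synapse parameters
#'
#' Sigmoidal gating of the chemical synapse,
#' `Gamma(v) = 1 / (1 + exp(-lambda * (v - theta_syn)))`, with reversal
#' potential `v_syn`. With the default `v_syn = -3` and `|v| <= 2`, the factor
#' `(v - v_syn)` is always positive, so inhibition/excitation is purely a sign
#' convention applied by the drift (the `polarity` field).
#'
#' @param v_syn Synaptic reversal potential.
#' @param theta_syn Synaptic firing threshold (sigmoid midpoint).
#' @param lambda Sigmoid slope, > 0.
#' @param polarity `"inhibitory"` or `"excitatory"`.
#' @return An object of class `"chem_params"`.
#' @export
chemical_synapse_params <- function(v_syn = -3.0, theta_syn = -0.25,
                                    lambda = 10.0,
                                    polarity = c("inhibitory", "excitatory")) {
  polarity <- match.arg(polarity)
  stopifnot(lambda > 0)
  structure(list(v_syn = v_syn, theta_syn = theta_syn, lambda = lambda,
                 polarity = polarity),
            class = "chem_params")
}

#' Specification of one ring layer
#'
#' A ring of `n_neurons` identical FitzHugh-Nagumo neurons coupled either by
#' diffusive electrical synapses (gap junctions; local, `range_n = 1`) or by
#' inhibitory chemical synapses (nonlocal, default `range_n = 8`), with a
#' common intra-layer coupling strength `kappa`, delay `tau`, and additive
#' noise amplitude `sigma`.
#'
#' @param n_neurons Number of neurons N on the ring.
#' @param synapse `"electrical"` or `"chemical_inhibitory"`.
#' @param kappa Intra-layer coupling strength, >= 0.
#' @param tau Intra-layer synaptic delay, >= 0, in model time units.
#' @param range_n Neighbour range on the ring; defaults to 1 (electrical) or
#'   8 (chemical). Must satisfy `2 * range_n < n_neurons`.
#' @param sigma Noise amplitude, >= 0.
#' @param neuron A [neuron_params()] object.
#' @param chem A [chemical_synapse_params()] object (chemical layers only).
#' @param include_self Include the delayed self-term `j = i` in the coupling
#'   sum? Default `FALSE` (no autapse, consistent with the `1/(2n)`
#'   normalization over `2n` neighbours).
#' @return An object of class `"layer_spec"`.
#' @examples
#' layer_spec(kappa = 0.1, tau = 1)
#' @export
layer_spec <- function(n_neurons = 25,
                       synapse = c("electrical", "chemical_inhibitory"),
                       kappa = 0, tau = 0, range_n = NULL, sigma = 0,
                       neuron = neuron_params(),
                       chem = chemical_synapse_params(),
                       include_self = FALSE) {
  synapse <- match.arg(synapse)
  if (is.null(range_n)) range_n <- if (synapse == "electrical") 1L else 8L
  range_n <- as.integer(range_n)
  stopifnot(n_neurons >= 3, kappa >= 0, tau >= 0, sigma >= 0,
            range_n >= 1, 2 * range_n < n_neurons,
            inherits(neuron, "neuron_params"), inherits(chem, "chem_params"))
  if (synapse == "electrical" && range_n != 1L)
    stop("electrical synapses are local: range_n must be 1", call. = FALSE)
  structure(list(n_neurons = as.integer(n_neurons), synapse = synapse,
                 kappa = kappa, tau = tau, range_n = range_n, sigma = sigma,
                 neuron = neuron, chem = chem,
                 include_self = isTRUE(include_self)),
            class = "layer_spec")
}

#' Specification of a two-layer multiplex network
#'
#' Two ring layers with the same number of neurons; inter-layer coupling is
#' restricted to replica pairs (neuron i of layer 1 with neuron i of layer 2)
#' and can be electrical or chemical (inhibitory or excitatory).
#'
#' @param layer1,layer2 [layer_spec()] objects with equal `n_neurons`.
#' @param m_type One of `"none"`, `"electrical"`, `"chemical_inhibitory"`,
#'   `"chemical_excitatory"`.
#' @param kappa_m Multiplexing strength, >= 0.
#' @param tau_m Multiplexing delay, >= 0.
#' @param chem Chemical parameters of the multiplexing synapse.
#' @return An object of class `"multiplex_spec"`.
#' @export
multiplex_spec <- function(layer1, layer2,
                           m_type = c("none", "electrical",
                                      "chemical_inhibitory",
                                      "chemical_excitatory"),
                           kappa_m = 0, tau_m = 0,
                           chem = chemical_synapse_params()) {
  m_type <- match.arg(m_type)
  stopifnot(inherits(layer1, "layer_spec"), inherits(layer2, "layer_spec"),
            layer1$n_neurons == layer2$n_neurons,
            kappa_m >= 0, tau_m >= 0)
  structure(list(layer1 = layer1, layer2 = layer2, m_type = m_type,
                 kappa_m = kappa_m, tau_m = tau_m, chem = chem),
            class = "multiplex_spec")
}

#' Network state
#'
#' Membrane potentials and recovery variables per (layer, neuron), stored as
#' `n_layers x N` matrices.
#'
#' @param v,w Numeric matrices of equal dimension (`n_layers` rows).
#' @return An object of class `"network_state"`.
#' @export
network_state <- function(v, w) {
  v <- as.matrix(v); w <- as.matrix(w)
  stopifnot(all(dim(v) == dim(w)), all(is.finite(v)), all(is.finite(w)))
  structure(list(v = v, w = w), class = "network_state")
}

#' Simulation configuration
#'
#' @param dt Integration step, > 0. Delays are snapped to the nearest integer
#'   multiple of `dt`.
#' @param t_end Time horizon T.
#' @param t_transient Initial span discarded from spike statistics.
#' @param n_realizations Number of independent noise realizations.
#' @param seed Base integer seed; realization r uses a seed derived from it.
#' @param record_stride Steps between stored trace samples (0 = no trace).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 0.01, t_end, t_transient = 0,
                       n_realizations = 1, seed = 1, record_stride = 0) {
  stopifnot(dt > 0, t_end > t_transient, t_transient >= 0,
            n_realizations >= 1, record_stride >= 0)
  structure(list(dt = dt, t_end = t_end, t_transient = t_transient,
                 n_realizations = as.integer(n_realizations),
                 seed = as.numeric(seed),
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf("<layer_spec> N=%d %s kappa=%g tau=%g n=%d sigma=%g\n",
              x$n_neurons, x$synapse, x$kappa, x$tau, x$range_n, x$sigma))
  invisible(x)
}

#' @export
print.multiplex_spec <- function(x, ...) {
  cat(sprintf("<multiplex_spec> m_type=%s kappa_m=%g tau_m=%g\n",
              x$m_type, x$kappa_m, x$tau_m))
  cat("layer1: "); print(x$layer1)
  cat("layer2: "); print(x$layer2)
  invisible(x)
}
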