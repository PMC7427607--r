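#' Ring neighbourhood of a neuron
#'
#' Indices of the `2 * range_n` nearest neighbours of neuron `i` on a ring of
#' `N` neurons, taken modulo N. Indexing is 0-based (matching the modular
#' arithmetic of the ring); neuron `i` itself is omitted unless
#' `include_self = TRUE` (the no-autapse convention, consistent with the
#' `1/(2n)` normalization of the coupling sums).
#'
#' @param i Neuron index in `0:(N-1)`.
#' @param range_n Neighbour range n.
#' @param N Ring size.
#' @param include_self Include `i` itself in the list?
#' @return Integer vector of neighbour indices in ring order
#'   (`i - range_n`, ..., `i + range_n`).
#' @examples
#' ring_neighbors(0, 1, 25)        # c(24, 1)
#' ring_neighbors(0, 1, 25, TRUE)  # c(24, 0, 1)
#' @export
ring_neighbors <- function(i, range_n, N, include_self = FALSE) {
  stopifnot(i >= 0, i < N, range_n >= 1)
  if (2 * range_n >= N)
    stop("neighbour range too large for ring size: need 2 * range_n < N",
         call. = FALSE)
  off <- seq.int(-range_n, range_n)
  if (!include_self) off <- off[off != 0]
  as.integer((i + off) %% N)
}

#' Sigmoidal synaptic gate
#'
#' `Gamma(v) = 1 / (1 + exp(-lambda * (v - theta_syn)))`: the fraction of open
#' channels of a chemical synapse given the (delayed) presynaptic potential.
#' Strictly increasing, range (0, 1), midpoint at `theta_syn`.
#'
#' @param v Presynaptic membrane potential(s).
#' @param params A [chemical_synapse_params()] object.
#' @return Gate value(s) in (0, 1).
#' @export
sigmoid_gate <- function(v, params = chemical_synapse_params()) {
  1 / (1 + exp(-params$lambda * (v - params$theta_syn)))
}

#' Electrical (gap-junction) coupling current
#'
#' Diffusive intra-layer coupling
#' `E = kappa / (2 n) * sum_j (v_j(t - tau) - v_i(t))`; vanishes when all
#' arguments are equal.
#'
#' @param v_i Potential of the target neuron at time t.
#' @param v_neighbors_delayed Potentials of its `2 * range_n` ring neighbours
#'   at time `t - tau`.
#' @param kappa Coupling strength.
#' @param range_n Neighbour range n.
#' @return The coupling current (scalar).
#' @export
electrical_coupling <- function(v_i, v_neighbors_delayed, kappa, range_n) {
  stopifnot(length(v_neighbors_delayed) == 2 * range_n)
  kappa / (2 * range_n) * sum(v_neighbors_delayed - v_i)
}

#' Chemical coupling current (unsigned)
#'
#' Intra-layer chemical coupling
#' `C = kappa / (2 n) * (v_i - v_syn) * sum_j Gamma(v_j(t - tau))`.
#' The returned value is unsigned; the drift subtracts it for inhibitory
#' synapses and adds it for excitatory ones.
#'
#' @inheritParams electrical_coupling
#' @param params A [chemical_synapse_params()] object.
#' @return The (unsigned) coupling current.
#' @export
chemical_coupling <- function(v_i, v_neighbors_delayed, kappa, range_n,
                              params = chemical_synapse_params()) {
  stopifnot(length(v_neighbors_delayed) == 2 * range_n)
  kappa / (2 * range_n) * (v_i - params$v_syn) *
    sum(sigmoid_gate(v_neighbors_delayed, params))
}

#' Multiplex (inter-layer) coupling current
#'
#' Replica coupling between layers: electrical
#' `M^e = kappa_m * (v_replica(t - tau_m) - v_own(t))`, or chemical
#' `M^c = kappa_m * (v_own(t) - v_syn) * Gamma(v_replica(t - tau_m))`.
#' The chemical value is returned unsigned; the drift applies the polarity
#' sign (minus for inhibitory, plus for excitatory).
#'
#' @param state_own Potential of the neuron in its own layer at time t.
#' @param replica_delayed Potential of the replica neuron in the other layer
#'   at `t - tau_m`.
#' @param spec A [multiplex_spec()] object (uses `m_type`, `kappa_m`, `chem`).
#' @return The (unsigned) coupling current; 0 when `m_type = "none"`.
#' @export
multiplex_coupling <- function(state_own, replica_delayed, spec) {
  switch(spec$m_type,
    none = 0,
    electrical = spec$kappa_m * (replica_delayed - state_own),
    spec$kappa_m * (state_own - spec$chem$v_syn) *
      sigmoid_gate(replica_delayed, spec$chem)
  )
}

#' Deterministic drift of the multiplex network
#'
#' Reference (R-level) evaluation of the right-hand side of the network
#' equations:
#' `dv/dt = v - v^3/3 - w + E + M^e - C - M^c` (chemical terms flip to `+` for
#' excitatory polarity) and `dw/dt = epsilon * (v + alpha - beta * w)`.
#' The fast production path is the compiled integrator; this function is the
#' module's explicit drift used for initialization, landscape consistency and
#' cross-checking the compiled code.
#'
#' @param state A [network_state()] with `2 x N` (or `1 x N`) matrices.
#' @param delayed A list with elements `v_intra` (matrix like `state$v`:
#'   the delayed potential of every neuron at its layer's intra-layer lag) and,
#'   when multiplexing is active, `v_mux` (delayed potentials at lag `tau_m`).
#' @param spec A [multiplex_spec()] or (single layer) [layer_spec()].
#' @return A list with matrices `dv` and `dw`.
#' @export
drift <- function(state, delayed, spec) {
  if (inherits(spec, "layer_spec"))
    spec <- structure(list(layer1 = spec, layer2 = NULL, m_type = "none",
                           kappa_m = 0, tau_m = 0,
                           chem = spec$chem),
                      class = "multiplex_spec")
  layers <- list(spec$layer1, spec$layer2)
  n_layers <- nrow(state$v)
  N <- ncol(state$v)
  if (is.null(delayed$v_intra)) stop("missing delayed values: v_intra",
                                     call. = FALSE)
  if (spec$m_type != "none" && is.null(delayed$v_mux))
    stop("missing delayed values: v_mux (multiplex lag)", call. = FALSE)
  dv <- matrix(0, n_layers, N)
  dw <- matrix(0, n_layers, N)
  for (l in seq_len(n_layers)) {
    lay <- layers[[l]]
    np <- lay$neuron
    for (i in seq_len(N)) {
      vi <- state$v[l, i]
      wi <- state$w[l, i]
      nb <- ring_neighbors(i - 1L, lay$range_n, N) + 1L
      coup <- 0
      if (lay$kappa > 0) {
        vnb <- delayed$v_intra[l, nb]
        coup <- if (lay$synapse == "electrical")
          electrical_coupling(vi, vnb, lay$kappa, lay$range_n)
        else
          -chemical_coupling(vi, vnb, lay$kappa, lay$range_n, lay$chem)
      }
      mux <- 0
      if (spec$m_type != "none" && n_layers == 2) {
        m <- multiplex_coupling(vi, delayed$v_mux[3 - l, i], spec)
        mux <- if (spec$m_type == "chemical_inhibitory") -m else m
      }
      dv[l, i] <- vi - vi^3 / 3 - wi + coup + mux
      dw[l, i] <- np$epsilon * (vi + np$alpha - np$beta * wi)
    }
  }
  list(dv = dv, dw = dw)
}

#' Initial history for the delayed system
#'
#' Delay differential equations need the state on `[-tau_max, 0]`. The
#' `"constant"` policy fills all lags with the initial state; `"perturbed"`
#' keeps the history at the initial state but offsets the time-zero membrane
#' potentials by `offset` (used by deterministic excitability probes).
#'
#' @param initial A [network_state()].
#' @param policy `"constant"` or `"perturbed"`.
#' @param offset Perturbation added to `v` at time zero (perturbed policy):
#'   a scalar applied to every neuron, or a matrix shaped like `initial$v`
#'   (e.g. to kick a single neuron).
#' @return An object of class `"history_buffer"` with fields `v0` (history
#'   value at every lag), `v_start` (state at t = 0) and `policy`.
#' @examples
#' h <- make_initial_history(network_state(matrix(-1), matrix(-2 / 3)))
#' history_depth(25, 0.01)  # 2500 slots
#' @export
make_initial_history <- function(initial, policy = c("constant", "perturbed"),
                                 offset = 0.5) {
  policy <- match.arg(policy)
  off <- if (policy == "perturbed") offset else 0
  if (is.matrix(off)) stopifnot(all(dim(off) == dim(initial$v)))
  v_start <- initial$v + off
  structure(list(v0 = initial$v, w0 = initial$w, v_start = v_start,
                 policy = policy, offset = off),
            class = "history_buffer")
}

#' @rdname make_initial_history
#' @param tau_max Largest delay in the system.
#' @param dt Integration step.
#' @export
history_depth <- function(tau_max, dt) as.integer(round(tau_max / dt))
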