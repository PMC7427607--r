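#' Renewal-process spike train
#'
#' Generates a spike train with i.i.d. interspike intervals from a named
#' family, for calibrating the R_T estimator against closed forms:
#' `periodic` (CV = 0), `poisson` (exponential ISIs, CV = 1), `gamma` with
#' shape `k` (CV = 1/sqrt(k)).
#'
#' @param family `"poisson"`, `"gamma"` or `"periodic"`.
#' @param mean_isi Mean interspike interval, > 0.
#' @param horizon Generate spikes up to this time.
#' @param k Gamma shape parameter (>= 1).
#' @param seed Optional seed (uses the R RNG).
#' @return Ordered numeric spike times in `(0, horizon]`.
#' @examples
#' renewal_train("periodic", 10, 100)  # 10, 20, ..., 100
#' @export
renewal_train <- function(family = c("poisson", "gamma", "periodic"),
                          mean_isi, horizon, k = 1, seed = NULL) {
  family <- match.arg(family)
  stopifnot(mean_isi > 0, horizon > mean_isi, k >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_guess <- ceiling(horizon / mean_isi * 1.5 + 10 * sqrt(horizon / mean_isi))
  isi <- switch(family,
    periodic = rep(mean_isi, ceiling(horizon / mean_isi)),
    poisson = stats::rexp(n_guess, rate = 1 / mean_isi),
    gamma = stats::rgamma(n_guess, shape = k, rate = k / mean_isi))
  times <- cumsum(isi)
  while (family != "periodic" && max(times) < horizon) {
    extra <- switch(family,
      poisson = stats::rexp(n_guess, rate = 1 / mean_isi),
      gamma = stats::rgamma(n_guess, shape = k, rate = k / mean_isi))
    times <- c(times, max(times) + cumsum(extra))
  }
  times[times <= horizon]
}

#' Synthetic voltage trace with pulses at known times
#'
#' Builds a trace at baseline `baseline` with stereotyped piecewise-linear
#' excursions to `peak` at the given times (rise over `rise` time units, fall
#' over `fall`), qualitatively matching a relaxation-oscillator spike. Used
#' to test [detect_spikes()] against constructed ground truth.
#'
#' @param spike_times Pulse onset times (must be separated by more than
#'   `rise + fall`).
#' @param dt Sampling step.
#' @param t_end Trace end time (default: last pulse + 5 * fall).
#' @param baseline,peak Resting and peak potentials.
#' @param rise,fall Rise and fall durations.
#' @return A tibble `time`, `layer`, `neuron`, `v` compatible with
#'   [detect_spikes()].
#' @export
pulse_trace <- function(spike_times, dt = 0.1, t_end = NULL,
                        baseline = -1.3, peak = 1.8, rise = 1, fall = 3) {
  if (length(spike_times) > 1 && any(diff(sort(spike_times)) <= rise + fall))
    stop("overlapping pulses: spike times closer than rise + fall",
         call. = FALSE)
  t_end <- t_end %||% ((if (length(spike_times)) max(spike_times) else 0) +
                         5 * fall)
  tm <- seq(0, t_end, by = dt)
  v <- rep(baseline, length(tm))
  for (ts in spike_times) {
    up <- tm >= ts - rise & tm < ts
    v[up] <- baseline + (peak - baseline) * (tm[up] - (ts - rise)) / rise
    dn <- tm >= ts & tm < ts + fall
    v[dn] <- peak - (peak - baseline) * (tm[dn] - ts) / fall
  }
  tibble::tibble(time = tm, layer = 1L, neuron = 1L, v = v)
}

#' Multi-neuron renewal fixture
#'
#' Independent renewal trains for N neurons, as a spike-train tibble, for
#' testing the network-level R_T against the mixture closed form.
#'
#' @param n_neurons Number of neurons.
#' @param family,mean_isi,horizon,k Passed to [renewal_train()]; `mean_isi`
#'   and `k` may be vectors of length `n_neurons`.
#' @param seed Base seed; neuron i uses `seed + i`.
#' @return Tibble `layer`, `neuron`, `time`.
#' @export
multi_neuron_fixture <- function(n_neurons, family = "gamma", mean_isi = 1,
                                 horizon = 1e4, k = 1, seed = 1) {
  mean_isi <- rep_len(mean_isi, n_neurons)
  k <- rep_len(k, n_neurons)
  purrr::map_dfr(seq_len(n_neurons), function(i) {
    tibble::tibble(
      layer = 1L, neuron = i,
      time = renewal_train(family, mean_isi[i], horizon, k[i],
                           seed = seed + i))
  })
}
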