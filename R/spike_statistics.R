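#' Detect spikes in a voltage trace
#'
#' Schmitt-trigger detection: a spike is the first upward crossing of
#' `up_threshold` after the potential has been below `rearm_threshold`; the
#' hysteresis gap spans the unstable middle branch of the cubic nullcline, so
#' subthreshold noise never triggers. Spike times are linearly interpolated
#' between the bracketing samples; samples before `t_min` are ignored.
#'
#' @param trace A tibble with columns `time`, `layer`, `neuron`, `v` (as
#'   produced by [simulate_network()] with `record_stride > 0` or by
#'   [pulse_trace()]).
#' @param up_threshold,rearm_threshold Detector thresholds
#'   (`rearm_threshold < up_threshold`). Defaults +1 / -1: the rest state sits
#'   near `v = -1` and spike excursions reach `v ~ +sqrt(3)`.
#' @param t_min Discard spikes before this time.
#' @return A tibble `layer`, `neuron`, `time` of class `"spike_trains"`
#'   (strictly increasing within each neuron; empty trains allowed).
#' @export
detect_spikes <- function(trace, up_threshold = 1.0, rearm_threshold = -1.0,
                          t_min = 0) {
  stopifnot(rearm_threshold < up_threshold)
  res <- trace |>
    dplyr::group_by(.data$layer, .data$neuron) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(time = schmitt_crossings(
        df$time, df$v, up_threshold, rearm_threshold, t_min))
    }) |>
    dplyr::ungroup()
  class(res) <- c("spike_trains", class(res))
  res
}

# vectorized Schmitt trigger over one neuron's samples
schmitt_crossings <- function(t, v, up, rearm, t_min) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  armed <- v[1] < rearm
  out <- numeric(0)
  for (k in 2:n) {
    if (armed && v[k] >= up && v[k - 1] < up) {
      ts <- t[k - 1] + (t[k] - t[k - 1]) * (up - v[k - 1]) / (v[k] - v[k - 1])
      if (ts >= t_min) out <- c(out, ts)
      armed <- FALSE
    } else if (!armed && v[k] < rearm) {
      armed <- TRUE
    }
  }
  out
}

#' Coefficient of variation of one spike train
#'
#' `R_T^i = sqrt(<ISI^2> - <ISI>^2) / <ISI>` with plain (population) means
#' over the observed interspike intervals. Zero for a periodic train, 1 for a
#' Poisson train. Needs at least two ISIs (three spikes); otherwise `NA`
#' (undefined, deliberately not zero).
#'
#' @param train Ordered numeric spike times of one neuron.
#' @return `R_T^i` (scalar) or `NA_real_`.
#' @examples
#' cv_single(c(0, 1, 4))  # ISIs {1, 3}: sqrt(5 - 4) / 2 = 0.5
#' @export
cv_single <- function(train) {
  isi <- diff(train)
  if (length(isi) < 2) return(NA_real_)
  m1 <- mean(isi); m2 <- mean(isi^2)
  sqrt(max(0, m2 - m1^2)) / m1
}

#' Network coefficient of variation R_T
#'
#' The network-level spike-regularity statistic: per-neuron first and second
#' ISI moments are averaged over neurons *first*,
#' `<ISI-bar> = (1/N) sum_i <ISI_i>`, `<ISI^2-bar> = (1/N) sum_i <ISI_i^2>`,
#' and then `R_T = sqrt(<ISI^2-bar> - <ISI-bar>^2) / <ISI-bar>`. This is not
#' the average of per-neuron CVs: dispersion of mean ISIs across neurons
#' contributes.
#'
#' A summary is flagged undefined (`rt = NA`) when the across-neuron mean ISI
#' count falls below `min_isi`; neurons contribute to the moment averages
#' once they have at least one ISI.
#'
#' @param spikes A spike-train tibble (`layer`, `neuron`, `time`) or a bare
#'   tibble with those columns; one layer at a time (filter first or pass
#'   `layer`).
#' @param n_neurons Total number of neurons N in the layer (zero-spike
#'   neurons are invisible in `spikes`, so N cannot be inferred).
#' @param layer Which layer to summarize if several are present.
#' @param min_isi Undefined-R_T policy threshold (mean ISIs per neuron).
#' @return An object of class `"isi_summary"`; see [tidy.isi_summary()] and
#'   [glance.isi_summary()].
#' @examples
#' tr <- tibble::tibble(layer = 1, neuron = rep(1:2, each = 3),
#'                      time = c(0, 2, 4, 0, 4, 8))
#' glance(cv_network(tr, n_neurons = 2, min_isi = 2))$rt  # 1/3
#' @export
cv_network <- function(spikes, n_neurons, layer = NULL, min_isi = 5) {
  if (!is.null(layer)) {
    l <- layer
    spikes <- dplyr::filter(spikes, .data$layer == l)
  }
  per <- spikes |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(
      n_isi = max(0L, dplyr::n() - 1L),
      mean_isi = if (dplyr::n() >= 2) mean(diff(.data$time)) else NA_real_,
      mean_isi2 = if (dplyr::n() >= 2) mean(diff(.data$time)^2) else NA_real_,
      .groups = "drop")
  n_isi_total <- sum(per$n_isi)
  mean_count <- n_isi_total / n_neurons
  inc <- dplyr::filter(per, .data$n_isi >= 1)
  if (mean_count < min_isi || nrow(inc) == 0) {
    net <- list(rt = NA_real_, mean_isi = NA_real_, mean_isi2 = NA_real_)
  } else {
    m1 <- mean(inc$mean_isi)
    m2 <- mean(inc$mean_isi2)
    net <- list(rt = sqrt(max(0, m2 - m1^2)) / m1, mean_isi = m1,
                mean_isi2 = m2)
  }
  per$rt_i <- unname(vapply(
    split(spikes$time, spikes$neuron)[as.character(per$neuron)],
    cv_single, 0))
  structure(list(per_neuron = per, rt = net$rt, mean_isi = net$mean_isi,
                 mean_isi2 = net$mean_isi2, n_neurons = n_neurons,
                 n_included = nrow(inc), n_isi_total = n_isi_total,
                 mean_isi_count = mean_count, min_isi = min_isi),
            class = "isi_summary")
}

#' @export
print.isi_summary <- function(x, ...) {
  cat(sprintf(
    "<isi_summary> R_T=%s from %d ISIs over %d/%d neurons (mean %.1f/neuron)\n",
    format(x$rt, digits = 4), x$n_isi_total, x$n_included, x$n_neurons,
    x$mean_isi_count))
  invisible(x)
}

#' Tidy per-neuron ISI statistics
#'
#' @param x An `isi_summary`.
#' @param ... Unused.
#' @return Tibble with one row per spiking neuron: `neuron`, `n_isi`,
#'   `mean_isi`, `mean_isi2`, `rt_i`.
#' @export
tidy.isi_summary <- function(x, ...) x$per_neuron

#' One-row network summary
#'
#' @param x An `isi_summary`.
#' @param ... Unused.
#' @return One-row tibble: `rt`, `mean_isi`, `mean_isi2`, `n_isi_total`,
#'   `n_included`, `n_neurons`, `defined`.
#' @export
glance.isi_summary <- function(x, ...) {
  tibble::tibble(rt = x$rt, mean_isi = x$mean_isi, mean_isi2 = x$mean_isi2,
                 n_isi_total = x$n_isi_total, n_included = x$n_included,
                 n_neurons = x$n_neurons, defined = !is.na(x$rt))
}
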