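#' Log-spaced noise-amplitude grid
#'
#' @param from,to Grid limits (inclusive decades).
#' @param per_decade Points per decade (default 10).
#' @return Ascending numeric vector.
#' @export
sigma_grid <- function(from = 1e-7, to = 1e-1, per_decade = 10) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

#' R_T versus noise amplitude
#'
#' For each noise amplitude on `grid`, runs `config$n_realizations`
#' independent simulations, detects spikes, computes the network [cv_network()]
#' R_T of the requested layer, and averages over realizations. A grid point is
#' flagged undefined when any realization fails the minimum-ISI policy
#' (mirroring that published R_T curves are drawn only where spiking occurs).
#' In multiplex sweeps both layers receive the same noise amplitude.
#'
#' @param spec A [layer_spec()] (isolated layer) or [multiplex_spec()].
#' @param grid Noise amplitudes (ascending), e.g. [sigma_grid()].
#' @param config A [sim_config()].
#' @param layer Layer whose spikes enter R_T (default 1; use 2 for the
#'   multiplexing experiments).
#' @param min_isi Undefined-R_T threshold, see [cv_network()].
#' @return A tibble of class `"sisr_rt_curve"`: `sigma`, `rt` (mean over
#'   realizations), `rt_sd`, `n_isi` (mean ISIs per neuron), `defined`.
#'   The spec and config travel along as attributes.
#' @export
rt_curve <- function(spec, grid, config, layer = 1, min_isi = 5) {
  stopifnot(!is.unsorted(grid))
  if (length(grid) == 0) {
    rows <- tibble::tibble(sigma = numeric(0), rt = numeric(0),
                           rt_sd = numeric(0), n_isi = numeric(0),
                           defined = logical(0))
    attr(rows, "spec") <- spec
    attr(rows, "config") <- config
    class(rows) <- c("sisr_rt_curve", class(rows))
    return(rows)
  }
  rows <- purrr::map_dfr(seq_along(grid), function(k) {
    sg <- grid[k]
    per_real <- purrr::map_dfr(seq_len(config$n_realizations), function(r) {
      sp <- set_layer_sigma(spec, sg)
      seed_r <- (config$seed * 1000 + k * 37 + r * 101) %% 2147483647
      sim <- simulate_network(sp, config, seed = seed_r)
      N <- if (inherits(sp, "layer_spec")) sp$n_neurons
           else sp$layer1$n_neurons
      g <- glance(cv_network(sim$spikes, n_neurons = N, layer = layer,
                             min_isi = min_isi))
      g$realization <- r
      g
    })
    tibble::tibble(
      sigma = sg,
      rt = mean(per_real$rt),
      rt_sd = stats::sd(per_real$rt),
      n_isi = mean(per_real$n_isi_total) /
        (if (inherits(spec, "layer_spec")) spec$n_neurons
         else spec$layer1$n_neurons),
      defined = all(per_real$defined))
  })
  rows$rt[!rows$defined] <- NA_real_
  attr(rows, "spec") <- spec
  attr(rows, "config") <- config
  attr(rows, "layer") <- layer
  class(rows) <- c("sisr_rt_curve", class(rows))
  rows
}

# set the swept noise amplitude on every layer of a spec
set_layer_sigma <- function(spec, sigma) {
  if (inherits(spec, "layer_spec")) {
    spec$sigma <- sigma
  } else {
    spec$layer1$sigma <- sigma
    spec$layer2$sigma <- sigma
  }
  spec
}

#' Minimum of an R_T curve
#'
#' Minimum over the defined grid points, ties broken toward smaller sigma.
#' The width column reports the log10 extent of the sigma range over which
#' `rt <= plateau_factor * rt_min` (the flat bottom of a pronounced-SISR
#' curve).
#'
#' @param curve A [rt_curve()] result (any tibble with `sigma`, `rt`,
#'   `defined`).
#' @param plateau_factor Multiplier defining the plateau threshold.
#' @return One-row tibble: `sigma_star`, `rt_min`, `width_decades`,
#'   `n_defined`.
#' @export
rt_min <- function(curve, plateau_factor = 2) {
  def <- dplyr::filter(curve, .data$defined, is.finite(.data$rt))
  if (nrow(def) == 0) stop("all grid points undefined: no R_T minimum",
                           call. = FALSE)
  i <- which(def$rt == min(def$rt))[1]
  plateau <- def$sigma[def$rt <= plateau_factor * def$rt[i]]
  tibble::tibble(sigma_star = def$sigma[i], rt_min = def$rt[i],
                 width_decades = if (length(plateau) > 1)
                   log10(max(plateau) / min(plateau)) else 0,
                 n_defined = nrow(def))
}

#' Deterministic excitability scan of a network configuration
#'
#' Classifies a (multiplex) configuration for the SISR protocol. Noise-free
#' runs kicked out of equilibrium at time zero must not sustain spiking
#' (otherwise coherent oscillations would be bifurcation-induced, not
#' noise-induced). Two kicks are probed, because delayed networks harbour
#' distinct attractor families: a homogeneous kick of every neuron (seeding
#' synchronous reverberation) and a localized kick of a single neuron in
#' layer 1 (seeding rotating-wave activity). If either run shows more than
#' one spike on any neuron during the second half of the horizon (the first
#' half absorbs the kick's excursion and its delayed echoes) the cell is
#' flagged `"oscillatory"`. A probe run at
#' `sigma_probe` that fails to elicit repeated spiking in any layer (fewer
#' than two spikes per neuron on average, i.e. not a single interspike
#' interval) flags the cell `"hyper_excitable"`: the multiplexing has made
#' the fixed point so stable that even sizeable noise cannot sustain firing. Everything else is
#' `"excitable"`. The horizon should cover several periods of any suspected
#' network oscillation.
#'
#' @param spec A [multiplex_spec()] or [layer_spec()].
#' @param config A [sim_config()] (its `t_end`/`t_transient` set the horizon
#'   of both runs).
#' @param sigma_probe Noise amplitude of the hyper-excitability probe.
#' @param perturb_offset Size of the time-zero kick of the noise-free run
#'   (scalar: applied to every neuron).
#' @return One-row tibble: `status`, `max_spikes_sigma0` (per-neuron maximum
#'   in the second half), `n_spikes_probe`.
#' @export
excitability_scan <- function(spec, config, sigma_probe = 1e-2,
                              perturb_offset = 0.5) {
  spec0 <- set_layer_sigma(spec, 0)
  N <- if (inherits(spec, "layer_spec")) spec$n_neurons
       else spec$layer1$n_neurons
  nl <- if (inherits(spec, "layer_spec")) 1L else 2L
  off_one <- matrix(0, nl, N)
  off_one[1, 1] <- perturb_offset
  max0 <- 0L
  for (off in list(perturb_offset, off_one)) {
    sim0 <- simulate_network(spec0, config, history_policy = "perturbed",
                             perturb_offset = off)
    settled <- dplyr::filter(sim0$spikes, .data$time > config$t_end / 2)
    per_neuron <- dplyr::count(settled, .data$layer, .data$neuron)
    max0 <- max(max0,
                if (nrow(per_neuron) == 0) 0L else max(per_neuron$n))
  }
  if (max0 > 1) {
    return(tibble::tibble(status = "oscillatory",
                          max_spikes_sigma0 = max0,
                          n_spikes_probe = NA_integer_))
  }
  simp <- simulate_network(set_layer_sigma(spec, sigma_probe), config,
                           seed = config$seed + 1)
  N <- if (inherits(spec, "layer_spec")) spec$n_neurons
       else spec$layer1$n_neurons
  n_layers <- if (inherits(spec, "layer_spec")) 1L else 2L
  per_capita <- vapply(seq_len(n_layers), function(l)
    sum(simp$spikes$layer == l) / N, 0)
  tibble::tibble(
    status = if (max(per_capita) < 2) "hyper_excitable" else "excitable",
    max_spikes_sigma0 = max0, n_spikes_probe = nrow(simp$spikes))
}

#' Layer-2 R_T minimum over the multiplexing parameter plane
#'
#' For each `(kappa_m, tau_m)` cell: run the deterministic
#' [excitability_scan()]; if the cell is excitable, sweep the noise grid with
#' [rt_curve()] restricted to layer-2 spikes and record [rt_min()]. Masked
#' cells (oscillatory or hyper-excitable at `sigma = 0`) carry no R_T value.
#'
#' @param spec_template A [multiplex_spec()] whose `kappa_m`/`tau_m` are
#'   overwritten cell by cell.
#' @param kappa_grid,tau_grid Multiplexing strengths and delays to sweep.
#' @param grid Noise amplitudes for the R_T sweep.
#' @param config A [sim_config()].
#' @param scan_config Optional shorter [sim_config()] for the deterministic
#'   excitability scans (defaults to `config`).
#' @param min_isi Undefined-R_T threshold.
#' @return A tibble of class `"sisr_heatmap"`: `kappa_m`, `tau_m`, `status`,
#'   `rt_min`, `sigma_star` (`NA` for masked or all-undefined cells).
#' @export
multiplex_heatmap <- function(spec_template, kappa_grid, tau_grid, grid,
                              config, scan_config = NULL, min_isi = 5) {
  scan_config <- scan_config %||% config
  cells <- tidyr::expand_grid(kappa_m = kappa_grid, tau_m = tau_grid)
  out <- purrr::pmap_dfr(cells, function(kappa_m, tau_m) {
    sp <- spec_template
    sp$kappa_m <- kappa_m
    sp$tau_m <- tau_m
    sc <- excitability_scan(sp, scan_config)
    if (sc$status != "excitable")
      return(tibble::tibble(kappa_m = kappa_m, tau_m = tau_m,
                            status = sc$status, rt_min = NA_real_,
                            sigma_star = NA_real_))
    cur <- rt_curve(sp, grid, config, layer = 2, min_isi = min_isi)
    if (!any(cur$defined))
      return(tibble::tibble(kappa_m = kappa_m, tau_m = tau_m,
                            status = "excitable", rt_min = NA_real_,
                            sigma_star = NA_real_))
    mn <- rt_min(cur)
    tibble::tibble(kappa_m = kappa_m, tau_m = tau_m, status = "excitable",
                   rt_min = mn$rt_min, sigma_star = mn$sigma_star)
  })
  attr(out, "spec") <- spec_template
  attr(out, "config") <- config
  class(out) <- c("sisr_heatmap", class(out))
  out
}
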