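#' Hopf bifurcation threshold of an isolated neuron
#'
#' Solves the zero-trace condition `1 - v*^2 - epsilon * beta = 0` jointly
#' with the fixed-point equations for `beta`. For `beta > beta_h` the neuron
#' is excitable (unique stable fixed point, spikes only as noise-triggered
#' excursions); for `beta <= beta_h` it oscillates. In the limit
#' `epsilon -> 0` the threshold tends to `(v* + alpha) / w*` at `v* = -1`,
#' i.e. 0.75 for `alpha = 0.5`.
#'
#' @param epsilon Timescale-separation ratio, > 0.
#' @param alpha Recovery offset.
#' @return The Hopf value `beta_h` (scalar).
#' @examples
#' round(hopf_beta(5e-4, 0.5), 4)  # 0.7497
#' @export
hopf_beta <- function(epsilon, alpha = 0.5) {
  stopifnot(epsilon > 0)
  g <- function(beta) {
    v <- -sqrt(1 - epsilon * beta)
    v - v^3 / 3 - (v + alpha) / beta
  }
  sol <- tryCatch(stats::uniroot(g, c(1e-3, min(2, 1 / epsilon - 1e-9)),
                                 tol = 1e-13),
                  error = function(e) NULL)
  if (is.null(sol)) stop("no Hopf value in (0, 2]", call. = FALSE)
  beta <- sol$root
  v <- -sqrt(1 - epsilon * beta)
  detJ <- (1 - v^2) * (-epsilon * beta) + epsilon
  if (detJ <= 0) stop("zero-trace point is not a Hopf point (det <= 0)",
                      call. = FALSE)
  beta
}

#' Homogeneous fixed point of an isolated layer
#'
#' Intersects the recovery nullcline `w = (v + alpha) / beta` with the cubic
#' nullcline of the coupled fast dynamics. At a homogeneous state the
#' diffusive electrical coupling vanishes, so electrical layers keep the
#' uncoupled fixed point; inhibitory chemical layers solve
#' `v - v^3/3 - w - kappa * (v - v_syn) * Gamma(v) = 0`.
#'
#' @param layer A [layer_spec()] or [neuron_params()] (treated as uncoupled).
#' @return An object of class `"sisr_equilibrium"`: list with `v`, `w`,
#'   `beta_h`, `excitable` flag and the drift `residual` at the point.
#' @examples
#' fp <- fixed_point(layer_spec(kappa = 0))
#' c(fp$v, fp$w)  # -1, -2/3
#' @export
fixed_point <- function(layer) {
  if (inherits(layer, "neuron_params"))
    layer <- layer_spec(kappa = 0, neuron = layer)
  np <- layer$neuron
  chem_term <- function(v) {
    if (layer$synapse == "chemical_inhibitory" && layer$kappa > 0)
      layer$kappa * (v - layer$chem$v_syn) * sigmoid_gate(v, layer$chem)
    else 0
  }
  h <- function(v) v - v^3 / 3 - (v + np$alpha) / np$beta - chem_term(v)
  sol <- tryCatch(stats::uniroot(h, c(-2.5, -0.2), tol = 1e-14),
                  error = function(e)
                    stop("no fixed point bracketed in [-2.5, -0.2]",
                         call. = FALSE))
  v <- sol$root
  w <- (v + np$alpha) / np$beta
  bh <- hopf_beta(np$epsilon, np$alpha)
  structure(list(v = v, w = w, beta_h = bh,
                 excitable = np$beta > bh,
                 residual = h(v)),
            class = "sisr_equilibrium")
}

#' @export
print.sisr_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> v*=%.8f w*=%.8f beta_h=%.4f excitable=%s\n",
              x$v, x$w, x$beta_h, x$excitable))
  invisible(x)
}

# Resolve the tau-proxy neighbour value: numeric scalar (frozen), "self"
# (neighbour tracks v itself), or NULL -> the layer's fixed-point v*.
resolve_vbar <- function(layer, vbar) {
  if (is.null(vbar)) fixed_point(layer)$v else vbar
}

#' Interaction potential of the fast variable
#'
#' Double-well potential `U(v; w)` whose negative gradient is the fast drift
#' of an isolated layer in the singular limit `epsilon -> 0`:
#' `U = v^4/12 - v^2/2 + v*w` plus the coupling term, electrical
#' `- kappa/(2n) * sum_j (v * vbar_j - v^2/2)` or chemical
#' `+ kappa/(2n) * sum_j (1/2) * v * (v - 2*v_syn) * Gamma(vbar_j)`.
#'
#' Because the true coupling involves *delayed* neighbour potentials, a static
#' landscape needs a substitution for `v_j(t - tau)`: either a frozen scalar
#' `vbar` (default: the layer's fixed point `v*`), which the caller can sweep
#' to expose delay effects, or `vbar = "self"` (the synchronized substitution
#' `v_j(t - tau) -> v`), which reproduces the depth-vs-kappa and symmetry
#' behaviour of the potential-landscape figures.
#'
#' @param layer A [layer_spec()] (its `synapse`, `kappa`, `range_n`, `chem`).
#' @param v Fast-variable value(s) at which to evaluate.
#' @param w Slow-variable value (scalar).
#' @param vbar Frozen neighbour value: numeric scalar, `"self"`, or NULL for
#'   the fixed-point default.
#' @return `U(v)` (same length as `v`).
#' @export
potential <- function(layer, v, w, vbar = NULL) {
  base <- v^4 / 12 - v^2 / 2 + v * w
  k <- layer$kappa
  if (k == 0) return(base)
  if (identical(vbar, "self")) {
    if (layer$synapse == "electrical")
      base - k * v^2 / 2
    else
      base + k * 0.5 * v * (v - 2 * layer$chem$v_syn) * sigmoid_gate(v, layer$chem)
  } else {
    vb <- resolve_vbar(layer, vbar)
    if (layer$synapse == "electrical")
      base - k * (v * vb - v^2 / 2)
    else
      base + k * 0.5 * v * (v - 2 * layer$chem$v_syn) * sigmoid_gate(vb, layer$chem)
  }
}

# dU/dv for the same conventions
potential_grad <- function(layer, v, w, vbar = NULL) {
  base <- v^3 / 3 - v + w
  k <- layer$kappa
  if (k == 0) return(base)
  if (identical(vbar, "self")) {
    if (layer$synapse == "electrical") base - k * v
    else {
      ch <- layer$chem
      g <- sigmoid_gate(v, ch)
      base + k * ((v - ch$v_syn) * g +
                    0.5 * v * (v - 2 * ch$v_syn) * ch$lambda * g * (1 - g))
    }
  } else {
    vb <- resolve_vbar(layer, vbar)
    if (layer$synapse == "electrical") base - k * (vb - v)
    else base + k * (v - layer$chem$v_syn) * sigmoid_gate(vb, layer$chem)
  }
}

#' Critical points of the interaction potential
#'
#' All real roots of `dU/dv = 0` at slow value `w`, sorted ascending. With
#' three roots they are the left stable, middle unstable and right stable
#' branches of the cubic nullcline (`v_l* < v_m* < v_r*`). Roots are polished
#' to residual `< 1e-10`.
#'
#' @inheritParams potential
#' @return Numeric vector of roots with attribute `three_roots` (logical).
#' @examples
#' cubic_roots(layer_spec(kappa = 0), w = 0)  # -sqrt(3), 0, sqrt(3)
#' @export
cubic_roots <- function(layer, w, vbar = NULL) {
  k <- layer$kappa
  self_chem <- identical(vbar, "self") && layer$synapse != "electrical" && k > 0
  if (!self_chem) {
    # dU/dv is an exact cubic v^3/3 + c1 v + c0
    if (k == 0) { c1 <- -1; c0 <- w }
    else if (identical(vbar, "self")) { c1 <- -(1 + k); c0 <- w }
    else {
      vb <- resolve_vbar(layer, vbar)
      if (layer$synapse == "electrical") { c1 <- k - 1; c0 <- w - k * vb }
      else {
        g <- sigmoid_gate(vb, layer$chem)
        c1 <- k * g - 1; c0 <- w - k * g * layer$chem$v_syn
      }
    }
    z <- polyroot(c(c0, c1, 0, 1 / 3))
    re <- Re(z)[abs(Im(z)) < 1e-6 * (1 + abs(Re(z)))]
    roots <- sort(re)
  } else {
    grid <- seq(-3.2, 3.2, length.out = 1281)
    gv <- potential_grad(layer, grid, w, vbar)
    sgn <- which(gv[-1] * gv[-length(gv)] < 0)
    roots <- vapply(sgn, function(j)
      stats::uniroot(function(v) potential_grad(layer, v, w, vbar),
                     c(grid[j], grid[j + 1]), tol = 1e-13)$root, 0)
    roots <- sort(c(roots, grid[gv == 0]))
  }
  # Newton polish
  for (it in 1:4) {
    fp <- potential_grad(layer, roots, w, vbar)
    h <- 1e-6
    d <- (potential_grad(layer, roots + h, w, vbar) -
            potential_grad(layer, roots - h, w, vbar)) / (2 * h)
    step <- ifelse(abs(d) > 1e-12, fp / d, 0)
    roots <- roots - step
  }
  roots <- sort(roots)
  structure(roots, three_roots = length(roots) == 3)
}

#' Energy barriers of the double well
#'
#' `Delta_U_l = U(v_m*) - U(v_l*)` (crossed to fire a spike) and
#' `Delta_U_r = U(v_m*) - U(v_r*)` (crossed to return to rest), both >= 0.
#'
#' @inheritParams potential
#' @return Named numeric `c(dU_l, dU_r)`; `NA` (with a message attribute) if
#'   the well is single.
#' @examples
#' barriers(layer_spec(kappa = 0), w = 0)  # c(0.75, 0.75)
#' @export
barriers <- function(layer, w, vbar = NULL) {
  r <- cubic_roots(layer, w, vbar)
  if (length(r) < 3) return(c(dU_l = NA_real_, dU_r = NA_real_))
  u <- potential(layer, r, w, vbar)
  c(dU_l = max(0, u[2] - u[1]), dU_r = max(0, u[2] - u[3]))
}

# Interval of w over which the potential has three critical points,
# located by scan + bisection (works for every vbar convention).
three_root_w_interval <- function(layer, vbar = NULL, w_lim = c(-2.5, 2.5)) {
  has3 <- function(w) isTRUE(attr(cubic_roots(layer, w, vbar), "three_roots"))
  grid <- seq(w_lim[1], w_lim[2], length.out = 201)
  ok <- vapply(grid, has3, TRUE)
  if (!any(ok)) stop("no three-root w interval found", call. = FALSE)
  i <- range(which(ok))
  refine <- function(lo, hi, want_hi) {
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (has3(mid) == want_hi) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (i[1] > 1) refine(grid[i[1] - 1], grid[i[1]], TRUE) else grid[1]
  hi <- if (i[2] < length(grid)) refine(grid[i[2] + 1], grid[i[2]], TRUE)
        else grid[length(grid)]
  sort(c(lo, hi))
}

#' Extremal barrier value F
#'
#' The barrier scale that fixes the upper end of the SISR noise window.
#' Electrical layers: the common barrier at the slow value `w_s` where
#' `Delta_U_l(w_s) = Delta_U_r(w_s)` (1-D root find; for `kappa = 0` this is
#' the symmetric double well with `F = 3/4` at `w_s = 0`). Chemical layers:
#' the maximum over the three-root `w` interval of the smaller of the two
#' barriers (which coincides with the equal-barrier value whenever the two
#' barrier curves cross).
#'
#' @inheritParams potential
#' @return List with `F`, `w_s` (argmax / equal-barrier location) and the
#'   barriers there.
#' @examples
#' f_extremal(layer_spec(kappa = 0))$F  # 0.75
#' @export
f_extremal <- function(layer, vbar = NULL) {
  iv <- three_root_w_interval(layer, vbar)
  pad <- 1e-6 * diff(iv)
  iv <- iv + c(pad, -pad)
  if (layer$synapse == "electrical") {
    d <- function(w) { b <- barriers(layer, w, vbar); b[1] - b[2] }
    dl <- d(iv[1]); dh <- d(iv[2])
    if (!is.finite(dl) || !is.finite(dh) || dl * dh > 0)
      stop("equal-barrier point not bracketed in the three-root interval",
           call. = FALSE)
    ws <- stats::uniroot(d, iv, tol = 1e-12)$root
  } else {
    obj <- function(w) { b <- barriers(layer, w, vbar); min(b) }
    ws <- stats::optimize(obj, iv, maximum = TRUE, tol = 1e-10)$maximum
  }
  b <- barriers(layer, ws, vbar)
  list(F = min(b), w_s = ws, dU_l = unname(b[1]), dU_r = unname(b[2]))
}

#' Admissible noise window for SISR
#'
#' Kramers-type escape over the left barrier at the resting slow value must be
#' slow enough, and escape anywhere along the slow relaxation fast enough,
#' which bounds the noise amplitude:
#' `sigma_min = sqrt(2 * Delta_U_l(w*) / ln(1/epsilon))` and
#' `sigma_max = sqrt(2 * F / ln(1/epsilon))`.
#'
#' @inheritParams potential
#' @param equilibrium Optional precomputed [fixed_point()] result.
#' @return Object of class `"noise_window"`: list with `sigma_min`,
#'   `sigma_max`, `dU_l_star`, `F`, `empty` flag and the equilibrium.
#' @examples
#' nw <- noise_window(layer_spec(kappa = 0))
#' nw$sigma_max  # sqrt(1.5 / log(2000)) ~= 0.4442
#' @export
noise_window <- function(layer, equilibrium = NULL, vbar = NULL) {
  eq <- equilibrium %||% fixed_point(layer)
  if (!eq$excitable)
    warning("layer is not excitable (beta <= beta_h); window not meaningful")
  b <- barriers(layer, eq$w, vbar)
  dUl <- unname(b[1])
  if (is.na(dUl)) dUl <- 0  # fixed point beyond the fold: no left well
  fe <- f_extremal(layer, vbar)
  ln_inv_eps <- log(1 / layer$neuron$epsilon)
  structure(list(sigma_min = sqrt(2 * dUl / ln_inv_eps),
                 sigma_max = sqrt(2 * fe$F / ln_inv_eps),
                 dU_l_star = dUl, F = fe$F, w_s = fe$w_s,
                 empty = dUl > fe$F, equilibrium = eq),
            class = "noise_window")
}

#' @export
print.noise_window <- function(x, ...) {
  cat(sprintf(
    "<noise_window> sigma_min=%.4g sigma_max=%.4g (dU_l*=%.4g, F=%.4g)%s\n",
    x$sigma_min, x$sigma_max, x$dU_l_star, x$F,
    if (x$empty) " EMPTY" else ""))
  invisible(x)
}

#' Is a noise amplitude inside the SISR window?
#'
#' Checks `Delta_U_l(w*) < sigma^2/2 * ln(1/epsilon) < F` together with the
#' excitability requirement `beta > beta_h`. The margins report the distance
#' of the scaled noise energy `sigma^2/2 * ln(1/epsilon)` to each boundary.
#'
#' @param sigma Noise amplitude(s).
#' @param layer The [layer_spec()].
#' @param window Optional precomputed [noise_window()].
#' @return A tibble with columns `sigma`, `admissible`, `margin_lower`,
#'   `margin_upper`.
#' @export
sisr_admissible <- function(sigma, layer, window = NULL) {
  win <- window %||% noise_window(layer)
  s <- sigma^2 / 2 * log(1 / layer$neuron$epsilon)
  tibble::tibble(
    sigma = sigma,
    admissible = win$equilibrium$excitable &
      sigma > win$sigma_min & sigma < win$sigma_max,
    margin_lower = s - win$dU_l_star,
    margin_upper = win$F - s)
}
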