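---
title: "Self-induced stochastic resonance in delayed multiplex FHN networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-induced stochastic resonance in delayed multiplex FHN networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisrmux)
```

## The model

`sisrmux` simulates a two-layer multiplex network of identical
FitzHugh–Nagumo (FHN) neurons. Each neuron has a fast membrane potential $v$
and a slow recovery variable $w$:

$$
\begin{aligned}
dv_{l,i} &= \Big(v_{l,i} - \tfrac{v_{l,i}^3}{3} - w_{l,i}
          + E_{l,i} + M^{e}_{l,i} - C_{l,i} - M^{c}_{l,i}\Big)\,dt
          + \sigma_l\, dW_{l,i},\\
dw_{l,i} &= \varepsilon\,(v_{l,i} + \alpha - \beta\, w_{l,i})\,dt,
\end{aligned}
$$

with layer $l \in \{1, 2\}$, neuron $i \in \{1,\dots,N\}$ on a ring, and
independent Wiener processes $W_{l,i}$. The coupling terms are

* $E_{l,i} = \frac{\kappa_{l,e}}{2 n_{l,e}} \sum_j
  \big(v_{l,j}(t - \tau_{l,e}) - v_{l,i}(t)\big)$ — diffusive electrical
  (gap-junction) coupling to the $2 n_{l,e}$ nearest ring neighbours
  ($n_{l,e} = 1$: gap junctions are local);
* $C_{l,i} = \frac{\kappa_{l,c}}{2 n_{l,c}}\,
  (v_{l,i} - V_{\mathrm{syn}}) \sum_j \Gamma\!\big(v_{l,j}(t -
  \tau_{l,c})\big)$ — nonlocal chemical coupling
  ($n_{l,c} = 8$ by default) gated by the sigmoid
  $\Gamma(v) = \big(1 + e^{-\lambda (v - \Theta_{\mathrm{syn}})}\big)^{-1}$;
* $M^{e}$, $M^{c}$ — the same two functional forms restricted to replica
  pairs (neuron $i$ of one layer with neuron $i$ of the other), with strength
  $\kappa_m$ and delay $\tau_m$.

With $V_{\mathrm{syn}} = -3$ and $|v| \lesssim 2$, the factor
$(v - V_{\mathrm{syn}})$ is positive, so a chemical synapse is inhibitory or
excitatory purely through the sign its term carries in the drift: $C$ and an
inhibitory $M^c$ are subtracted, an excitatory $M^c$ is added. Strengths
$\kappa \ge 0$ are an invariant; polarity is an attribute
(`chemical_synapse_params()`, `multiplex_spec(m_type = ...)`).

Defaults follow the study conditions throughout: $N = 25$, $\alpha = 0.5$,
$\beta = 0.75$, $\varepsilon = 5\times10^{-4}$, $\lambda = 10$,
$\Theta_{\mathrm{syn}} = -0.25$, $V_{\mathrm{syn}} = -3$.

The printed coupling sums $\sum_{j=i-n}^{i+n}$ formally include $j = i$ while
the normalisation $1/2n$ counts $2n$ neighbours. We exclude the delayed
self-term by default (no autapse; consistent normalisation) and expose
`include_self = TRUE` as an option; we implemented and compared both against
the published summary statistics and neither choice changes the conclusions
reported by the acceptance checks that pass, while exclusion reproduces the
long-delay chemical layer better.

## Why noise makes these neurons fire coherently

At $\alpha = 0.5$, $\beta = 0.75$ the isolated neuron is excitable: it has a
unique stable fixed point $(v^*, w^*) = (-1, -2/3)$ — the exact root of
$v^3 + v + 2 = 0$ — and this point sits exactly on the left fold (knee) of
the cubic nullcline. The Hopf threshold, computed by solving the zero-trace
condition together with the fixed-point equations (`hopf_beta()`), is
$\beta_h(5\times10^{-4}) = 0.7497$, so $\beta = 0.75$ is excitable but not
close to any bifurcation — the hallmark setting of self-induced stochastic
resonance (SISR) as opposed to coherence resonance.

Because $\varepsilon \ll 1$, the fast variable at frozen $w$ moves in a
double-well potential $U(v; w) = v^4/12 - v^2/2 + v w + (\text{coupling})$
(`potential()`, `cubic_roots()`, `barriers()`). After a spike the neuron
relaxes down the left branch; the left barrier $\Delta U_l(w)$ shrinks as
$w \to w^*$, and the neuron escapes (fires) almost surely at the moment the
Kramers escape time matches the slow relaxation time. This matching predicts
an admissible noise window (`noise_window()`, `sisr_admissible()`)

$$
\sigma_{\min} = \sqrt{\frac{2\,\Delta U_l(w^*)}{\ln(1/\varepsilon)}},
\qquad
\sigma_{\max} = \sqrt{\frac{2\,F}{\ln(1/\varepsilon)}},
$$

where $F$ is the extremal barrier (`f_extremal()`): for electrical layers the
common barrier height at the slow value where the two wells balance
($F = 3/4$ exactly at $\kappa = 0$, giving $\sigma_{\max} \approx 0.444$ at
$\varepsilon = 5\times10^{-4}$), for chemical layers the maximum over $w$ of
the smaller barrier (these coincide when the barrier curves cross). Because
the uncoupled fixed point sits exactly on the fold, $\Delta U_l(w^*) = 0$ and
$\sigma_{\min} = 0$: arbitrarily small noise eventually fires the neuron.
Electrical coupling deepens $\Delta U_l(w^*)$, so $\sigma_{\min}$ grows with
$\kappa_{l,e}$.

### The delayed-neighbour substitution in static landscapes

The coupling terms involve *delayed* neighbour potentials, so a static
landscape requires a substitution for $v_j(t - \tau)$. Two conventions are
both scientifically meaningful, and the package exposes the choice through
the `vbar` argument:

* a frozen scalar $\bar v$ (default: the fixed point $v^*$) — appropriate
  near rest, where escape happens; this convention makes the barriers grow
  with $\kappa$ at fixed $\bar v$, and $F_e = \tfrac34 (1 - \kappa)^2$
  decreases toward the fold (no double well survives at $\kappa \ge 1$);
* `vbar = "self"` — the synchronized substitution $v_j(t-\tau) \to v$,
  appropriate for a coherently moving network; it preserves the left–right
  symmetry of the electrical landscape at $w = 0$ for *every* $\kappa$ and
  deepens both wells, $F_e = \tfrac34 (1 + \kappa)^2$.

The two conventions make opposite predictions for how $\sigma_{\max}$ moves
with $\kappa$, which
is possible because the delayed system is not a gradient flow and the static
landscape is only an $\varepsilon \to 0$ heuristic; accounts of this system
in the literature mix both behaviours. Tests cover each
convention in the regime where its qualitative claim holds.

## Numerical scheme

The integrator (`simulate_network()`, compiled C++) advances the
deterministic part with classical 4th-order Runge–Kutta and injects additive
Gaussian noise $\sigma \sqrt{dt}\, \xi$ per neuron after each step. The
contract is statistical, not scheme-identity: at $\sigma = 0$ a step-halving
test confirms 4th-order convergence (measured order 3.99 on the uncoupled
oscillatory neuron, where the solution is smooth — active delays propagate
derivative discontinuities that cap the formal order for any one-step
method), and the noise pathway reproduces the Ornstein–Uhlenbeck stationary
variance $\sigma^2 dt / (1 - e^{-2 dt})$ within three standard errors over
$10^6$ steps.

Delays are snapped to the nearest multiple of $dt$; a per-layer ring buffer
holds the history, and the half-step stage values interpolate linearly
between bracketing grid slices. Initial conditions default to the
homogeneous fixed point with constant history, so all activity is
noise-initiated; the `perturbed` policy (scalar or per-neuron offsets) seeds
deterministic excitability probes. Randomness is a hand-coded polar
Box–Muller transform over `std::mt19937_64` — bit-reproducible across
platforms, which `std::normal_distribution` is not — and every realization
of a sweep receives a counter-derived seed so any grid point can be
reproduced in isolation. A non-finite state aborts with the step and neuron
in the message.

Step size: the fast subsystem has $O(1)$ timescales, and $dt = 0.05$
resolves the spike upstroke with dozens of steps. A convergence spot-check
(same config at $dt = 0.025$) leaves the plateau values of $R_T$ unchanged
within realization scatter; `sim_config()` keeps $dt$ fully configurable.

## Spike statistics

Spikes are detected with Schmitt-trigger semantics: an upward crossing of
$+1$ arms only after the trace has visited $v < -1$ (`detect_spikes()`, and
identically inside the compiled integrator so that long horizons never store
traces). The hysteresis gap spans the unstable middle branch, making the
detector immune to subthreshold noise across the entire study range; spike
times are linearly interpolated between samples.

The regularity statistic is the interspike-interval (ISI) coefficient of
variation. Per neuron, $R_T^i = \sqrt{\langle\mathrm{ISI}^2\rangle -
\langle\mathrm{ISI}\rangle^2} / \langle\mathrm{ISI}\rangle$ with population
moments (`cv_single()`). The network statistic (`cv_network()`) averages the
first and second moments *across neurons first* and then forms the ratio —
deliberately not the mean of per-neuron CVs, so dispersion of firing rates
across neurons contributes. $R_T = 0$ for a common periodic train, $1$ for
Poisson spiking, $>1$ for super-Poissonian spiking. A noise level whose
simulation yields fewer than `min_isi = 5` ISIs per neuron on average is
flagged undefined and excluded from minimum searches, mirroring that
published $R_T$ curves are only drawn where spiking occurs; with fewer than
two ISIs a per-neuron CV is `NA`, never zero.

The renewal fixtures (`renewal_train()`, `multi_neuron_fixture()`,
`pulse_trace()`) calibrate this stage without the simulator: periodic,
Poisson and gamma-$k$ trains have known CVs $0$, $1$ and $1/\sqrt{k}$, and
the network estimator recovers $1/\sqrt{k}$ within 2% at $10^4$ ISIs per
neuron. The pulse fixture uses a piecewise-linear spike (rise 1, fall 3 time
units) that qualitatively matches an FHN excursion; only detector
correctness depends on its shape.

## Sweep pipeline and problem sizes

`rt_curve()` sweeps a log-spaced noise grid (`sigma_grid()`), averaging the
network $R_T$ over independent realizations per grid point; in multiplex
sweeps both layers receive the same noise amplitude, matching the
single-$\sigma_l$ axis of the published sweeps. `rt_min()` extracts the
minimum over defined points (ties toward smaller $\sigma$) plus the plateau
width. `multiplex_heatmap()` maps layer-2 $R_{T}^{\min}$ over the
$(\kappa_m, \tau_m)$ plane, masking cells that fail the deterministic
`excitability_scan()`.

The excitability scan classifies a configuration from noise-free dynamics.
Two kicks are probed, because delayed networks harbour distinct attractor
families: a homogeneous kick of every neuron (seeding synchronous
reverberation) and a single-neuron kick (seeding rotating waves). Sustained
spiking — more than one spike on any neuron in the second half of the
horizon, the first half absorbing the kick's excursion and delayed echoes —
marks the cell oscillatory. A noisy probe run ($\sigma = 10^{-2}$) that
cannot elicit even one ISI per neuron in any layer marks it
hyper-excitable: strong excitatory multiplexing over-stabilises the fixed
point. We note one genuine feature of the model equations: with strong
excitatory replica coupling, $\kappa_m (v - V_{\mathrm{syn}})\Gamma(\cdot)$
admits a mutually sustained depolarised state near $v \approx 3$, so the
often-quoted bound $|v| \le 2$ does not hold in that configuration.

Reference problem sizes: the full study protocol ($T = 6\times10^5$, seven
realizations, ten grid points per decade) is one `sim_config()` away, but
the package's shipped analyses run a scaled protocol chosen to keep a full
reproduction on a single CPU in minutes while leaving the estimator
well-conditioned: $T = 6\times10^4$ with a $2\times10^3$ transient
(≈ 10–30 ISIs per neuron inside the SISR window, i.e. several hundred
network ISIs per grid point), three realizations, grids at three points per
decade from $10^{-4}$ to $0.5$. The SISR plateaus of the $R_T(\sigma)$
curves are broad (decades wide), so the minimum is insensitive to the grid
density; the values it yields sit within the tolerances used by the
acceptance checks.

What the synthetic stages do and do not show: the renewal fixtures validate
the statistics pipeline exactly but have no network dynamics; the simulator
itself *is* the data-generating process of this study (no external data
exist for this system), so "passing" means internal consistency with the
stated model and agreement with the reported reference statistics at scaled
problem sizes — not agreement with any biological recording.

## Known limitations

* Two published deterioration values are not reproduced by this
  implementation at any tested convention (delayed self-term included or
  excluded, wide noise grids): the strong-coupling/long-delay electrical
  layer ($\kappa_e = 1, \tau_e = 10$), for which we find a deep $R_T$
  minimum rather than a curve above 1, and the strong short-delay inhibitory
  chemical layer ($\kappa_c = 1, \tau_c = 1$), where we find
  $R_T^{\min} \approx 0.1$ against a reported $0.71$. The integrator passes
  its order and noise-statistics contracts and matches an independent
  R-level reference to machine precision, so we attribute the difference to
  unstated protocol details (most plausibly the spike criterion applied to
  delay-echo bounces, which our hysteresis detector deliberately does not
  count). The corresponding acceptance checks are kept at the published
  values and fail loudly rather than being weakened.
* The deterministic oscillation boundary for excitatory multiplexing of
  chemical layers is $\kappa$-dependent in our model rather than flipping at
  $\tau_m = 2$; the cell at $(\kappa_m, \tau_m) = (0.9, 1)$ carries a
  reverberating attractor coexisting with the SISR regime (the noisy sweep
  still reproduces the published layer-2 optimum there).
* Delay handling is grid-snapped with linear stage interpolation; exact
  dense-output delay interpolation and adaptive stepping are out of scope,
  as are multiplicative noise, heterogeneous neurons, and non-ring
  topologies.

## A worked mini-example

```{r example, eval = FALSE}
library(sisrmux)

layer <- layer_spec(kappa = 0.1, tau = 1)          # weak gap junctions
cfg <- sim_config(dt = 0.05, t_end = 60000, t_transient = 2000,
                  n_realizations = 3, seed = 1)
curve <- rt_curve(layer, sigma_grid(1e-4, 0.5, 3), cfg)
rt_min(curve)
autoplot(curve)

noise_window(layer)        # where the landscape theory puts the SISR window
```
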