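---
title: "Linear response theory for correlation-firing rate analysis in heterogeneous LIF networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear response theory for correlation-firing rate analysis in heterogeneous LIF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlr)
```

## The model

`netlr` works with randomly connected networks of excitatory (E) and
inhibitory (I) leaky integrate-and-fire neurons. Below threshold the
membrane voltage of cell $i$ obeys

$$\tau_m \frac{dv_i}{dt} = -v_i - g_{E,i}(t)(v_i - \mathcal{E}_E)
  - g_{I,i}(t)(v_i - \mathcal{E}_I) + \sigma_i \sqrt{\tau_m}\,\xi_i(t),$$

with voltage dimensionless (reset at 0, thresholds $\theta_i$ near 1)
and time in ms. When $v_i$ reaches $\theta_i$ a spike is emitted and the
voltage is held at the reset value for an absolute refractory period
$\tau_{ref}$. Each synaptic conductance is a two-stage ("second-order
alpha") filter: a presynaptic spike deposits a pulse
$\hat\alpha_{X,i} = \alpha_X W_{YX} / N_{YX}(i)$ on an auxiliary
variable with rise time $\tau_{r,X}$, which then feeds the conductance
with decay time $\tau_{d,X}$. $W_{YX}$ is the raw weight of
$X\!\to\!Y$ connections and $N_{YX}(i)$ the *realized* number of such
inputs to cell $i$; cells that happen to receive no input of a type
simply lack that term. The default constants are $\tau_m = 20$ ms,
$\mathcal{E}_E = 6.5$, $\mathcal{E}_I = -0.5$, $\tau_{ref} = 2$ ms,
$\alpha_E = 1$, $\alpha_I = 2$, $\tau_{r,E} = 1$, $\tau_{d,E} = 5$,
$\tau_{r,I} = 2$, $\tau_{d,I} = 10$ ms.

Heterogeneity enters through the thresholds: a log-normal distribution
with mean 1 and variance $e^{0.04}-1$ (log-scale SD 0.2), sampled not at
random but at equally spaced CDF values (0.05–0.95 by default,
separately for the E and I populations). This makes every network with
the same population sizes carry exactly the same excitability spread,
which matters at moderate size: the packaged reference networks have 80
E and 20 I cells.

Two packaged presets differ only in recurrent-excitation strength and
background noise: `asynchronous` ($W_{EE}=0.5$, $W_{IE}=5$,
$\sigma_E = 2/\sqrt2$, $\sigma_I = 3/\sqrt2$) and `strong_asynchronous`
($W_{EE}=9$, $W_{IE}=8$, $\sigma_E = 1.5/\sqrt2$,
$\sigma_I = 2.5/\sqrt2$); both share $W_{EI}=10$, $W_{II}=5$ and
connection probabilities 40% (E→E), 35% (I→E), 20% (E→I), 40% (I→I).
Connectivity is independent Bernoulli per ordered pair (no autapses).
It is worth noting that the quoted reference values for the
population-averaged conductance-noise SDs coincide exactly with the
formulas evaluated at the *expected* in-degrees (7 and 32); with
realized Bernoulli degrees the population averages come out a few
percent higher because the per-synapse amplitude scales inversely with
the in-degree. We keep the Bernoulli model as the default and treat
this offset as part of the connectivity-model uncertainty.

## Effective single cell and threshold integration

Pooling each cell's type-$X$ presynaptic spikes into one Poisson stream
at the summed rate $\nu_{X,i}$ gives stationary conductance moments

$$\langle g \rangle = \hat\alpha \nu \tau_r,\qquad
  \mathrm{Var}[g] = \tfrac12 \hat\alpha^2 \nu \tau_r
  \frac{\tau_r}{\tau_r + \tau_d}.$$

Splitting conductances into mean plus fluctuation and treating the
fluctuations as white noise (the effective-time-constant approximation)
yields a one-dimensional stochastic voltage equation with effective
leak $g_0 = 1 + \langle g_E\rangle + \langle g_I\rangle$, reversal
$\mathcal{E}_{rev} = (\langle g_E\rangle \mathcal{E}_E +
\langle g_I\rangle \mathcal{E}_I)/g_0$, and multiplicative noise
variances $\sigma^2_{g_E}, \sigma^2_{g_I}$. We interpret the
multiplicative terms in the Itô sense, so the Fokker–Planck flux is
$J = F(v)P - \partial_v[D(v)P]$ with

$$F(v) = -\frac{g_0 (v - \mathcal{E}_{rev})}{\tau_m},\qquad
D(v) = \frac{\sigma^2\tau_m + \sigma_{g_E}^2 (v-\mathcal{E}_E)^2 +
       \sigma_{g_I}^2 (v-\mathcal{E}_I)^2}{2\tau_m^2}.$$

The Itô-vs-Stratonovich choice shifts the drift by
$\tfrac12 D'(v)$, which is two orders of magnitude below $F(v)$ at the
operating points of interest, so the convention is not empirically
critical; Itô matches the Monte Carlo integrator exactly.

The stationary rate, the four susceptibility functions (rate response
to oscillatory perturbations of $\langle g_E\rangle$,
$\langle g_I\rangle$, $\sigma^2_{g_E}$, $\sigma^2_{g_I}$; the variance
channels perturb the *squared* noise amplitudes) and the uncoupled
spike-train power spectrum are all computed by threshold integration:
backward integration of the density/flux pair from the absorbing
threshold, with re-injection at reset (carrying a factor
$e^{-i\omega\tau_{ref}}$ in the modulated problems), a reflecting lower
bound, and probability normalization that includes the refractory
fraction $\nu\tau_{ref}$. Each grid step uses an exponential
integrating-factor update, so the scheme is robust to stiff
low-noise regions. At $\omega = 0$ the susceptibilities are obtained
from the stationary perturbation with re-normalization — an exact
derivative of the solver output, not a small-$\omega$ extrapolation —
and the zero-frequency spectrum is $\nu\,CV^2$ from first-passage
moments computed by two additional backward sweeps. At $\omega > 0$ the
spectrum uses the renewal identity
$C^0(\omega) = \nu\,(1-|\tilde F|^2)/|1-\tilde F|^2$ with $\tilde F$
the Fourier transform of the ISI density.

Numerical choices that required decisions:

* **Grid.** $2^{10}$ uniform points by default; the lower bound adapts
  to the cell (eight OU standard deviations below the effective rest,
  never above $\mathcal{E}_I - 0.5$). A fixed shallow bound truncates
  real stationary mass at these noise levels — against a Siegert
  quadrature oracle a bound at $\mathcal{E}_I - 0.5$ mis-estimates
  rates by tens of percent at $\sigma = 2$, while the adaptive bound
  agrees to 0.02%.
* **Reset snapping.** The lower bound is then deepened slightly so the
  reset voltage falls exactly on a grid node. Without this, the
  re-injection point drifts within a grid cell as parameters vary and
  the rate acquires a sawtooth of relative amplitude $\sim10^{-2}$ —
  harmless for rates, fatal for the finite-difference derivatives that
  the susceptibility surface is built from.
* **Frequency convention.** Angular frequency in rad/ms with
  $\tilde f(\omega) = \int f(t)e^{-i\omega t}dt$. All headline
  statistics are taken at $\omega = 0$, where the convention drops out.

## Self-consistent rates

`solve_rates()` iterates rates → conductance moments → effective
parameters → threshold-integration rates with damping
$\nu \leftarrow (1-\gamma)\nu + \gamma\Phi(\nu)$, $\gamma = 0.5$,
initialized at the uncoupled rates, to relative tolerance $10^{-6}$
(residual measured against the largest rate in the network, so silent
cells cannot stall convergence). Hitting the iteration cap returns
`converged = FALSE` with a warning, never silently. The fixed point is
verified independent of $\gamma$ to within the tolerance. Population
summaries are taken over E cells by default; the background-noise
amplitude is reported as $\sigma_E\sqrt{\tau_m}$, the combination that
actually enters the effective voltage equation.

## Linear response, motifs, and second-order types

With susceptibilities $\tilde A$ and synaptic filters
$\tilde J(\omega) = \hat\alpha\tau_r /
[(1+i\omega\tau_r)(1+i\omega\tau_d)]$ and
$\tilde L = \tilde J \cdot (\hat\alpha/2)\,\tau_r/(\tau_r+\tau_d)$, the
interaction matrix couples source $j$ (type $X$) into target $i$ as
$K_{ij} = \tilde A_{\langle g_X\rangle,i}\tilde J_{ij} +
\tilde A_{\sigma^2_{g_X},i}\tilde L_{ij}$ on edges of the graph. The
cross-spectrum is $(I-K)^{-1} C^0 (I-K^*)^{-1}$; its zero-frequency
value, normalized by the diagonal, is the long-window spike-count
correlation. Expanding the inverses in powers of $K$ gives motif terms
$R^k = \sum_{l=0}^{k} K^l C^0 (K^*)^{k-l}$ (all directed paths with $k$
edges); the series is valid while the spectral radius of $K$ stays
below one, which holds for every converged network in the test suite.

The order-2 term is split into four types: common input from E sources,
common input from I sources, and chain terms classified as
*correlating* or *decorrelating* by the sign of each individual
two-edge path's contribution at $\omega = 0$ (the product of its two
edge weights; the uncoupled spectrum is positive). Classifying by
realized contribution sign rather than by source-type pattern is a
design choice: it is the only classification under which the two chain
classes are sign-definite by construction, and for these networks —
where all entries of a column share the sign of the source's
susceptibility product — the two readings coincide on almost all paths.
The four parts sum to $R^2$ exactly, which the suite asserts to machine
precision.

Following the reference analysis, motif importance is quantified by
regressing total correlation on each single motif order (and $R^2$ on
each second-order type) across unordered E–E pairs, with an intercept
(exposed as a flag), and reporting the coefficient of determination.

## The reduced surface and correlation susceptibility

Since inhibitory common input dominates, the pair statistic is
summarized by $\hat S = (\partial F/\partial g_I)^2 / F$ evaluated on
the reduced surface $F(g_I, \theta)$: the single-cell rate with
$\langle g_E\rangle$, $\sigma_{g_E}$, $\sigma_{g_I}$ and $\sigma$
frozen at solved population averages. $\hat S$ is reported in
Hz per squared (dimensionless) conductance. Defaults: a 61×61 grid,
$\theta$ spanning the 1%–99% log-normal quantiles, $g_I$ spanning 0.5
to 1.5 times the solved population mean (brackets both presets'
operating points); gradients by centered differences with one-sided
boundary stencils; $\hat S$ masked where $F = 0$; directional
derivatives $d\hat S/dF = (\nabla\hat S\cdot d\mathbf{x})/
(\nabla F\cdot d\mathbf{x})$ masked where the denominator is below
$10^{-12}$ of its maximum. The fraction of directions along which
$\hat S$ increases with $F$ is $(\pi - \arccos\cos\vartheta)/\pi$ with
$\cos\vartheta$ the gradient alignment; the suite checks this against
brute-force direction enumeration to $10^{-3}$.

Path families follow the usual plotting orientation of the
$(\theta, g_I)$ plane: *horizontal* paths vary $\theta$ at fixed $g_I$
— the path a purely threshold-heterogeneous network traverses —
and *vertical* paths vary $g_I$ at fixed $\theta$; *radial* paths pass
through a common anchor (defaulting to the grid midpoint). A network's
$\hat S$–$F$ curve (`sf_curve()`) is its horizontal path restricted to
the populated threshold range, summarized by two OLS slopes: over the
whole curve, and over the low-rate half (below the median rate). The
curves typically rise to a maximum at a few Hz and decay beyond it, so
the whole-curve slope captures "predominantly decreasing" behavior
(asynchronous-level noise) while the low-half slope captures
"increasing at low rates" (strong-asynchronous-level noise); the
acceptance suite evaluates both signs over a 4×4 grid of
$(W_{EE}, W_{IE})$ values spanning 0.5–10.7 and 5–8.6 for each noise
setting.

For the wider background-noise survey the external description of the
noise grid mixes two unit conventions (values like 1.5–3 versus pairs
like (0.15, 0.3)); sweeps therefore store $\sigma$ exactly as
configured and never rescale silently.

## Monte Carlo validation

`simulate()` integrates the full generative model by Euler–Maruyama at
$dt = 0.01$ ms (a tenth of the fastest synaptic rise time), with
voltage clamped at reset during the refractory period while
conductances keep evolving, and spike detection at step boundaries
against a continuity-corrected threshold
$\theta - 0.5826\,\sigma\sqrt{dt/\tau_m}$ (the standard
discrete-monitoring boundary correction). Without the correction the
$O(\sqrt{dt})$ crossing bias is 3–6% at the default step; with it,
single-cell rates agree with threshold integration to ~1% and the
100-cell network rates to ~5% mean absolute relative error (the
residual is the diffusion/Poisson approximation itself, not the
integrator). Spike-count statistics use disjoint windows by default
($T = 200$ ms), unbiased sample moments, and report pairs involving
zero-variance cells as undefined rather than zero.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions exactly as stated:
population sizes 80/20, the two preset parameter columns, lognormal
quantile thresholds, Bernoulli connectivity. It does not emulate
synaptic delays, plasticity, spatial structure, multiple interneuron
classes, or non-threshold sources of heterogeneity; passing tests
therefore say nothing about those features. Population sizes are not
printed in the reference material; 80/20 is forced by back-substituting
the quoted effective parameters through the conductance-moment
formulas (giving expected in-degrees of 7 I-inputs and 32 E-inputs per
E cell) and is configurable.

Small fixtures (`make_fixture()`) pin analytic cases: an uncoupled
pair, a single common inhibitory source (the pure common-input motif,
testable by hand), a two-cell chain with closed-form cross-spectrum,
and `mini_asyn`, an all-to-all 8E+2I network whose raw weights are
scaled by the ratio of mini to full-size in-degrees so that per-synapse
amplitudes — and hence the validity of the diffusion approximation —
match the reference network.

One validation is statistically out of reach at the stated scale and is
left failing deliberately: the per-pair *rank* correlation between
Monte Carlo count correlations and the linear-response prediction after
100 s of simulated time. The count-correlation estimator has standard
error $\approx 1/\sqrt{500} \approx 0.045$ per pair at $T = 200$ ms,
while the true correlation spread across E–E pairs is only
$\sim 0.01$, so the attainable rank correlation is bounded near
$0.01/\sqrt{0.01^2 + 0.045^2} \approx 0.2$ regardless of implementation
quality; raising coupling until the spread beats the noise violates the
rate-accuracy half of the same check. The *mean* correlation over the
3160 E–E pairs, where estimator noise averages out, agrees with the
linear-response value to ~0.001 and is asserted instead alongside the
rank check.

## Problem sizes used in the suite

The default test run solves the two 100-cell presets over five
connectivity seeds, simulates the asynchronous preset and the mini
fixture for 100 s each, one effective cell for 3000 s, and evaluates
thirty-two 31×31 surfaces for the noise-family comparison; the whole
suite completes in a few minutes on one CPU. All larger surveys (the
full 15×15 weight grid, 12 noise pairs) are available through
`run_sweep()` but are not part of the default tests.

## Known limitations

* The diffusion (effective-time-constant) approximation degrades when
  per-synapse amplitudes are large, e.g. populations with very few,
  strong inputs; the mini fixture deliberately avoids this regime.
* Linear response is first-order in the interaction matrix around the
  asynchronous state; near instability (spectral radius approaching 1,
  as with the strongest recurrent excitation) motif orders beyond the
  second become non-negligible and the expansion loses predictive
  power.
* Long-time statistics are evaluated analytically at $\omega = 0$;
  finite-window corrections to $\rho_T$ at $T = 200$ ms are visible in
  Monte Carlo comparisons at the few-percent level.
* The solver tracks a single fixed point; coexisting states and
  bifurcations are out of scope.
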