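---
title: "Reconstructing stochastic tree-cover dynamics from short annual panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing stochastic tree-cover dynamics from short annual panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

borealstate treats the tree cover $X_t$ (percent of a ~6 ha plot) as a
one-dimensional Langevin process,

$$ dX_t = f(X_t)\,dt + g(X_t)\,dW_t, $$

with a deterministic drift $f$ (expected annual change, % y$^{-1}$), a
state-dependent process noise $g$ (% y$^{-1/2}$) and Wiener increments
$dW_t$. What a satellite records is not $X_t$ but

$$ \hat X_t = X_t + h(X_t)\,B_t, $$

where $h$ is a cover-dependent observation-noise SD and $B_t$ is standard
normal white noise. Integration uses the Euler–Maruyama scheme
$X_{t+\Delta t} = X_t + \Delta t\, f(X_t) + \sqrt{\Delta t}\, g(X_t)\,\xi_t$
with $\Delta t = 0.1$ y by default.

The scientific payoff of this decomposition is that the zeros of $f$ are
the equilibria of the cover dynamics: stable zeros (negative local slope)
are attractors the landscape is moving toward, unstable zeros are
watersheds between alternative states. When the present cover distribution
differs from the stationary distribution implied by $(f, g)$, the system is
in disequilibrium and ensembles simulated forward show where it is heading.

## Estimating the drift

Each plot contributes one robust trend: the Theil–Sen slope of its annual
series (median of all pairwise slopes), which is insensitive to the heavy
observation noise typical of remote-sensing records. Trends are related to
*initial* (first-year) cover with a penalized cubic regression spline
(`mgcv::gam`, `bs = "cr"`, basis dimension `k = 10`, smoothness by GCV),
independently within each 0.5 °C mean-annual-temperature bin between −14
and 6 °C (40 bins), optionally further split by categorical strata such as
region, fire or management. Temperature bins act as quasi-fixed
environments; the bins are fitted independently rather than by a 2-D
tensor smooth.

Choices a user can revisit:

* **Basis dimension 10 and GCV.** The smoother family is fixed by the
  method; basis size and penalty selection are conventions. `k = 10` keeps
  the drift flexible enough for two-attractor shapes while damping
  wiggles.
* **Minimum group size 50** (`min_n`). Below a few dozen plots the spline
  fit is unstable; smaller groups are skipped and reported.
* **Extrapolation.** Outside the fitted cover range the smooth is
  continued *linearly* from the boundary value and slope. Warming-driven
  bin switching routinely pushes plots into bins whose models were fitted
  on different cover ranges, so the extrapolation rule is part of the
  model contract rather than an afterthought.
* **Initial-cover definition.** The drift is regressed on first-year
  cover, as the record's design implies; pooling all start years is
  available via the lag machinery but is not the default.

A transparency note on what this estimator can and cannot see: the
Theil–Sen trend is an average over a 21-year window. If the dynamics
traverse a large part of the cover axis within that window (fast rates,
strong noise), the window average is flatter than the instantaneous drift
and zero crossings shift — the package's own validation shows the
strong-Allee threshold recovered at ~15% instead of 20% when the intrinsic
rate is tripled. Recovery tests therefore use rates at which the window is
short relative to the dynamics, and users should treat fitted drifts as
window-averaged objects.

## Separating process from observation noise

All plot-year occurrences are pooled into 1%-wide cover groups. For each
group and each lag $\Delta t = 1,\dots,10$ y, the SD of cover $\Delta t$
years later is computed across occurrences (cells with fewer than 30
occurrences are dropped). Process noise grows like $\sqrt{\Delta t}$;
observation noise does not. The default regression follows that logic
literally: OLS of $\sigma(\Delta t)$ on $\sqrt{\Delta t}$, intercept $a$ =
observation noise, slope $b$ = process noise ("sqrt-sd" method). The
per-group coefficients are then smoothed over cover with the same spline
contract to give $g(X)$ and $h(X)$, clipped at zero; a single
temperature-independent pair is used, since per-bin noise fits do not
differ materially.

For two independent Gaussian noise sources the group variance is exactly

$$ \sigma^2(\Delta t) = 2a^2 + b^2\,\Delta t , $$

the factor 2 arising because grouping plot-years by *observed* cover
conditions the time-$t$ observation error into the group spread as well.
Since $\sigma$ itself is then a square root, the sd-scale regression is
systematically biased: with true $(a, b) = (2, 1)$ it converges to roughly
$(2.34, 0.59)$ no matter how much data is available. The package therefore
also provides the "variance" method — OLS of $\sigma^2$ on $\Delta t$ with
$\hat a = \sqrt{\mathrm{intercept}/2}$, $\hat b = \sqrt{\mathrm{slope}}$ —
which is exactly linear under the model and recovers the true amplitudes;
the recovery checks in the test suite use it. The sd-scale method remains
the default because it is the form the two-step procedure is usually
stated in, and because for *projection* the drift, not the precise noise
split, dominates where ensembles end up.

Known biases, deliberately not corrected: no drift correction is applied
to the lagged SDs (fine where the drift is small over 10 y, optimistic in
strongly drifting cover groups), and clipping at the cover boundaries
compresses SDs for groups near 0 and 100.

## Projection

`simulate_ensemble()` integrates every plot with the drift of its current
temperature bin and the shared process noise. With a warming trajectory
(MAT offsets per year), each plot's bin is re-resolved once per simulated
year — not per substep, since warming inputs are annual — and plots
warming beyond the warmest fitted bin keep the warmest bin's model (and
symmetrically at the cold end, and across gaps left by skipped groups:
bins snap to the nearest fitted bin). Observation noise is superimposed on
stored snapshots only and never fed back into the dynamics; it is a
measurement artifact, not mass. The default horizon is 990 steps of 0.1 y,
the published convention for a 2000→2100 run; `steps = 1000` gives the
literal century and the discretization check in the test suite shows the
difference is immaterial.

Boundary policy: cover is clipped to [0, 100] after every step (a
reflecting boundary is available behind `boundary = "reflect"`). Clipping
is the simplest contract to test, but it is also why noisy dynamics near
0% show a small upward bias — mass that would diffuse below zero is
returned to the boundary, so drift estimates at very low cover tilt
positive and the low stable root of Allee-type fits sits a few percent
above the true attractor at 0.

## Equilibria, densities, modes

`find_equilibria()` locates sign changes of the drift on a 0.1% grid,
refines them by bisection to 1e-4, and classifies them by local slope.
Endpoints where the drift is numerically zero are classified by their
one-sided slope; endpoints the drift *pushes into* (negative drift at 0,
positive at 100) are reported as stable boundary equilibria only on
request (`include_boundaries = TRUE`) — fitted smooths whose boundary
attractor is displaced a little off zero need this, while a constant
nonzero drift should report no equilibria.

Density landscapes are exact Gaussian kernel densities on [0, 100]
(Silverman bandwidth by default) with reflection at both boundaries and
trapezoid normalization to 1 (enforced to 1e-6). Modes are grid maxima
filtered by topographic prominence of at least 5% of the global peak,
which suppresses sampling ripples without a formal bimodality test.
Windowed densities pool all plot-year values per period, by default
{2000–04, 2005–09, 2010–14, 2015–20}; the exact window boundaries are a
convention.

## Biomass

Cover–biomass calibration pairs are fitted by three candidate families —
linear, power, exponential — by least squares on the natural scale, with a
common Gaussian-error AIC (comparing log-scale and natural-scale fits by
AIC would be invalid); the lowest-AIC family is selected. Nonlinear
families start from their exact log-linearizations and are refined with
`nls`; on noiseless data, where `nls`'s relative-offset criterion cannot
be met, the (already exact) start values are kept. Simulated ensemble
change is converted per bin: mean biomass at the start and end snapshots
over *latent* covers, relative change, and total change =
(mean end − mean start) × bin area, with exact aggregation of per-bin
totals to the grand total.

## The synthetic generator, and what passing tests do (and do not) show

`generate_panel()` draws plots along a MAT range, integrates a known
ground-truth model (logistic, weak or strong Allee, or any custom drift)
by Euler–Maruyama at `dt_internal = 0.1` y — the same step the projector
uses, so generation and inference share a discretization-error scale —
samples annually, and superimposes observation noise. A linear MAT→(r, K)
gradient option produces the warm-dense / cold-sparse pattern of real
boreal cover; it is a fixture convention, not a claim about how
temperature really enters the dynamics.

Validation conditions are fixed once: logistic truth r = 0.3, K = 60,
g ≡ 2 for drift recovery; Allee-type truths r = 0.1, K = 60, A = 20,
g ≡ 1 (rates at which the 21-year window resolves the skeleton — see the
transparency note above); f ≡ 0, g ≡ 1, h ≡ 2 for noise separation;
panels of 20,000 (drift) and 5,000 (noise) plots over 21 years. Test
problem sizes (10,000-plot OU ensembles, 100 selection replicates of
2,000 calibration pairs) are the package's own choices, large enough that
Monte-Carlo spread sits well inside the asserted tolerances.

What the synthetic panels deliberately do *not* emulate: spatial
correlation between plots (plots are independent, as in the fitted model),
non-Gaussian disturbance noise such as fire (jumps enter only through what
the drift and diffusion can absorb), discretization of cover to integer
percent by real sensors (available in the shipped fixture but not in the
generator default), temporally autocorrelated observation error, and any
real geography. A green suite therefore shows the estimators recover the
model class they assume; it does not show boreal forests obey that class.

## Numerical conventions

Seeds are explicit everywhere (generator, simulator, observation noise;
the pipeline refuses to run without them) and identical seeds give
bit-identical output. Tables are written as comma-separated UTF-8 text
with 17-significant-digit numerics so every file round-trips exactly
through the package's own readers. Theil–Sen uses the midpoint convention
for even slope counts and drops pairs at identical time points; lagged-SD
cells and spline groups below their minimum counts are dropped and
reported rather than silently fitted.
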