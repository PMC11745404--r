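# borealstate

Boreal tree cover is widely bimodal — sparse (~5–15%) and dense (~60%)
states coexist along the mean-annual-temperature gradient — yet the
*direction* of recent change need not point back at either mode. This
package reconstructs the stochastic dynamics of tree cover from panels of
short annual time series and asks where the landscape is heading: it is a
toolkit for ecosystem modellers and remote-sensing ecologists who have
plot-level cover records (e.g. satellite vegetation-cover products) and
want equilibria, forward ensembles and carbon-relevant summaries out of
them.

## The model

Cover $X_t$ (% of a plot) follows a Langevin equation

$$dX_t = f(X_t)\,dt + g(X_t)\,dW_t, \qquad \hat X_t = X_t + h(X_t) B_t,$$

with drift $f$, process noise $g$, and observation noise $h$ superimposed
on measurements. All three are estimated from data:

* **Drift** — per-plot Theil–Sen trends (median of all pairwise slopes)
  related to initial cover by penalized cubic regression splines,
  independently per 0.5 °C temperature bin (−14…6 °C, 40 bins) and
  optional strata. Zeros of the fitted drift are the equilibria: stable
  zeros are attractors, unstable zeros separate alternative states.
* **Noise separation** — the SD of cover $\Delta t$ years ahead (1%
  cover groups, lags 1–10 y) regressed on the lag: the lag-independent
  part is observation noise, the $\sqrt{\Delta t}$ part process noise.
* **Projection** — Euler–Maruyama ensembles ($\Delta t = 0.1$ y) per
  temperature bin, with optional warming-driven bin switching and
  observation noise added to the stored snapshots; summarized as density
  landscapes, modes, and cover→biomass change via AIC-selected
  calibration models.

A synthetic-panel generator with known ground-truth dynamics (logistic,
weak/strong Allee, custom) makes the whole chain testable without any
satellite data.

## Worked example

Generate a panel from a known logistic truth (carrying cover 60%, process
noise 2, observation noise 2), refit the stochastic model from the panel
alone, and project a century ahead:

```r
library(borealstate)

truth <- ground_truth("logistic", r = 0.3, K = 60,
                      process_noise = 2, obs_noise = 2)
panel <- generate_panel(truth, synthetic_config(n_plots = 5000, seed = 1,
                                                mat_range = c(-2, 2)))

model <- fit_treecover_model(panel, temperature_bins(-2, 2, 1), min_n = 100)
model
#> Stochastic tree-cover model (drift-diffusion with observation noise)
#>   5000 plots, years 2000-2020
#>   drift: 4 fitted bin group(s) (0 skipped), cubic regression splines
#>   noise: one temperature-independent process/observation pair

coef(model)   # equilibria of the fitted drifts, per temperature bin
#>   group bin     root stability     type
#> 1     1   1 59.81900    stable crossing
#> 2     2   2 60.24375    stable crossing
#> 3     3   3 59.67139    stable crossing
#> 4     4   4 60.84158    stable crossing

ens <- simulate(model, seed = 2, steps = 1000)   # year 2000 -> 2100
find_modes(density_landscape(ensemble_snapshot(ens, 100, "observed")))
#>   cover   density prominence
#> 1  59.7 0.1257...  0.1257...
```

Each fitted bin recovers a single stable equilibrium within ~1% of the
true attractor at 60% cover, and the projected year-2100 ensemble
(including observation noise) is unimodal with its mode at 59.7% — the
refitted model sends the landscape where the generating dynamics say it
should go. `plot(model)` draws the fitted drift curves with their
equilibria and the two noise functions; `run_pipeline()` executes the
whole chain from a YAML config (see `inst/extdata/pipeline.yaml`) and
writes every intermediate table plus a reproducibility manifest.

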