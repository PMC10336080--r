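---
title: "Meta-learning carbon fluxes from sparse station networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learning carbon fluxes from sparse station networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmeta)
```

## The problem

Eddy-covariance towers measure ecosystem–atmosphere carbon exchange at points,
and the global network is heavily biased toward temperate, data-rich regions;
the tropics and semi-arid zones — which dominate the interannual variability of
the land carbon sink — are represented by only a handful of stations. A
regression model trained by pooling all station records inherits that bias:
every record pulls equally on the loss, so the fitted parameters serve the
abundant regions first. `fluxmeta` implements an optimization-based
meta-learning (MAML-family) alternative for predicting daily gross primary
production (GPP) and ecosystem respiration (Reco, both gC m⁻² d⁻¹) from five
predictors — precipitation `P`, 2-m air temperature `TA`, vapor pressure
deficit `VPD`, incoming shortwave radiation `SW_IN` and leaf area index
`LAI` — together with the full downstream pipeline: deep-ensemble uncertainty,
site-level and extreme-value evaluation, gridded upscaling to a four-variable
NetCDF product, and product diagnostics.

## The two-loop trainer

Stations are grouped into *tasks*. **Target tasks** are the data-sparse
stations (half of the tropical and semi-arid stations plus one representative
of each plant functional type, `split_tasks()`); **base tasks** are the rest.
Each station's rows split 80:20 chronologically into train/test, giving the
four sets (base-train, base-test, target-train, target-test).

For every outer step, each base task in the current chunk clones the shared
parameters θ and takes `inner_steps` plain gradient steps on its own training
batches, proposing task-adapted parameters φ. The meta-objective — by default
the MSE on a batch of the target-task training pool — is evaluated at φ, its
gradient is averaged over the chunk, and applied to θ by an Adam outer step.
Thus θ is optimized for *what it becomes after adapting to a base task*, with
the adaptation geometry supplied by data-rich tasks and the objective anchored
on the sparse tasks. The non-meta baseline (`baseline_train()`) trains the same
architecture on the pooled training rows with the same optimizer, epochs and
ensemble contract.

Where the loss used in the outer step lives is genuinely ambiguous in this
family of algorithms, so it is a switch: `meta_objective = "target"`
(default), `"base_test"`, or `"both"`.

### First-order versus exact meta-gradients

By default the inner Jacobian is dropped (first-order; FOMAML). The exact
option (`first_order = FALSE`) back-propagates through the inner trajectory by
reverse accumulation, `v ← (I − α·H_k)·v`, with every Hessian-vector product
computed by central differences of the exact analytic gradient. This reuses
the hand-derived backprop (no symbolic second derivatives for three
architectures) at ~1e-7 accuracy; the two options coincide exactly when
`inner_steps = 0`, which the tests assert.

### Learning-rate defaults

Inputs are z-normalized, so MSE curvature along well-populated directions is
O(1)–O(10). An inner step of 1e-2 routinely *overshoots*: the gradient at φ
then points back past the task minimum, and because Adam normalizes
coordinates, that reversed component is amplified into a persistent ascent
direction — we observed clean, monotone divergence with inner_lr = 1e-2.
The shipped defaults are `inner_lr = 3e-3`, `outer_lr = 1e-3`,
`inner_steps = 1`, `tasks_per_meta_batch = 4`; k-fold selection
(`kfold_select()`) is the sanctioned tuner beyond that. The paired benchmark
(`meta_benchmark()`) raises `outer_lr` to 1e-2 *for both arms alike* so both
converge inside its 30-epoch budget.

## The learners

All three regressors share one contract: forward evaluation, MSE loss, exact
gradient with respect to a flat parameter vector, and parameter get/set (the
inner loop needs cheap cloning). The MLP is three weight layers
(input → hidden → hidden → 1) with LeakyReLU, R(x) = x for x > 0 and αx
otherwise (α = 0.01 by default; the reference formulation leaves α unstated,
and 0.01 is the conventional choice). At the production width of 350 this is
125,301 parameters for five inputs. The LSTM and BiLSTM replace the first
layer with a recurrent cell consuming a 30-step window (gap-free by
construction); the prediction head is identical. The recurrent output is the
final hidden state — forward direction only for the LSTM, both directions
concatenated for the BiLSTM — matching the convention that a window predicts
its *final* timestep. Which timestep inside the window is predicted is not
fixed by the method description; final-step prediction keeps the LSTM and
BiLSTM interfaces identical and avoids future leakage in the unidirectional
model, at the cost of using the BiLSTM below its design point (its backward
pass sees only the window's interior). Initialization is uniform with fan-in
scaling, biases zero except the LSTM forget gates (1); everything is a pure
function of the seed. Gradients for all three architectures are verified
against central finite differences at toy size (≤ 1e-4 relative).

## The synthetic world

`gen_network()` is first-class, tested code, not a fixture: every downstream
claim is only as good as the world it is tested in.

- **Fluxes.** GPP = pmax·(1 − exp(−k·SW/pmax)) · exp(−(TA − t_opt)²/2σ²) ·
  s(W) · (1 − exp(−0.5·LAI)); Reco = r0·q10^((TA−10)/10)·s(W). The water
  stress s(W) = (W/(W+20))^w_sens follows a precipitation bucket with
  exponential decay at `memory_halflife` days — the minimal mechanism giving
  fluxes a multi-day memory. `w_sens = 0` switches stress off exactly.
- **Exchangeable zones.** Every station draws weather from one shared
  seasonal climatology (reference latitude 40°, wetness 0.6, AR(1) noise,
  gamma rainfall, Magnus-consistent dewpoint/VPD). Climate zones differ
  *only* through `zone_shift`, a multiplier on pmax and r0. This is
  deliberate: it makes zones statistically exchangeable when the shift is 1
  (a tested invariant) and turns any shift into a pure concept shift —
  same predictor distribution, different response — which is the regime where
  pooled training is genuinely biased and meta-learning can help. Had zones
  kept distinct climates, the predictors would identify the zone and a pooled
  model of adequate capacity would fit both responses without compromise.
- **Extremes.** With probability `extreme_tail`, a record receives a positive
  heavy-tailed spike (3σ + exponential). Spikes are drawn for *all* records
  at fixed seed and applied where a uniform draw falls under the tail weight,
  so selections are nested in `extreme_tail` and extreme counts are monotone.
- **Gaps** are an explicit missing sentinel (`NA` in GPP/RECO), excluded from
  instantaneous rows and forbidden inside windows — never imputed.
- **Grid.** `gen_grid()` keeps latitudinal gradients plus smooth longitudinal
  perturbations and carries its own noise-free truth fields, enabling
  closed-loop upscaling tests.

What a green test does *not* establish: realism of magnitudes beyond "typical
flux-tower ranges", radiative transfer, acclimation, disturbance, or any
calibration against real sites. The world is a controlled instrument for
recovering known structure, not an emulator of any particular biome.

### The paired benchmark

`meta_benchmark()` states the sparse-task experiment: 20 base-zone
(temperate) stations, 4 target-zone (tropics) stations whose responses are
shifted ×1.3, two years of daily data, MLP hidden 16, 30 epochs, one member
per arm, ten paired seeds. The target tasks are the whole sparse zone — the
point of the experiment is the sparse-zone gap, so the benchmark pins
membership explicitly via `make_meta_split()` rather than re-sampling half the
zone into base as the production splitter would. Meta wins when its
target-test RMSE is lower than the matched baseline's; the acceptance test
requires ≥ 8 of 10. Margins are honest but small (the irreducible noise floor
is `noise_sd` = 0.8 gC m⁻² d⁻¹ and both arms approach it): this reproduces the
*direction* of the advantage, not any published magnitude.

## Evaluation machinery

`rmse()`, per-zone reports with across-member spread, and the extreme sweep:
observations whose z-normalized value (statistics fitted on *training*
targets, pooled across stations — per-station standardization is the noted
alternative) exceed t ∈ [1, 2] are selected; subsets are nested, and only the
high tail is used, since peak fluxes are the quantity of interest. The zone
decomposition satisfies the exact identity
rmse² = Σ n_z·rmse_z² / Σ n_z, tested to 1e-10.

## Upscaling and the product

`compute_vpd()` derives VPD = SVP(TA) − SVP(TD) with the Magnus formula
0.61094·exp(17.625·T/(T+243.04)) kPa (coefficients are a documented choice;
the reference names no formula), clamping supersaturation to zero and
counting the clamps. `regrid_mean()` block-averages fine grids (missing-aware).
`build_mask()` excludes cold regions poleward of 66.5°N and 60°S
(configurable; "Arctic circle and Antarctica" comes without coordinates).
`upscale_grid()` normalizes the grid predictors with the *training*
statistics, runs each flux ensemble per cell/timestep and stores ensemble
mean and population standard deviation — the four product variables. Windowed
models consume the trailing 30 steps; the first 29 timesteps are missing by
default (`spin_up = "missing"`) or can be predicted from a first-step-padded
window (`"shortened"`).

Products are written as classic NetCDF (float32, CF-style `units`,
`long_name`, `_FillValue`), one file per month (daily,
`METAFLUX_GPP_RECO_daily_<year><month>.nc`) or per year (monthly). The
environment provides no NetCDF bindings, so the package carries a minimal
classic-format codec; its files are read back bit-for-bit (within float32)
and cross-validated against an independent SciPy reader in the tests.

## Product diagnostics

Zone seasonality (calendar-month climatology over zone means), interannual
CV = σ/μ of per-cell annual means with the sample (n−1) standard deviation
(the reference writes only σ; the sample convention is pinned by tests),
OLS trends of area-integrated annual totals (spherical cell-area weights;
PgC yr⁻¹ needs the integration even though the source does not detail it),
NEE = Reco − GPP, and Pearson correlation against a reference field per zone
(zone-mean series first, then correlate — the alternative order is noted) and
per pixel (zero-variance pixels are missing). Correlations are computed on
raw series; min-max scaling belongs to plots only and cannot change r.

## Numerical choices and degenerate inputs

- Sample (n−1) standard deviations everywhere statistics are fitted.
- Zero-variance features raise an error naming the feature rather than
  emitting NaNs.
- Non-finite training loss aborts with the epoch and member named.
- An exact-line trend reports stderr 0 (the ~1e-15 `lm` artifact is clamped).
- Empty extreme subsets are recorded as missing with count 0, not errors.
- All randomness flows from explicit seeds through a 32-bit child-seed
  derivation; no global RNG state leaks (`with_seed` restores it).

## Known limitations

- The BiLSTM is used below its design point (final-step targets).
- The instantaneous-input MLP cannot represent the water-stress memory by
  construction; that is visible in the closed-loop test design, which turns
  stress off to measure the upscaler rather than the generator.
- The NetCDF codec covers the classic subset the product needs (fixed
  dimensions, no compression, no groups); it is not a general NetCDF-4
  reader.
- Second-order meta-gradients use finite-difference Hessian-vector products;
  for ill-conditioned parameter scales the 1e-7 accuracy could matter.
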