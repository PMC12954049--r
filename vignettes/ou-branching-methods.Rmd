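---
title: "Methods: mean-reverting trait dynamics coupled to branching demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-reverting trait dynamics coupled to branching demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oubranch)
```

## The model

`oubranch` models a scalar phenotype — in the motivating application, the
log10 mutation frequency of a bacterial lineage — as an
Ornstein–Uhlenbeck (OU) diffusion

$$dY_t = \theta(\mu - Y_t)\,dt + \sigma\,dW_t,$$

where $\mu$ is the equilibrium mean, $\theta > 0$ the mean-reversion rate
(interpretable as an effective stabilizing-selection strength), and
$\sigma > 0$ the diffusion scale. The stationary law is
$\mathcal N(\mu, \sigma^2/2\theta)$; on the log10 scale the derived
quantities $10^\mu$ (equilibrium frequency) and $\sigma^2/2\theta$
(stationary variance) are the biologically-interpretable summaries.

The OU transition is Gaussian in closed form for any step $\Delta t$:

$$y_i \mid y_{i-1} \sim \mathcal N\!\big(m_i, v_i\big),\quad
m_i = \mu + (y_{i-1} - \mu)e^{-\theta \Delta t_i},\quad
v_i = \tfrac{\sigma^2}{2\theta}\big(1 - e^{-2\theta \Delta t_i}\big).$$

Everything in the package rests on this: `simulate_exact()` draws from it
(no integrator error on any grid), `negative_log_likelihood()` sums the
transition log-densities, and `predictive_trajectory()` evaluates
$m(t), v(t)$ analytically.

The demographic side couples the trait to a birth–death process through

$$\lambda(Y) = \lambda_0 e^{\alpha (Y - \mu_{\mathrm{ref}})},\qquad
\delta(Y) = \delta_0 e^{-\beta (Y - \mu_{\mathrm{ref}})},$$

both clipped to $[0, \texttt{rate\_cap}]$ for numerical stability. With
$\alpha = \beta = 0$ this is the classical linear birth–death process
(per-capita rates $b = \lambda_0$, $d = \delta_0$), for which
`simulate_constant_bd()` provides an exact Gillespie reference with
closed-form checks ($E[N_t] = n_0 e^{(b-d)t}$; single-founder ultimate
extinction probability $\min(1, d/b)$). The demographic nullcline — the
trait value where division balances death — is
$Y^* = \mu_{\mathrm{ref}} + \ln(\delta_0/\lambda_0)/(\alpha+\beta)$.

## Preprocessing: detection floor and log transform

Raw frequencies contain exact zeros below the assay's detection limit.
Per lineage (never pooled), `floor_and_log()` computes
$\epsilon = 0.5 \times \min\{x : x > 0\}$, floors every observation at
$\epsilon$, and models $y = \log_{10} \max(x, \epsilon)$. Zeros are
floored rather than dropped (dropping would bias the level upward);
negative inputs are rejected because frequencies cannot be negative;
duplicate (lineage, replicate, time) rows are an error rather than being
silently averaged. Flooring is idempotent and never decreases a value.

## Likelihood, optimization, and model comparison

The replicate-grouped objective sums transition terms over all replicates
of a lineage; each replicate's first observation is conditioned on and
contributes no term (a stationary-density term for the first point is
available behind `stationary_init = TRUE`; conditioning is the default
because it makes no distributional claim about how each replicate was
initialized). Irregular sampling needs no special handling — the exact
transition absorbs any $\Delta t$.

`fit_mle()` minimizes the NLL over the internal coordinates
$(\mu, \log\theta, \log\sigma)$ with bounded L-BFGS-B and multiple random
restarts (default 24; $\theta$ starts log-uniform on $[10^{-3}, 10^2]$,
$\sigma$ on $[10^{-2}, 10^1]$, $\mu$ uniform over the data range $\pm 1$).
The log parameterization enforces positivity and conditions the problem
far better than box bounds near zero; the box bounds that remain (at
$10^{\pm 8}$) only keep every objective evaluation finite. Ties between
restarts (NLL within $10^{-6}$) are broken toward smaller $\sigma$, then
smaller $\theta$, so output is deterministic. A fit whose $\sigma$ lands
on its floor (constant data) is flagged `degenerate`.

`fit_shared()` fits one triple to several lineages by summing their NLLs
(the null of the heterogeneity test, $k = 3$); `model_comparison()`
computes $\mathrm{LRT} = 2(\mathrm{NLL}_\mathrm{null} -
\mathrm{NLL}_\mathrm{alt})$ with $df = k_\mathrm{alt} - k_\mathrm{null}$,
the chi-square upper-tail p-value, and $\mathrm{AIC} = 2k +
2\,\mathrm{NLL}$ for both models. AIC (not BIC) is reported because
temporal correlation reduces the effective sample size that BIC's penalty
presumes.

### Profile surfaces and identifiability

`profile_surface()` fixes $\mu$ at its MLE and evaluates
$\Delta\mathrm{NLL}$ on log-spaced $(\theta, \sigma)$ grids spanning
$\pm 3$ log10 units around the optimum (default $61 \times 61$; "log
units" read as decades to match the log-spaced grids). A point worth
stating plainly: when the sampling interval is coarse relative to
$1/\theta$ (e.g. $\Delta t = 3$ with $\theta \approx 0.8$, so
$e^{-\theta\Delta t} \approx 0.1$), successive observations are nearly
decorrelated and the likelihood has a ridge along which $\theta$ and
$\sigma$ rise together at fixed stationary variance. On such designs the
*identified* quantities are $\mu$ and $\sigma^2/2\theta$, not $\theta$
and $\sigma$ separately; the test suite asserts exactly that (recovery of
$\mu$ within 0.2 and of the stationary variance within a factor of 1.5 on
5-replicate, 8-point panels), while dense designs (6 replicates × 200
unit-spaced points) identify all three parameters to about 10%. Slow
mean reversion widens the low-confidence $\theta$ region along the
fitted-$\sigma$ slice relative to fast reversion at matched length.

### Bootstrap

`bootstrap()` resamples replicate trajectories with replacement (same
count), refits, and records $(\mu, \theta, \sigma)$ plus the derived
$10^\mu$ and $\sigma^2/2\theta$ per draw; 2.5/50/97.5 percentile
intervals are taken per quantity *directly from the draws* — derived
quantities are transformed per draw before quantiles, never by
transforming interval endpoints. Refits start from the full-data MLE with
a small jitter (sd 0.05 in the internal coordinates) and 3 restarts:
running a full 24-restart search per draw would cost an order of
magnitude more for no measurable change in the draws. The
$\mathrm{corr}[\log\theta, \log\sigma]$ summary quantifies the ridge
coupling described above. Draws whose refit fails are skipped and
counted; more than 20% failures aborts. With few replicates (5–6, as
here) the percentile interval is known to be anti-conservative; the
nested simulation study in the test suite (30 outer panels, $B = 120$)
demands at least 80% empirical coverage of a nominal 95% interval for
each parameter, which is what this estimator honestly delivers at that
replicate count.

## Trajectory separation

For two lineages with predictive laws $\mathcal N(m_A(t), v_A(t))$ and
$\mathcal N(m_B(t), v_B(t))$ on a shared grid (default
$t = 0, 3, \dots, 21$ relative to the first observation):

- $D_\mathrm{mean} = \mathrm{mean}_t\,|m_A - m_B|$, with
  $10^{D_\mathrm{mean}}$ an approximate fold separation;
- the time-averaged 2-Wasserstein distance. The exact 1-D Gaussian W2 is
  $\sqrt{(m_A - m_B)^2 + (\sqrt{v_A} - \sqrt{v_B})^2}$ (the `"sd"`
  convention, default, a true metric); a `"variance"` convention
  substituting $(v_A - v_B)^2$ is retained because some published
  formulations print it that way — the two nearly coincide whenever the
  variance paths are similar;
- the dominance probability
  $P(A>B) = \mathrm{mean}_t\,\Phi\!\big((m_A - m_B)/\sqrt{v_A + v_B}\big)$,
  antisymmetric by construction.

`separation_summary()` recomputes all metrics across *paired* bootstrap
draws and reports per-metric percentile quantiles. The conditioning value
$y_0$ of each lineage defaults to the mean of its replicates' first
observations — the paper-level convention adopted package-wide for
lineage-level predictions, with an explicit override everywhere.

## Lineage networks

`simulate_lineage_network()` advances every extant clone's trait by one
exact OU transition per step `dt` (default 0.05), then lets it divide
with probability $1 - e^{-\lambda(Y)dt}$ and die with probability
$1 - e^{-\delta(Y)dt}$, death resolved after division within a step.
The exponential-waiting forms stay in $[0, 1]$ for any clipped rate and
any `dt`, unlike the naive $\mathrm{rate}\times dt$. A daughter starts at
its parent's current trait; an optional Gaussian inheritance jitter
(default sd 0) covers the alternative reading in which division itself
perturbs the trait. At most one division per clone per step is possible,
so the simulator warns when the realized $\lambda \cdot dt$ exceeds 0.2.
Runs stop at `t_max` (default 40), extinction, or a population cap
(default $10^5$, flagged as truncation, not an error). Extant/extinct
status is recorded at the snapshot time (default 20);
`downsample_extant()` draws a seeded uniform subset of extant clones
(default cap 2000) plus their ancestor paths so the displayed forest
stays connected — ancestors kept only for connectivity are marked
`in_sample = FALSE`, and the underlying simulation is never altered.
Networks export to GraphML (via igraph), edge-list CSV, or JSON.

## Phase plane and therapy

`vector_field()` samples the deterministic skeleton
$dY/dt = \theta(\mu - Y)$, $dN/dt = (\lambda(Y) - \delta(Y))N$;
`simulate_phase_trajectory()` overlays stochastic paths using exact OU
updates and Poisson (tau-leap) birth/death events with $\Delta t = 0.05$,
deaths capped at $N$ and $N = 0$ absorbing.

The therapy simulator holds the OU parameters fixed (drug exposure enters
phenomenologically through the demographic rates only) and modulates

$$\lambda(Y, C) = \lambda_0 e^{\alpha(Y - \mu_0) - k_\lambda g(C)},\qquad
\delta(Y, C) = \delta_0 e^{-\beta(Y - \mu_0) + k_\delta g(C)},\qquad
g(C) = \frac{C}{C + EC_{50}},$$

with $\mu_0$ the pre-therapy optimum (default: the OU equilibrium mean).
The default schedule is six 21-day cycles followed by observation to 200
days at $\Delta t = 0.5$ day, 256 replicates per arm, with the untreated
control arm run from the identical seed so a null therapy
($k_\lambda = k_\delta = 0$) yields bit-identical arms. "Cure" means the
population reaches exactly zero by `t_max`.

The exposure constants are illustrative, not calibrated: $\lambda_0 =
0.30$, $\delta_0 = 0.15$ per day, $\alpha = \beta = 0.5$, $k_\lambda =
k_\delta = 1.5$, $EC_{50} = 1$, amplitude $2 \cdot EC_{50}$. The default
pulse lasts 14 of each cycle's 21 days. This duration was chosen
deliberately: with the constants above, the qualitative regime in which
strong mean reversion favors cure and strong diffusion favors escape
requires the regimen to be net-lethal at the baseline optimum (on-drug
kill must outweigh between-dose regrowth, here $14 \times 0.30 >
7 \times 0.15$ per cycle in log units). A short pulse (say 5 of 21 days)
leaves the equilibrium phenotype net-growing through each cycle, and the
only route to extinction is then a long low-phenotype excursion — which
*inverts* the parameter trends. `cure_probability_map()` sweeps
$(\theta, \sigma)$, reusing the treated arm only; replicates that hit the
population cap are frozen there and counted as not cured, and a cell
whose every replicate escapes has $P(\mathrm{cure}) = 0$.

## The synthetic-data generator

`generate_panel()` emulates the structure of replicate
mutation-frequency panels from a long-term evolution experiment: three
default lineages with the reported OU triples — WT $(-6.799, 0.775,
0.727)$, priA $(-5.000, 0.117, 0.436)$, recG $(-7.652, 8.516, 2.789)$ —
5 replicates each (the source experiment's replicate count is not public;
5 is a typical evolution-experiment panel), sampled on $t = 0, 3, \dots,
21$, initialized from the stationary law so early observations are
typical, transformed to frequencies $x = 10^y$, and censored to exact
zeros below a true detection floor of $10^{-8}$ (so that the recG
lineage, whose stationary mass dips below $-8$, produces realistic
zeros). Ground truth travels with the panel for recovery tests.

What the generator does *not* emulate: measurement error on top of the
process (the trait is modelled as directly observed), mechanistic
mutation-accumulation dynamics, replicate-level parameter heterogeneity,
and irregular or missing visits. Passing recovery tests therefore
demonstrate correctness of the inference machinery under the model, not
robustness to observation noise or model misspecification.

## Numerical choices

- Quantiles everywhere (envelopes, bootstrap intervals, ensemble bands)
  use linear interpolation between order statistics (`stats::quantile`
  type 7): standard and continuous in the sample size.
- Optimizer: L-BFGS-B on $(\mu, \log\theta, \log\sigma)$, relative NLL
  tolerance $10^{-10}$, 500 iterations, 24 restarts (3 with jitter for
  bootstrap refits); restart ties broken toward smaller $\sigma$ then
  $\theta$.
- Profile grid entries that overflow are stored as `+Inf`; small negative
  $\Delta\mathrm{NLL}$ from finite optimizer tolerance is clamped to 0,
  and anything below $-10^{-6}$ triggers a warning that the fit may not
  be at the MLE.
- Chi-square tails come from `stats::pchisq`; the test suite checks them
  against an independent even-df incomplete-gamma series to $10^{-10}$.
- Degenerate inputs: $dt = 0$ duplicates are rejected at dataset
  construction; a zero summed predictive variance contributes 0.5 to the
  dominance probability when means are equal (logged) and 0/1 otherwise;
  constant data yield a `degenerate`-flagged fit rather than an error.
- Every stochastic operation takes an explicit integer seed, restores the
  caller's RNG state, and derives any internal sub-streams
  deterministically from that seed, so identical calls are bit-identical
  and independent of execution order at the operation level.

## Problem sizes used by the test suite

Simulation sizes in the shipped tests were chosen to keep the full suite
around five minutes on one core while retaining statistical power: 10,000
trajectories for envelope self-coverage (checked against 4,000 fresh
ones), 4,000 birth–death runs for the extinction fraction, a 30-panel ×
$B = 120$ nested bootstrap coverage study, 200 networks for the selection
differential, and 200 replicates per cell on a $4 \times 4$ cure map. The
demonstration pipeline (`run_full_demo()`) uses $B = 200$ and 64 therapy
replicates for the same reason; all sizes are arguments, and the
full-scale settings ($B = 2000$, 256 replicates, 10,000-replicate
envelopes) are the package defaults.

## Known limitations

- No observation-noise layer: $y$ is the state, so assay noise inflates
  $\sigma$ estimates. A state-space extension is the natural next step.
- The replicate bootstrap needs several replicates to be meaningful; with
  5–6 it undercovers somewhat (see above), and with one replicate it
  degenerates to zero-width intervals by construction.
- $\theta$ and $\sigma$ are separately identified only when the sampling
  interval resolves the relaxation time $1/\theta$; report
  $\sigma^2/2\theta$ on coarse designs.
- The therapy layer is deliberately phenomenological: no pharmacokinetic
  compartments, no resistance evolution through parameter shifts, no
  schedule optimization. Its outputs are regime maps, not predictions.
- Branching simulators are non-spatial and single-trait.
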