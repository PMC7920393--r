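---
title: "Inferring seizure propagation on brain networks: model, inversion, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring seizure propagation on brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizprop)
```

## The model

`seizprop` models an epileptic seizure as a threshold cascade on a
weighted, directed structural brain network. Each region $i$ carries a
slow variable $z_i$ that accumulates from zero at a rate set by the
excitation function, and the region switches irreversibly from the
healthy to the seizure state when $z_i$ crosses 1:

$$\dot z_i = f_q\!\left(c_i,\; \sum_j w_{ij}\, H(z_j - 1)\right), \qquad z_i(0) = 0 .$$

Here $c_i$ is the region's scalar *excitability* (the model's proxy for
epileptogenicity), $w_{ij}$ the connection strength from region $j$ to
region $i$, and $H$ the Heaviside step. The *onset time* $t_i$ is the
first time $z_i$ reaches 1. The excitation function is a bilinear
interpolant in $(c, y)$ through four anchor values
$q = (q_{aa}, q_{ab}, q_{ba}, q_{bb})$ at $c = \mp 1$, $y \in \{0, 1\}$,
followed by exponentiation, so it is positive everywhere; declaring
$q_{ba} = q_{aa} + q_{ba}^\*$ and $q_{bb} = q_{ab} + q_{bb}^\*$ with
nonnegative starred increments makes it nondecreasing in $c$. The
connectome is normalized so that the maximal ingoing weight sum is 1,
which keeps the input argument $y$ inside the interpolation square.

Because $f_q > 0$, every region eventually seizes; regions with onset
after the seizure time limit $t_\mathrm{lim} = 90$ s are *associated
with the non-seizing state*. This turns the discrete question "does
region $i$ seize?" into the continuous question "when?", which is what
makes gradient-based posterior sampling workable.

Between threshold crossings the right-hand side is constant, so the
trajectory is piecewise linear and the forward problem
$P_{W,q}(c) = t$ has an exact event-driven solution: repeatedly advance
to $\min_i (1 - z_i)/\dot z_i$, switch the crossing regions in one
batch, and update the inputs. `simulate_onsets()` implements this in
C++ and, on request, propagates forward sensitivities
$\partial t_i / \partial c_j$ and $\partial t_i / \partial q$ along the
event sequence — between events the dynamics is linear, so the
sensitivities are exact wherever the event order is locally constant.
`simulate_dense()` is a deliberately independent explicit-Euler
integrator used only as an oracle in the tests.

## Statistical model and sampler

Observations are per-region onset times with Gaussian error
($\sigma_t = 5$ s). A seizing observation $\tilde t_i$ enters as
$\mathcal N(\tilde t_i \mid \min(t_i, t_\mathrm{lim}), \sigma_t)$; an
observed non-seizing region contributes
$\mathcal N(t_\mathrm{lim} \mid \min(t_i, t_\mathrm{lim}), \sigma_t)$ —
a one-sided soft penalty that is maximal (and flat) once the simulated
onset passes the limit. Hidden regions contribute nothing.
Excitabilities have a standard-normal prior; the hyperparameters have
$q_{aa}, q_{ab} \sim \mathcal N(0, \sigma_q)$ and
$q_{ba}^\*, q_{bb}^\* \sim \mathrm{HalfNormal}(\sigma_q)$ with
$\sigma_q = 30$.

Sampling uses a No-U-Turn Hamiltonian Monte Carlo sampler written for
this package (dual-averaging step size, windowed metric adaptation)
over the analytic gradients of the log posterior. The
$\min(t, t_\mathrm{lim})$ kink is handled by its flat subgradient, and
onset times are differentiable in $(c, q)$ except where the event order
changes — a measure-zero set that HMC crosses without issue in
practice. Two design points deserve mention:

* **The no-seizing plateau.** Wherever the simulated onsets of many
  regions exceed $t_\mathrm{lim}$, their likelihood terms are constant
  and gradient-free. A chain that wanders deep into this plateau sees
  only the prior and can drift far from the data-supported region,
  with the basin boundary acting as a divergence wall at the adapted
  step size. Three mitigations are built in: hierarchical fits
  initialize with anchor log-rates near $\log(1/t_\mathrm{lim})$ so
  initial onsets fall on the observation time scale; during warmup a
  chain that has fallen more than 50 log-posterior units below its
  best visited state is reset there and the poisoned adaptation window
  is discarded; and after sampling, any chain whose mean log posterior
  sits far below the best chain's is flagged together with
  variance-stuck chains, excluded from posterior summaries, and fits
  with *all* chains flagged are excluded from downstream analyses.
  This mirrors the stuck-chain bookkeeping that region-level fits on
  real recordings require.
* **Metric shape.** The hyperparameter posterior is strongly
  correlated (notably $q_{ab}$ with $q_{bb}^\*$), so `fit_cohort()`
  uses a dense metric block over the four hyperparameters and a
  diagonal metric over the excitabilities. Cohort fits cap the
  trajectory doubling depth at 8 to bound the cost of a single
  iteration; single-seizure fits use the conventional 10.

`fit_seizure()` holds $q$ fixed (two chains, 500 warmup + 500 kept
draws by default); `fit_cohort()` samples $(q, c_1, \dots, c_K)$
jointly (four chains by default) on the unconstrained scale, with the
log-transform Jacobian for the starred increments. A gradient-free
adaptive random-walk fallback (`method = "rwm"`) is available for tiny
networks. Chains for $c$ initialize from the prior.

## Preprocessing

The raw-data path mirrors what a clinical application needs:

* `normalize_connectome()` divides streamline counts by target-region
  volume, adds the 98th percentile of the volume-scaled weights to both
  directed entries of each anterior–posterior hippocampus pair (white
  matter tractography misses that strong gray-matter connection), and
  rescales so the maximal ingoing sum is 1. The percentile is computed
  over all entries with linear interpolation; a flag restricts it to
  nonzero entries.
* `band_logpower()` computes a sine-taper multitaper spectrogram (2 s
  windows, 1 s steps, 3 tapers — the 20 s mask smoothing downstream
  dominates the timing, so these are not critical and are exposed as
  arguments) and returns the natural-log band power in 1–12.4 Hz and
  12.4–100 Hz bands. `detect_channel_onset()` normalizes to the mean
  over the 60 s before the clinician's mark (the baseline ends at the
  mark), thresholds at $\log \delta$ with $\delta = 5$ (a five-fold
  power increase; the mask follows the one-sided rule, with a
  two-sided option), smooths the mask with a centered area-normalized
  20 s rectangle, re-binarizes at 0.5, and discards seizure intervals
  shorter than 20 s.
* `assign_channel_to_region()` maps a bipolar contact midpoint to its
  nearest region by minimum Euclidean distance to region voxels,
  leaving it unassigned when $d_2 / (d_1 + 0.5\,\mathrm{mm}) < 2$; no
  upper distance cap is applied, but midpoints more than 5 mm from
  gray matter trigger a warning. `aggregate_region_observation()`
  takes the median with lower interpolation (non-seizing channels
  entering as $\infty$), which coincides with the channel majority
  vote, ties resolved to the seizing side. `finalize_seizure()` aligns
  the earliest onset to $t_1 = 30$ s, reclassifies onsets beyond
  $t_\mathrm{lim}$ as non-seizing, and drops seizures with no seizing
  region. Seizures must last longer than 30 s to be included.

## Synthetic data: what it emulates, and what it does not

`generate_network()` draws Bernoulli edges with log-normal weights
(heavy-tailed, like streamline counts) and normalizes;
`generate_seizure()` draws $c \sim \mathcal N(0,1)$, simulates, hides a
uniform random subset of regions, and adds Gaussian onset noise;
`generate_seeg_signal()` produces band-limited noise whose variance
steps up by a chosen gain at the region onset. The default study
conditions are 20-region networks with edge density 0.3, 15 patients
with 2 seizures each (30 seizures), hidden fraction 0.3, and noise SD
5 s — large enough to constrain the four hyperparameters, small enough
for minutes-scale MCMC.

The default generating parameterization is
$q = (-6, -2.5, 3, 5)$. It was chosen on two *a priori* grounds: the
simulated ensembles resemble clinical seizure ensembles (per-seizure
seizing fractions spread over roughly 0.4–0.9, onset times dispersed
over the 90 s window with SD around 20 s, coupling excitatory), and
the starred components lie inside the central band of their
HalfNormal(30) hyperprior, so that interval-coverage checks of the
hierarchical fit are a meaningful calibration test — a truth in the
extreme low tail of its own prior would be excluded from
weakly-identified posteriors no matter how correct the sampler.

The generator reproduces the statistical structure the model assumes
and nothing more. Real SEEG morphology (spikes, DC shifts, artifacts),
spatially structured implantation bias, inter-patient variability of
the propagation dynamics, and connectome estimation error are all
absent. Passing the synthetic recovery tests therefore shows the
inversion machinery is correct and calibrated under the model's own
assumptions; it does not certify performance on clinical recordings.

## Validation machinery

Prediction quality is measured by the state prediction accuracy (the
posterior probability assigned to the true seizing/non-seizing state,
with the strict rule $t < t_\mathrm{lim}$ for seizing) and the onset
prediction accuracy (posterior probability of landing within $T = 5$ s
of the true onset, evaluated only for seizing regions with
$\tilde t_i < t_\mathrm{lim} - T$ to avoid the border effect). Two
estimator baselines replace the posterior draws with the other
observed regions' onsets — unweighted, or weighted by the symmetrized
connection strength $w_{ij} + w_{ji}$ normalized once. `run_loo()`
hides each observed region in turn, refits, and scores all three
methods against the withheld truth.

Epileptogenic-zone scoring thresholds the high-excitability
probability $p(c_i > c_h)$ at $c_h = 2$ — under the prior this marks
an expected $162 \times (1 - \Phi(2)) = 3.69$ regions in a 162-region
parcellation — and compares against a resected-region set (regions
with resection extent strictly above 50%) via precision–recall curves
swept over the probability threshold. With no predicted regions,
precision is reported as 1 with an explicit flag, and such points are
dropped from curves by default. `virtual_resection()` removes the
resected regions, re-simulates every posterior draw, and reports the
number of regions with recruitment probability above 50% at
$t_\mathrm{lim}$ before (all regions) and after (surviving regions
only) surgery, the relative reduction, and a thresholding-free mean
seizure-probability decrease in which resected regions enter the
post-operative mean as zero. Per-patient aggregation over seizures
defaults to the mean, with the minimum as an option.
`permutation_feature_importance()` scores any regressor with a
`predict` method by the drop in $R^2$ after permuting one feature
column $K = 30$ times.

## Numerical choices and edge cases

* Heaviside at the threshold: $H(0) = 1$; a region counts as seizing
  from its onset instant. Onsets exactly at $t_\mathrm{lim}$ classify
  as non-seizing (strict inequality for seizing).
* Simultaneous crossings are switched in one batch (a measure-zero
  event for continuous $c$); the batch tolerance is
  $10^{-12}(1 + |t|)$.
* $c$ outside $[-1, 1]$ is extrapolated with the same bilinear form —
  standard-normal excitabilities routinely exceed the anchors and the
  formula stays valid (linear in $c$).
* `invert_excitabilities()` solves the accumulated-growth equation by
  bisection after geometric bracket expansion from $[-50, 50]$, to
  $10^{-10}$; a flat excitation function (zero derivative in $c$) is
  reported as non-identifiable. The exact inversion applies only to
  fully observed, fully seizing, noiseless networks.
* Event-cascade monotonicity ("raising one $c_i$ never delays any
  onset") holds when the excitation rate is nondecreasing in the input
  $y$; the hyperprior also admits inhibitory parameterizations
  ($q_{ab} < q_{aa}$) in which an early-seizing neighbour genuinely
  delays others — both solvers agree on this. The property-based tests
  therefore sample the uniform excitatory regime where the property is
  provable.
* The dense-oracle tolerance scales as
  $\mathrm{d}t\,(1 + n\, r_\max / r_\min)$: a one-grid-step delay of an
  input switch converts to a downstream onset shift of at most the
  step times the rate ratio, once per event.
* The `+Inf` onset sentinel is serialized as the string `"inf"` in
  CSV.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic
data: oracle comparisons on 50–60 networks of up to 15 regions;
round-trip inversion on 10-region networks; single-seizure fits on
10–15 regions at 2 chains × (500 + 500); hierarchical recovery on the
default 30-seizure, 20-region cohorts, refit from scratch for several
seeds at 2 chains × (500 + 500) — the chain count is the knob we
reduce relative to the 4-chain default, keeping the per-chain layout.
Interval coverage is then required for every hyperparameter component
in at least 80% of the repeats.

## Known limitations

The model has no seizure offset and no per-seizure time limit; the
excitation parameterization is shared across seizures and patients
(no patient level in the hierarchy); the non-seizing likelihood term
is the printed soft penalty, not a renormalized censored density; the
sampler's R-hat for hyperparameters can sit somewhat above 1.1 on
weakly identified components even when interval coverage is correct —
the hyperparameter posterior is reduced to its mean before any
downstream use, which is far less demanding than tail estimation. The
gradient-boosting regressor behind the feature-importance analysis is
out of scope by design; any fitted regressor can be plugged in.
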