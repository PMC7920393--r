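# seizprop

Clinical evaluation of drug-resistant epilepsy observes a seizure only
where depth electrodes happen to be: a handful of brain regions are
seen seizing (with an onset time) or not seizing, and the rest of the
brain is hidden. `seizprop` fills in that picture. It implements a
data-driven model of seizure recruitment and propagation across the
patient's structural connectome, and inverts it with Bayesian
inference to estimate *if and when* the unobserved regions are
recruited, and *which regions are excitable enough* to be part of the
epileptogenic zone.

The package is aimed at computational neuroscientists working with
stereo-EEG (SEEG) and diffusion-MRI connectomes, and at methodologists
who want a fully testable, synthetic-data-backed reference
implementation of threshold dynamics inversion on networks.

## The model

A seizure is a threshold cascade on a weighted directed network
*W* = (*w<sub>ij</sub>*), normalized so the maximal ingoing weight sum
is 1. Each region *i* has a slow variable *z<sub>i</sub>* with

  *ż<sub>i</sub>* = *f<sub>q</sub>*(*c<sub>i</sub>*, Σ<sub>j</sub> *w<sub>ij</sub>* *H*(*z<sub>j</sub>* − 1)),  *z<sub>i</sub>*(0) = 0,

seizing from the moment *z<sub>i</sub>* crosses 1 (its *onset time*
*t<sub>i</sub>*). The excitation function
*f<sub>q</sub>*(*c*, *y*) = exp(bilinear in (*c*, *y*)) is positive and
nondecreasing in the excitability *c*; it is parameterized by four
anchor values *q*. Regions seizing after *t*<sub>lim</sub> = 90 s count
as non-seizing. Onset observations carry Gaussian error
(σ<sub>t</sub> = 5 s); excitabilities have a standard-normal prior; the
four hyperparameters *q* are shared across seizures and patients and
carry Normal/HalfNormal(σ<sub>q</sub> = 30) hyperpriors.

The forward map is solved exactly by an event-driven simulator (with
analytic forward sensitivities, in C++), and the posterior is sampled
with a No-U-Turn Hamiltonian Monte Carlo sampler written for this
package: `fit_seizure()` for one seizure at fixed *q*, `fit_cohort()`
for the joint hierarchical fit of *q* and per-seizure excitabilities.
Around the core sit the preprocessing (SEEG band-power onset
detection, channel-to-region mapping, connectome normalization),
validation (leave-one-out accuracies, estimator baselines,
precision–recall against resections, virtual resection, permutation
feature importance) and synthetic-data generators, so the entire
pipeline runs end-to-end with no external data.

## Worked example

Simulate a partially observed seizure on a random normalized
connectome, then invert it:

```r
library(seizprop)
W  <- generate_network(12, density = 0.3, seed = 42)
q  <- excitation_params(-6, -2.5, 3, 5)
sz <- generate_seizure(W, q, hidden_fraction = 0.25, noise_sd = 5, seed = 7)
sz$obs
#> Seizure observation: 12 regions (5 seizing, 4 non-seizing, 3 hidden)

fit <- fit_seizure(sz$obs, W, q, chains = 2, seed = 99)
fit
#> Single-seizure fit (nuts): 12 regions, 2 chains x 500 draws
#>   max R-hat 1.023, min N_eff 83, stuck chains 0/2

head(summary(fit), 6)
#>   region_id      status   mean    sd  rhat   n_eff p_high
#> 1        R1     seizing  2.037 0.445 1.013 376.314  0.462
#> 2        R2 non-seizing -0.865 0.584 1.003 340.490  0.000
#> 3        R3 non-seizing -0.871 0.583 1.015 214.370  0.000
#> 4        R4 non-seizing -0.994 0.503 1.000 368.805  0.000
#> 5        R5      hidden -0.049 1.039 1.003 480.508  0.033
#> 6        R6      hidden -0.256 0.939 0.998 616.572  0.016
```

`mean`/`sd` summarize each region's posterior excitability, and
`p_high` is the probability that it exceeds the high-excitability
threshold *c<sub>h</sub>* = 2 — the model's epileptogenicity score.
Here the observed early-seizing region R1 is flagged
(p(c > 2) ≈ 0.46) while the observed non-seizing regions are cleared.
Recruitment probabilities *r<sub>i</sub>*(*t*) = p(*t<sub>i</sub>* ≤ *t*)
fill in the hidden regions' time courses:

```r
predict(fit, "recruitment", times = c(30, 60, 90))[, 1:6]
#>    R1   R2   R3   R4   R5   R6
#> 30  1 0.00 0.00 0.00 0.25 0.14
#> 60  1 0.00 0.00 0.00 0.43 0.28
#> 90  1 0.05 0.05 0.05 0.56 0.39
```

The hidden region R5 is recruited by *t*<sub>lim</sub> with posterior
probability 0.56 — information no per-channel reading could provide.
From here, `run_loo()` scores such predictions against withheld
observations, and `virtual_resection()` predicts the effect of a
surgical resection by removing regions and re-simulating every
posterior draw.

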