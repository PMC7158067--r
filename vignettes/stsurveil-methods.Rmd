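---
title: "Models and detection rules in stsurveil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and detection rules in stsurveil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stsurveil` implements Bayesian hierarchical models for surveillance of
non-communicable disease counts on an area-by-time grid, together with the
detection rules that turn their posteriors into per-area anomaly flags and a
replicate benchmark that scores those rules. This vignette is the package's
account of the science: the models and their assumptions, the priors and
tunable parameters, the synthetic scenario the benchmark runs on, and the
numerical and design choices that were genuinely open.

## Data model

All three models share the Poisson data layer

$$y_{it} \sim \mathrm{Poisson}(E_{it}\,\rho_{it}), \qquad
  \log \rho_{it} = \eta_{it},$$

where $y_{it}$ and $E_{it}$ are the observed and expected counts for area
$i = 1,\dots,N$ at time $t = 1,\dots,T$, and $\rho_{it}$ is the relative
risk. Expected counts are the usual reference-rate offsets; everything the
models explain lives in $\eta_{it}$.

Spatial dependence uses the intrinsic CAR (ICAR) prior on the adjacency
graph of the areas: for a spatial field $\theta$,
$p(\theta \mid \tau_\theta) \propto
 \exp\{-\tfrac{\tau_\theta}{2}\sum_{i \sim j}(\theta_i - \theta_j)^2\}$,
an improper density that penalises differences between neighbouring areas
and is identified by sum-to-zero constraints (one per connected component in
the prior; the sampler recentres each sweep, absorbing the mean into the
flat-prior intercept — an exact gauge move). Temporal dependence uses the
analogous first-order random walk (RW1) on successive time points, which is
the ICAR prior of the path graph.

## The three models

**Disease mapping (DM).**
$\eta_{it} = \alpha + \theta_i + \phi_i + \gamma_t + \psi_{it}$ with ICAR
$\theta$, exchangeable normal $\phi$ (the BYM convolution), RW1 $\gamma$,
and exchangeable interaction noise $\psi_{it}$. DM is descriptive; it is
used for detection informally, by thresholding the posterior probability
that the space-time interaction exceeds 1 on the risk scale,
$P(\psi_{it} > 0 \mid y)$ (a configuration switch thresholds the total
relative risk $P(\rho_{it} > 1 \mid y)$ instead).

**STmix.** The same structure with the interaction prior replaced by a
two-component zero-mean normal mixture,
$\psi_{it} \sim p\,N(0, \sigma_1^2) + (1 - p)\,N(0, \sigma_2^2)$,
$\sigma_1 \le \sigma_2$: the small component carries ordinary
overdispersion, the large one absorbs genuinely anomalous space-time units.
Label switching is the classic failure mode of such mixtures; the package
uses both published devices at once by default: asymmetric informative
Gamma priors on the two precisions (defaults centre $\sigma_1$ near 0.05 —
a few percent wobble on the risk scale — and $\sigma_2$ near 0.5, tens of
percent) *and* the ordering constraint $\sigma_2 \ge \sigma_1$, enforced by
truncated-Gamma Gibbs draws so every retained draw is ordered. A
symmetric-vague-plus-ordering variant is selectable
(`identification = "ordered"`).

**FlexDetect core (common-trend vs area-specific-trend mixture).** Each
area follows one of two submodels: a *common* model in which all areas share
one temporal trend, and an *area-specific* model in which each area has its
own RW1 trend,

$$\text{common: } \eta_{it} = \alpha + \theta_i + \phi_i + \gamma_t + \psi_{it},
 \qquad
 \text{specific: } \eta_{it} = a_i + \delta_{it},$$

with a per-area indicator $z_i \in \{0 = \text{common}, 1 = \text{unusual}\}$.
Both submodels are fitted to the full data and the feedback from $z$ into
the submodel fits is severed (the model-choice "cut"); each sweep, $z_i$ is
Gibbs-drawn from the two submodels' at-draw likelihoods for area $i$ with
prior odds $\pi/(1-\pi)$ for the common model. The detection score is the
posterior model probability $\tilde p_i = \Pr(z_i = 0 \mid y)$, the draw
frequency of the common model.

Three design choices here were genuinely open and matter in practice:

* *The common submodel is the full standard spatiotemporal specification*
  (convolution $\phi$ and iid interaction $\psi$ included), not the bare
  $\alpha + \theta_i + \gamma_t$ skeleton. With the bare skeleton, ordinary
  area-level heterogeneity and cell-level overdispersion — both present in
  any realistic panel — have nowhere to go in the common model, so the
  area-specific submodel wins the likelihood comparison for perfectly
  ordinary areas and the method flags areas for their *level* or *wobble*
  rather than their *trajectory*. The detection contrast is then exactly
  "shares the global trend, up to ordinary noise" versus "needs its own
  trend". Both simplifications are recoverable
  (`common_bym = FALSE`, `common_overdispersion = FALSE`).
* *The prior inclusion probability is a design prior, fixed at 0.95 by
  default* (the mean of the Beta(19, 1) surveillance prior: unusual areas
  are rare). Sampling $\pi$ from its Beta full conditional is available
  (`update_pi = TRUE`) but not the default: with a couple of hundred areas
  the likelihood swamps the prior and the sampler admits a collapsed
  low-$\pi$ regime in which ordinary areas are absorbed by the
  area-specific submodel en masse.
* *Per-area trend precisions with an informative smoothing prior.* Each
  area's trend $\delta_{i\cdot}$ has its own RW1 precision
  $\tau_{\delta,i} \sim \mathrm{Gamma}(2, 0.02)$ (prior mean 100, i.e.
  month-to-month increments of about 10%). Ordinary areas keep stiff,
  near-flat trends — the area-specific model cannot chase Poisson noise —
  while a genuinely anomalous area pulls its own precision down and frees
  its trend. This is the informative-variance identification device the
  mixture needs; no standard values exist for
  these hyperparameters, so the defaults are the package's own choice,
  exposed as `tau_delta_a` / `tau_delta_b`.

Whether the mixture indicator should sit at area level or area-time level
is a genuinely open design point; the package places it at area level
(`z_i`), matching the stated goal of detecting *areas with unusual time
trends*, and matching the area-level truth labels of the benchmark.

## Priors, parameters, defaults

| Parameter | Default | Meaning |
|---|---|---|
| precisions $\tau$ (structural blocks) | Gamma(1, 0.01) | vague but proper |
| $\alpha$, $a_i$ | flat | identified via sum-to-zero constraints; conjugate log-Gamma Gibbs |
| STmix $\tau_1$ | Gamma(2, 0.005) | $\sigma_1 \approx 0.05$, common wobble |
| STmix $\tau_2$ | Gamma(2, 0.5) | $\sigma_2 \approx 0.5$, anomalies |
| STmix $p$ | Beta(1, 1) | mixture weight, data-dominated |
| FlexDetect $\pi$ | 0.95, fixed | prior probability of the common model |
| FlexDetect $\tau_{\delta,i}$ | Gamma(2, 0.02) | per-area trend smoothing |
| exceedance thresholds | 0.8 / 0.9 | strict inequality at the boundary |
| FDR budget $\alpha$ | 0.05 | Bayesian FDR rule |

## Computation

Posteriors are explored by MCMC written for this package: vectorised
single-site random-walk Metropolis for the latent fields (areas in one
colour class of a greedy graph colouring are pairwise non-adjacent, hence
conditionally independent, and move as one vectorised block; time points
alternate odd/even), conjugate Gibbs draws for all precisions and for the
flat-prior intercepts (whose exponentials have Gamma full conditionals),
Bernoulli Gibbs draws for the mixture indicators, and truncated-Gamma Gibbs
draws for the ordered STmix precisions. Proposal scales adapt during
burn-in only (Robbins-Monro towards 0.44 acceptance), so the retained chain
is Markovian. Defaults: 2 chains of 20 000 sweeps, 10 000 burn-in, thin 10;
`fast_mcmc_config()` (2 x 5 000 / 2 500 / 5) is the desk-scale setting used
by the replicate benchmark and the test suite. Convergence is assessed with
the Gelman-Rubin potential scale reduction (floored at 1; mixture models
are the usual suspects for poor mixing).

Two internal audits run continuously: incremental likelihood caches are
compared against a fresh recomputation every 100 sweeps, and the
FlexDetect mixture likelihood is checked to equal the Poisson
log-likelihood of the $z$-selected log-risks. A joint-distribution
(successive-conditional) audit validates the transition kernels: prior
draws and MCMC-plus-data-refresh draws of a small disease-mapping model
must agree in all marginal moments. Because the recentring gauge move is
exact only under the flat intercept prior, that audit runs with the
intercept fixed and moves the intrinsic fields by sum-preserving pairwise
Metropolis kernels (antisymmetric $\pm\varepsilon$ proposals on a random
pairing), which are exactly invariant on the constraint subspace; all
density code, iid-field kernels and precision updates are the production
paths.

Numerical details worth knowing: exceedance probabilities use strict
inequality (`draws > 0`), matching the strict thresholds of the rules; the
Bayesian FDR rule flags ties with the last flagged value together; metrics
with empty denominators are reported as 0 (so a rule that flags nothing has
FDR 0, the convention benchmark tables use); truncated-Gamma draws clamp
their uniforms away from 0 and 1 to avoid infinite quantiles; isolated
areas receive no spatial smoothing and are warned about; disconnected
graphs are allowed — the sampler recentres the spatial field globally and
the exchangeable area effect keeps per-component levels proper.

## The synthetic scenario

The benchmark scenario emulates a monthly panel over an irregular
administrative map: 211 areas, 15 time points, Poisson counts around a
smooth spatiotemporal baseline, with 15 areas carrying a known signal —
log relative risk raised by $\log 2$ at time points 3 and 10 and lowered by
$\log 2$ at time points 6, 12 and 15. Baseline scales: spatial difference
sd 0.2, RW1 increment sd 0.15, unstructured and interaction sd 0.05;
per-area expected counts uniform on [20, 60], drawn once and held constant
over time — plausible for monthly small-area admission counts. Unusual
areas are chosen uniformly at random (no spatial pattern is imposed). The
adjacency map is a Gabriel-graph-plus-2-nearest-neighbour triangulation of
random points (mean degree about 4-6, always connected), built once per
study and shared across replicates the way one real map underlies every
replicate of a study; no boundary files are shipped or processed.

What the generator does *not* emulate: population denominators and age-sex
standardisation (expected counts are abstract offsets), seasonality,
covariates, spatially clustered anomalies (the signal areas are scattered),
reporting artefacts, and any fitting to real hospital-episode data.
Benchmark results on this scenario therefore show that the detectors work
as designed under a known, additive-log-signal mechanism — not that they
would achieve the same numbers on real admissions data, whose baseline
parameters are unknown here.

One consequence deserves emphasis. With expected counts of 20-60, a
$\pm\log 2$ shift is decisively detectable (model-choice sensitivity sits
near 0.85-1.0), and per-cell exceedance statistics are *sharp*: an
ordinary cell whose residual happens to reach ~0.35 on the log scale gets
$P(\psi_{it} > 0 \mid y)$ above 0.8 even under heavy shrinkage, because the
posterior standard deviation of a shrunken interaction is small at these
counts. Across 196 x 15 ordinary cells such residuals occur regularly, so
the any-single-time-point rules (the 0.8/0.9 exceedance rules and the
single-point mixture rule) carry a substantial false-discovery rate under
this scenario. The three-point mixture rule and the model-choice FDR rule,
which require evidence aggregated over time, keep their false discoveries
near zero. The qualitative ranking of the detectors — exceedance
thresholding worst-controlled, time-aggregated mixture rules
best-controlled — is robust; the individual FDR values depend strongly on
the expected-count regime.

## Problem sizes used by the shipped tests

Unit tests run on panels of roughly 20-40 areas with short chains; the
acceptance suite runs the joint-distribution audit on a 6-area x 4-time
model (20 000 sweeps), recovery and null-calibration experiments at 50-120
areas, and the benchmark at full scenario size with 3 fast-mode replicates.
The full published-scale benchmark (50 replicates, full-length chains) is a
few hours of single-core work: `run_study(n_replicates = 50,
cfg = mcmc_config())`, or `stsurveil benchmark` from the shell.

## Known limitations

* Single outcome, single spatial resolution; no shared-component or
  multivariate models, no forecasting, no scan-statistic comparisons.
* The per-area trend smoothing prior trades sensitivity against false
  discoveries; its defaults were chosen for monthly panels and should be
  revisited for other time scales.
* MCMC only — no INLA-style approximation (the mixtures are outside its
  reach) and no Hamiltonian sampler; long panels with many areas pay the
  usual single-site price.
* Exceedance-rule thresholds (0.8, 0.9) are conventions whose operating
  characteristics depend on expected counts, panel size and spatial
  structure; a simulation with the characteristics of the data at hand
  (which `run_study` makes cheap) is the recommended way to choose them.
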