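---
title: "Methods: race-model SSRT, locus coeruleus contrast, and the moderated-mediation layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-model SSRT, locus coeruleus contrast, and the moderated-mediation layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsst)
```

`lcsst` implements a complete analysis chain linking locus coeruleus (LC)
integrity to response inhibition: a hierarchical Bayesian ex-Gaussian race
model of the stop-signal task (SST) with attentional failures, atlas-based
contrast-to-noise (CNR) extraction from magnetization-transfer-weighted
brainstem volumes, and an inferential layer built around moderated
regression, default Bayes factors and moderated mediation. Because the
cohort data this kind of study uses are not freely redistributable, every
stage is paired with a seeded synthetic-data generator with known ground
truth, so the whole chain can be exercised and validated end to end. This
vignette explains the models, the defaults, and the choices made where the
design was genuinely open.

## The stop-signal race model

Each SST trial is modelled as a race between three independent processes:
a go process matching the stimulus direction, a go process mismatching it,
and — on stop-signal and no-go trials — a stop process that starts at the
stop-signal delay (SSD). Each racer's finish time follows an ex-Gaussian
distribution (normal with mean $\mu$ and SD $\sigma$ convolved with an
exponential of mean $\tau$), the standard parametric family for response
times. The observed response is the earliest go finisher unless the stop
process finishes first.

Two attentional-failure probabilities complete the model: with probability
$p_{tf}$ (*trigger failure*) the stop process never starts, and with
probability $p_{gf}$ (*go failure*) neither go process starts, producing
an omission. Ignoring these failures is known to bias SSRT estimation,
which is why they are estimated jointly with the racer parameters.

The stop-signal reaction time is defined as the mean of the stop racer's
finish-time distribution, $SSRT = \mu_{stop} + \tau_{stop}$, computed per
posterior draw to give a full SSRT posterior; mean go RT is
$\mu_{go\text{-}match} + \tau_{go\text{-}match}$ in the same way.

The per-trial likelihood is a defective-density mixture
(see `?loglik_trial`). Its key integral, the probability that the stop
racer beats both go racers,

$$P_{success}(d) = \int f_{stop}(s - d)\,[1 - F_{match}(s)]\,[1 -
F_{mismatch}(s)]\,ds,$$

has no closed form. `stop_success_probability()` evaluates it by adaptive
quadrature (relative tolerance $10^{-8}$); inside the sampler a fixed
composite Gauss–Legendre rule is used instead, with one panel over the
Gaussian bump ($\mu \pm 8\sigma$) and one over the exponential tail
($12\tau$ beyond it), 16 nodes each. The two-panel split matters: the bump
is typically an order of magnitude narrower than the tail, and a single
panel across the union wastes most of its nodes. Log-likelihoods of
impossible outcomes are floored at $-10^{10}$ rather than $-\infty$ for
sampler stability.

No-go trials are treated as stop trials with a nominal 5-ms SSD, both in
generation and in fitting, matching how such trials are scored in this
task family.

### Hierarchical structure and priors

Participant-level parameters are drawn from independent group-level normal
distributions: one (location, scale) pair per parameter, with the failure
probabilities mapped to the probit scale so their group normals are
unbounded. The nine ex-Gaussian parameters are restricted to positive
support *implicitly*: the participant-level prior is a plain normal and
the support restriction is enforced through the likelihood, without
renormalizing by $\Phi(\mathrm{loc}/\mathrm{scale})$. We initially
implemented the exactly renormalized truncated-normal model and found it
poorly identified at cohort sizes of interest: the normalizer lets a very
negative location with a large scale mimic an exponential shape, creating
a likelihood ridge along which the "group location" of the stop racer
drifted to meaningless negative values. The implicit-truncation
convention, which is also what the established toolboxes for this model
family use, removes the ridge entirely; for realistic settings
($\mathrm{loc}/\mathrm{scale} > 3$) the two models are numerically almost
identical anyway.

Priors (`default_priors()`): group locations are normal with means 1.5 s
for the two go-racer $\mu$s and 1.0 s for $\mu_{stop}$ — deliberately slow
centres appropriate for an older cohort — 0.1 s for all $\sigma$ and
$\tau$ locations, $-1.5$ for the probit failure locations, all with SD
1.0. Group scales have half-normal priors with SD 0.15 for the nine
seconds-scale parameters and 0.5 on the probit scale. The 0.15 figure is a
deliberate tightening relative to a generic half-normal(0.5): a
between-participant SD of half a second for an RT component is not
scientifically plausible, and the heavy tail it allows makes the scale
posteriors of data-poor parameters (the mismatch racer is informed only by
choice errors, a few percent of trials) mix far too slowly. All priors are
plain configuration and can be overridden.

### Sampler

`fit_hierarchical()` uses differential-evolution MCMC at the participant
level: each chain proposes a crossover step built from the difference of
two other randomly chosen chains ($\gamma = 2.38/\sqrt{2d}$, jittered),
applied to a random subset of the 11 dimensions (all of them half of the
time). Each iteration adds two further moves per participant: a targeted
crossover on the stop-racer/failure subspace, whose posterior is the most
weakly identified, and an independence move that redraws a random subset
of the data-poor dimensions (mismatch racer, failure probabilities) from
the chain's current group prior — for those dimensions the prior terms
cancel in the Metropolis ratio and the move is accepted on the likelihood
ratio alone, giving near-iid mixing where the data say little. With the
configured probability (default 5%) an iteration instead performs a
migration step: a random subset of chains cyclically exchanges states
through Metropolis-accepted swaps.

At the group level the conditional posterior factorizes over the 11
parameters, so the sampler uses exact conjugate Gibbs draws for each
location and univariate slice sampling (on the log scale) for each scale.
We first implemented a 22-dimensional crossover for the hyperparameters,
mirroring the participant level, and measured group-level potential scale
reduction statistics above 3 at desk scale — the crossover acceptance rate
collapses in that geometry. The factorized conditional updates are exact,
cheap, and mix essentially instantly given the participant states.

Defaults follow the conventions of this model family: 33 chains (three
times the parameter count; at least twice is enforced), thinning of every
10th iteration, 5% migration probability, 500 retained iterations per
chain. Burn-in is adaptive: sampling proceeds in blocks and burn-in ends
once the running Gelman–Rubin statistic (second half of the burn-in
history) of every group-level parameter falls below 1.2, capped at a
configured maximum. If the retained draws still show a group-level R-hat
at or above 1.1 the run is extended (retained draws folded into burn-in)
up to `max_rounds` times and flagged by a warning if still not converged —
a non-convergent fit is never silently accepted.

Chains are initialized from the data (go-RT moments) with broad jitter,
never from generating values. Desk-scale analyses in the test suite and
the acceptance script use 24 chains with reduced thinning and retention
(8 participants × 480 trials converge in a few minutes on one core);
the full defaults are intended for real cohorts.

### Diagnostics and checks

`compute_rhat()` implements the classic Gelman–Rubin statistic
$\hat R = \sqrt{(\frac{n-1}{n} W + B/n)/W}$ over chains (floored at 1,
where the estimator can dip slightly below), with the conventional
convergence criterion $\hat R < 1.1$ for all parameters.
`posterior_predictive()` simulates fresh participants from random retained
draws of the group-level posterior through the same task simulator used
for data generation (staircase included), and compares observed response
proportions, accuracies and median RTs per trial type against the
predictive median and 95% quantile interval.

## Synthetic task data

`make_session_design()` reproduces the session layout: 360 go, 80 stop and
40 no-go trials by default, randomly interleaved with balanced left/right
stimulus directions. The SSD tracks behaviour with a one-up/one-down
staircase in 50-ms steps targeting 50% successful stopping; since no
starting value or bounds are printed for such procedures, we declare
0.25 s start and [0, 0.9] s bounds. The tracker reacts only to observed
behaviour: a trigger-failed stop trial that produces a response moves the
SSD down like any failed stop, and no-go trials (fixed 5-ms nominal delay)
do not move the staircase.

The default group hyperparameters (`group_hyperparams()`) describe a
plausible older-adult cohort: mean go RT near 0.59 s and mean SSRT near
0.16 s — matching the magnitudes this literature reports — with a clearly
slower mismatching racer so that choice error rates land at a few percent
(a cohort generated with a mismatch racer close to the match racer
produces chance-level 2AFC accuracy and fails the standard behavioural
inclusion rules, which is not what the task produces in practice), a
trigger-failure rate around 7% and a go-failure rate around 1–2%.

What the generator does *not* emulate: RT autocorrelation and fatigue
drifts, within-trial dependence between racers, scanner-related censoring,
or strategic slowing after stop trials. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to the many ways real
data violate them.

## Brainstem phantoms and CNR extraction

The contrast-to-noise ratio of a voxel $v$ against a reference region in
the central pons is

$$CNR = \frac{v - \mathrm{Mean}_{REF}}{\mathrm{SD}_{REF}},$$

computed voxelwise (`cnr_map()`); it is invariant to affine intensity
rescaling of the volume. Segmentation marks voxels exceeding the reference
mean by more than 5 reference SDs (`segment_lc()`); individual binary
masks average into a probabilistic atlas (`build_atlas()`), thresholded at
5% (sensitive) or 25% (conservative) probability — the comparison is
inclusive ($\ge$), one of several conventions the source material leaves
unstated. The thresholded mask is split into caudal/middle/rostral thirds
by z slices (`split_subregions()`), with the convention that when the
occupied slice count is not divisible by three the extra slices go to the
middle subregion first, then the rostral. Mean CNR is reported for the
whole structure — a single pooled-voxel mean across both hemispheres, not
a mean of hemisphere means — and per subregion. SNR has no universal
definition in this context; we report mean raw subregion intensity divided
by the reference SD and flag it as a declared convention. The z axis must
run inferior to superior; `read_oriented_nifti()` refuses volumes whose
orientation metadata cannot confirm this.

`make_phantom()` builds test volumes with two ellipsoidal LC regions, a
pontine reference cuboid, additive Gaussian noise, and per-subregion
intensity offsets expressed in reference-SD units, so the true subregion
CNR equals the configured offset. Since the contrast definition is
invariant to intensity scale and offset, Gaussian noise is sufficient: the
noise family affects only the variance of the estimates, not the
extraction logic. For a noisy phantom to be self-consistent the declared
reference SD should equal the noise SD (the pipeline does this); the
noiseless phantom is used where exactness matters.

## The inferential layer

All regressions enter age (the moderator) and the focal predictor
mean-centred before forming their product, preventing artificial
collinearity with the main effects; sex is a 0/1 covariate left uncentred.
LC contrast is first residualized on age (`residualize()`) so that
moderation findings are over and above the mean age effect on the LC
itself. `fit_moderated_regression()` reports per-term partial
$\eta^2 = t^2/(t^2 + df)$ (the source material writes $\eta^2$ without
qualification; partial is the common convention for individual regression
terms), variance inflation factors with a warning above 10, and Cook's
distances against the 4/n rule-of-thumb cutoff. `robust_regression()`
refits the same design by Huber M-estimation (tuning constant 1.345, MAD
scale), the standard confirmation against outlier-driven results.

### Bayes factors

`jzs_bf()` computes default Bayes factors for nested linear models under
the Jeffreys–Zellner–Siow prior: standardized effects receive a Zellner
g-prior with an inverse-gamma(1/2, $nr^2/2$) mixture over $g$, integrated
numerically in one dimension on the log scale (each model against the
intercept-only model; the ratio gives full vs null). The default scale is
$r = \sqrt{2}/4$ for regression terms and $\sqrt{2}/2$ for the one-sample
test in `paired_bayes_ttest()` — the "medium" defaults of the standard BF
software, which names but does not print them. `subregion_model_comparison()`
mirrors the fallback analysis used when the three subregion interaction
terms are too collinear to share one model (VIF > 10): for each subregion,
the model with that subregion's CNR × age interaction is compared against
the same model without the interaction.

### Moderated mediation

`moderated_mediation()` implements the "model 15" configuration: with
predictor X (age-residualized LC CNR), mediator M (preSMA–rIFG
connectivity), outcome Y (SSRT) and moderator W (age, mean-centred in
products),

$$M = a_0 + a_1 X, \qquad
Y = b_0 + c_1 X + b_1 M + b_2 MW + c_2 XW + gW,$$

optionally with covariates in both equations (the source material does not
say which equation carried them; both is the conservative default, and the
placement is configurable). The index of moderated mediation is
$a_1 b_2$; its confidence interval comes from case-resampling bootstrap
(5000 resamples by default; percentile intervals; rank-deficient resamples
are redrawn and counted; a two-sided bootstrap p is reported as
$2\min\{P(\mathrm{index}^* \le 0), P(\mathrm{index}^* \ge 0)\}$, one of
several constructions since the published analyses do not state theirs).
Conditional indirect ($a_1(b_1 + b_2 w)$) and direct ($c_1 + c_2 w$)
effects are reported across the observed moderator range with bootstrap
bands. A "proportion moderated" is offered under a declared convention
(moderated share of the conditional indirect effect one SD of W above its
centre) because no defining formula is in general use.

`simulate_mediation_dataset()` generates covariate tables from this exact
path model with known coefficients (ages uniform on 50–88, X standard
normal, SSRT residual SD 0.05 s, defaults giving a detectable moderated
mediation around n = 150–200), recording the true index. The test suite
verifies the calibration of the percentile interval at n = 200 over 200
seeded replicates under the null (zero moderated paths). Percentile
intervals for products of coefficients are known to run a little below
nominal coverage; treat intervals near the boundary with care.

### Power

`regression_power()` returns the achieved power of a regression
coefficient test from the noncentral F distribution with noncentrality
$\lambda = f^2 n$; the worked value for the design of interest
($f^2 = 0.15$, $n = 63$, five predictors, $\alpha = 0.05$) is 86%.

## Pipeline

`run_all()` chains simulate → preprocess/QC → fit → phantom-CNR → analyze
from one `run_config()`, with every stage seeded, stages communicating
only through files in the output directory, MD5 hashes of every output in
the run report, and a halt-with-partial-report on the first stage error.
Identical configurations reproduce byte-identical tables. The interface of
the package is its R functions (plus `scripts/acceptance.R` for the
reproduction run); we deliberately ship no shell entry point, since the
intended users work in R.

## Numerical choices and limitations

* Quadrature: adaptive integration at $10^{-8}$ for user-facing
  probabilities; 16-node two-panel Gauss–Legendre inside the sampler
  (absolute likelihood error around $10^{-3}$ per cohort, negligible
  against posterior spread, and configurable via `gl_nodes`).
* The ex-Gaussian density and CDF are computed fully in log space and are
  stable for $\sigma/\tau$ ratios of at least $10^{-2}$–$10^{2}$; the
  compiled kernels use an asymptotic normal log-CDF below $z = -37.5$.
* Desk-scale problem sizes used by the test suite and acceptance script: 8
  participants × 480 trials for recovery (24 chains, adaptive burn-in up
  to 3500 iterations, 250 retained per chain), 200 mediation replicates at
  n = 200 with 1000 bootstrap resamples, phantoms of 48×48×30 voxels.
  These sizes give stable checks in minutes on a single core; real
  analyses should scale chains and retention up to the defaults.
* R-hat is the classic (non-split) Gelman–Rubin statistic to match the
  convention of the toolbox family; split-chain variants are stricter.
* The synthetic cohort draws participants independently; there is no
  between-parameter correlation at the group level, matching the
  independent-normals group model but not necessarily real populations.
* Mediation inference is associational; nothing here identifies causal
  directions.
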