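---
title: "Models and methods behind eeanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eeanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

eeanet links n-back task behavior to large-scale brain network activation
through the *efficiency of evidence accumulation* (EEA): the mean drift rate
of a diffusion decision model (DDM) fitted to a person's choices and response
times. This vignette documents the models, the numerical choices, the
synthetic cohort generator, and the design decisions that were genuinely
open, in enough detail that a maintainer can judge (and, where needed,
revisit) each one.

## 1. The behavioral model

### Parameterization

Each load condition (0-back, 2-back) gets its own 8-parameter DDM:
three stimulus-class drift rates `v_target`, `v_novel`, `v_lure`
(evidence units per second), boundary separation `a` (evidence units),
non-decision time `t0` (s), the width `st0` of uniform between-trial
non-decision-time variability (s), relative start point `z` (fraction of
`a`), and a contaminant-omission probability `p_contam`. The within-trial
diffusion coefficient is fixed at 1 — a pure scale convention that the model
needs to be identified; drift and boundary estimates are only comparable
across studies that share it. Between-trial drift variability (`sv`) and
start-point variability (`sz`) are deliberately absent: they are poorly
recoverable at 80 trials per condition, and the model is used for
individual-differences measurement, not for error-RT asymmetry modeling.

Accuracy coding is used throughout: the upper boundary is defined as the
*correct* response for every stimulus class ("match" for targets, "nonmatch"
for novels and lures), so each class's drift is interpretable as that class's
signal quality toward the correct response. EEA per condition is the mean of
the three class drifts; `eea_mean` averages the two conditions.

### Likelihood with censoring and contaminants

A trial with an observed response at time `rt` contributes
`(1 - p_contam) * E[f_b(rt - t0')]`, where `f_b` is the Wiener
first-passage density at the boundary implied by accuracy coding and `t0'`
is uniform on `[t0, t0 + st0]`. The expectation is a 10-node Gauss-Legendre
quadrature, validated in the test suite against adaptive integration at
relative tolerance 1e-6. An omission contributes the mixture

```
P(omit) = p_contam + (1 - p_contam) * P(T_decision + T_nondecision > window)
```

with a 2-s response window. The mixture-with-censoring form is a design
decision of this package: omissions can arise either from a process outside
the diffusion race (attention lapses; the contaminant component) or from the
race simply not finishing inside the window (the censoring component). Both
must be present — a pure-censoring model cannot produce omissions from
subjects with fast parameters, and a pure-contaminant model would force
`p_contam` to absorb deadline effects and bias the drifts.

### Numerics

The first-passage density uses the classic small-time and large-time series
with the automatic switching rule that picks whichever representation needs
fewer terms at tolerance 1e-10 on the unit-scale density. The boundary CDF
is obtained by composite 20-node Gauss-Legendre integration of that density;
panels grow geometrically from the natural time scale of the early density
spike (the squared distance of the start point to the nearer boundary), so
sharp peaks when the start point sits close to a boundary are resolved. The
survival function used inside the likelihood comes from the analytic
exponential tail series; when `|v| * a * max(z, 1 - z) > 18` the series
suffers catastrophic cancellation between sine terms and the code falls back
to the integrated-density route. Because the CDF and the survival function
are computed by *independent* numerical routes,
`P(correct) + P(error) + P(omission) = 1` is a genuine numerical check, not
an identity; the test suite verifies it to 1e-6 over a 1000-point random
parameter sweep (observed error is ~1e-14).

### Simulation

Trials are simulated by Euler-Maruyama stepping of the diffusion at
`dt = 1e-4` s with a Brownian-bridge correction: within each step the exact
conditional crossing probability `exp(-2 d0 d1 / dt)` is evaluated for both
boundaries. Plain Euler at this step size has an O(sqrt(dt)) first-passage
bias (effectively widening each boundary by about `0.58 * sqrt(dt)`), which
would be of the same order as the package's own density-vs-simulator
equivalence tolerance (Kolmogorov-Smirnov distance < 0.005 at one million
passages); the bridge correction removes that bias while keeping the same
time grid, and is the package's chosen simulation scheme. The path loop uses
a local xorshift128+ generator with polar Box-Muller normals, seeded from
R's RNG stream, so results remain reproducible under `set.seed()`. Bulk
cohort synthesis uses `dt = 1e-3` (the bridge correction makes the remaining
discretization error negligible relative to between-subject variation);
oracle comparisons use `dt = 1e-4`.

### Behavioral exclusions

Response times below 200 ms are removed trial-wise *first* (they are fast
guesses, and counting them as errors would contaminate the accuracy
criterion); then a subject is excluded if, in either condition, accuracy
over non-omitted trials falls below 55% or the omission rate over all trials
exceeds 25%. The two criteria use different denominators on purpose:
accuracy is a property of committed choices, omission rate of the whole
trial schedule.

## 2. Bayesian estimation

Each subject's 16 parameters are estimated jointly by
differential-evolution MCMC with `3 x n_free` interacting chains.
Proposals are classic DE jumps, `x + gamma (x_r1 - x_r2) + e`, with a
randomized subspace crossover (each chain updates a random subset of
coordinates, `gamma = 2.38 / sqrt(2 d_sel)`, occasionally `gamma = 1` for
mode hopping). Two further mechanisms matter in practice:

* during warm-up only, a migration step lets a random ring of chains adopt
  each other's states (Metropolis-accepted), which quickly absorbs
  stragglers from the over-dispersed prior initialization;
* before sampling begins, a Gaussian is moment-matched to the late warm-up
  population and *frozen*; during sampling each iteration uses, with
  probability 0.5, independence-Metropolis proposals from that Gaussian
  instead of DE jumps. Because the proposal is frozen, the sampling kernel
  is a fixed, valid MCMC kernel; the independence jumps break the
  random-walk autocorrelation that otherwise keeps the split-chain rhat
  above 1.1 at practical round lengths. If a round fails the rhat check,
  the Gaussian is re-frozen from that round's draws and another round is
  run (only the final round is ever reported, so the reported draws always
  come from a fixed kernel).

Rounds of 500 kept iterations are repeated until every free parameter's
split-chain rhat falls below 1.1, up to 5 rounds (split-rhat behaves like
sqrt(1 + tau/n) at integrated autocorrelation time tau, so the round length
is sized at roughly six times the observed tau); a fit that never converges
is retained but flagged, and downstream analyses exclude flagged fits by
default. `p_contam` is sampled on the logit scale (with the Jacobian) to
respect its `[0, 0.5]` bounds. Priors with `lower == upper` pin a parameter
exactly, which the tests use to verify the prior machinery end to end.

### Informative priors

The shipped priors (`default_priors()`) were generated by the package's own
prior-emulation run: 300 synthetic subjects drawn from the default
population, fitted individually under broad priors, all posterior draws
pooled per parameter, and a truncated normal fitted to each pool by maximum
likelihood (`emulate_priors()`). Pooling individual posteriors stands in
for a group-level hierarchical fit, which is out of scope; the pooled
distribution mixes posterior uncertainty with population spread and some
residual under-mixing of the broad-prior fits, all of which *widen* the
resulting priors — a conservative direction for an informative prior.
Truncation bounds (drifts in [-10, 10], `a` in (0, 10], `t0` in
[0.05, 1] s, `st0` in [0, 1] s, `z` in (0.1, 0.9), `p_contam` in [0, 0.5])
cover plausible human RT regimes with room to spare. `scale_priors(p, 1.5)`
reproduces the conventional widening used when transporting priors to a
population that may differ from the prior-generation sample.

## 3. The synthetic cohort generator

The generator exists to give every pipeline stage data with *known* ground
truth. It emulates the statistical structure the analyses assume — not the
physiology.

**Task schedule.** Per condition: 8 blocks of 10 trials, exactly 2 targets
and 2-3 lures per block (the lure count drawn uniformly), remainder novel,
order randomized within block; 80 trials per condition, 2-s response window.

**Behavioral population.** Class drifts within a condition share a single
per-subject efficiency deviation; its two condition values correlate at 0.45,
with family and site components (fractions 0.3 and 0.1 of SD) and a
covariate channel (fraction 0.3, loading mostly on motion, negatively).
Population means put the 0-back near 95% accuracy and the 2-back near
85-90%, with mean RTs of roughly 0.6-0.75 s and a few percent omissions —
the regime of a healthy developmental cohort. Collapsing the three class
drifts onto one condition-level factor is deliberate: it makes the planted
correlation between activation and EEA exact rather than attenuated by
class-specific noise, at the cost of not modeling class-specific individual
differences (which nothing downstream consumes).

**Activation model.** Activation is generated at parcel level (400 parcels
labeled into the Yeo-7 networks) rather than at the ~91k-grayordinate level,
for desk-scale speed; the prediction module is agnostic to column count.
For network `n` and condition `c` the standardized network signal is

```
u(n,c) = r(n,c) * zEEA + g(n) * G + s * Site + f * Family
         + sqrt(1 - r^2 - g^2 - s^2 - f^2) * noise
```

where `zEEA` is the standardized covariate-free latent EEA, `G` is a
subject-level "general activation" factor shared across conditions, and
`g(n)` is chosen so the cross-condition correlation of the network signal
equals its planted `rho_cross`. Parcel values add a network baseline, a
nuisance-covariate effect, and parcel noise. Three structural facts follow
by construction and drive everything downstream: (i) the correlation of
`u(n,c)` with EEA equals the planted `r(n,c)`; (ii) condition signals
correlate positively through `G`, site, and family; (iii) `G`, site, and
family cancel exactly in the 2-0 contrast — which is why the load contrast
is the cleaner predictor of EEA, the phenomenon the quadrant and decile
analyses visualize. The default preset plants the divergent pattern
(task-positive networks: 2-back positive, 0-back negative; somatomotor
reversed) at the magnitudes of the published child-cohort network table,
and is documented as a *target of the generator, not a result*.
`implied_load_r2()` gives the closed-form population R-squared of the load
contrast for EEA implied by a specification (a rank-one-plus-diagonal
identity), and `calibrate_activation_r2()` rescales all planted correlations
by a common factor to hit a target R-squared exactly.

What the generator does **not** emulate: spatial autocorrelation within
networks (parcel noise is i.i.d.), hemodynamics and GLM estimation (maps are
generated directly at the contrast level), stimulus-category effects, and
any nonlinearity in covariate effects. Passing tests therefore demonstrate
that the *statistical machinery* behaves as claimed under the planted
structure — not that real cortical data satisfy that structure.

## 4. Prediction: cross-validated PCR with partial correlation

The predictive model is principal-components regression with
nuisance-covariate handling via cross-validated partial correlation. Per
outer fold: features are centered on training means (no per-feature
scaling — activation features share units); K principal components are
extracted from training rows; the component count K is chosen by a nested
5-fold cross-validation *inside the training data only*, scored with the
same partial-correlation metric as the outer loop (self-consistency), ties
broken toward smaller K; component expressions and the outcome are each
regressed on the covariate design (intercept, age, age squared, sex,
dummy-coded race/ethnicity, motion, motion squared) and the training betas
residualize both training and test data; OLS on residualized training
components yields prediction weights; the fold score is the Pearson
correlation between predictions and residualized outcome in the held-out
fold. Fold correlations are averaged unweighted. The candidate grid is
{5, 10, 25, 50, 100, 250, near-full-rank} intersected with feasibility.

Fold schemes: leave-one-site-out (fold = site) or k-fold with families
assigned whole to folds (greedy balancing of subject counts). The family
constraint is the conservative default even for single-site designs, since
sibling pairs otherwise leak across folds; it can be bypassed by passing
singleton family IDs.

Consensus maps multiply each fold's component loadings by its prediction
betas and sum over components, giving one weight per feature; per-fold maps
are averaged and the result z-scored for reporting. Averaging fold maps
(rather than refitting on the full sample) is the default because it
summarizes exactly the models whose out-of-sample performance was measured;
`consensus_feature_map()` on a single full-sample model provides the other
reading.

## 5. Network association statistics

Network means are unweighted means over member parcels per contrast.
All variables of interest are residualized on the covariate design before
correlation; correlations are Pearson throughout.

**Clustered bootstrap.** Confidence intervals resample *sites* with
replacement, keeping each drawn site's families and members intact, and take
percentile intervals (2000 replicates by default). Resampling the top-level
cluster only is the standard consistent scheme for nested dependence; the
two-stage variant that additionally resamples families within drawn sites
is available (`stages = "site-family"`) but is not the default, because in
coverage simulations on clustered data with known correlation the two-stage
scheme over-covers (~99% at nominal 95%) through the extra resampling
variance, while site-level resampling lands near 94%. Replicates with
degenerate variance are redrawn, with an error if more than 1% degenerate.
The coverage simulations use 40 sites of 5 two-person families — sized so
the site-resampling bootstrap operates in its asymptotic regime while
staying desk-scale.

**Comparisons and summaries.** `bootstrap_diff_ci()` computes
`|r1| - |r2|` inside each shared replicate, for comparing the load contrast
against single-condition predictors. `network_regression_compare()` fits
OLS of residualized EEA on a network subset (default FPN/DAN/SMN) and on
all seven networks, reporting observed-vs-fitted correlations with
clustered CIs (models refitted within every replicate).
`decile_bin_summary()` ranks subjects by EEA, splits them into 10
near-equal bins (remainder spread over the lowest bins), and reports bin
means with normal-theory 95% intervals plus the OLS slope of bin means on
bin rank — the slope is fitted on bin means, matching the binned
visualization it supports, not on subject-level data.
`quadrant_summary()` z-scores 0-back activation, 2-back activation, and
EEA, fits the regression of 2-back on 0-back, and crosses
above/below-the-line with 0-back above/below its mean; the upper-left
quadrant holds the "flexible adapters" (more 2-back activation than their
0-back level predicts), and their mean EEA exceeding the lower-right
quadrant's is the planted signature the tests check.

## 6. Problem sizes and determinism

The validation suite uses: a 1000-point parameter sweep for normalization;
five parameter sets with one million simulated passages each for the
density-simulator equivalence (KS < 0.005, about twice the pure sampling
band at that n); 50 subjects at 80 trials per condition for EEA recovery
(recovery correlation at least 0.8, at least 95% of fits converged); 100
confounded-null cohorts of 500 subjects and 100 features for null
calibration (mean out-of-fold partial r within 0.04 of zero); one cohort of
2000 subjects with planted population R-squared 0.36 for signal recovery
(mean cross-validated r in [0.5, 0.7] — the square root of 0.36 attenuated
by estimation noise); 300 clustered datasets for bootstrap coverage
(92-98%); and a 4000-subject preset cohort for the sign-pattern,
decile-slope, and quadrant checks. These sizes were chosen as the smallest
at which each check's Monte-Carlo error is comfortably inside its
acceptance band. Every stochastic step takes an explicit seed; a fixed seed
reproduces trial tables, fits, folds, and bootstrap replicates exactly
within one build.

## 7. Known limitations

* Individual-level fits only; no hierarchical shrinkage across subjects
  (the prior-emulation pooling is a documented stand-in).
* The activation generator is linear-Gaussian with i.i.d. parcel noise; it
  reproduces the three phenomena the analyses rely on (divergent EEA
  correlations, positive cross-condition correlation, cluster structure)
  and nothing else.
* The broad-prior reference fits used for prior emulation mix slightly
  slower than informative-prior fits; residual under-mixing widens the
  pooled priors, which is conservative but means the shipped priors should
  not be read as a precise posterior summary of the reference cohort.
* Percentile CIs (not BCa); with site-level resampling these sit near 94%
  empirical coverage at 40 sites, slightly below nominal.
* The quadrant divider and bin-slope conventions follow the visualization
  they support; alternative conventions (subject-level slope fits, medians
  instead of means) are not implemented.
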