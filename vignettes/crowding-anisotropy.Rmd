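---
title: "Methods: simulating and analysing crowding-anisotropy training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing crowding-anisotropy training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdaniso)
```

This vignette documents the generative model, the analysis chain, the
parameter choices that matter, and the package's numerical and design
decisions. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The behavioural model

A trial presents a Landolt C at fixed eccentricity with two flanking rings
along either the radial or the tangential axis, at one of five
target–flanker spacings $s \in \{0.75, 1.25, 1.75, 2.25, 2.75\}$ degrees
(method of constant stimuli). The observer reports the gap direction
(4AFC). Accuracy follows the cumulative-normal psychometric model

$$P(\text{correct} \mid s) = \gamma + (1 - \gamma - \lambda)\,
  \Phi\!\left(\frac{s - \mu}{\sigma}\right),$$

with guess rate $\gamma = 0.25$ fixed by the 4AFC design and lapse rate
$\lambda \in [0, 0.06]$. The *critical spacing* (extent of the crowding
zone along the flanker axis) is the spacing at which accuracy reaches the
68% criterion; it has the closed form
$s^* = \mu + \sigma\,\Phi^{-1}\big((0.68 - \gamma)/(1 - \gamma - \lambda)\big)$.
Note the spacing range quoted for the design ("0.75° to 3° in 0.5° steps")
cannot land on 3°; the generator uses the five levels above and exposes
them in `study_config()`. The criterion is applied on the raw
proportion-correct scale (not a guess/lapse-corrected scale); since the
fitted curve is evaluated on the same scale, the identity
$P(s^*) = 0.68$ holds exactly either way.

### Fitting

`fit_psychometric()` aggregates trials to per-level binomial counts
(equivalent to the per-trial Bernoulli likelihood) and maximises the
likelihood over $(\mu, \log\sigma, \lambda)$ with `nlminb` under box
constraints ($\lambda \le 0.06$; $\sigma$ bounded well away from 0 and
above by four times the spacing range). A coarse grid of
$(\mu, \sigma)$ values is scored first and the optimiser is started from
the three best grid points; ties are broken by log-likelihood, then by
smaller $\sigma$. No prior or penalty beyond the box constraints is used —
an earlier design with a lapse prior was rejected because it biases $\mu$
on clean data.

The convergence flag is honest: data at chance at every level, all-correct
or all-incorrect data, estimates at a parameter bound, and optimiser
failures are all reported as `converged = FALSE` with boundary estimates,
never as a silent success. A fitted critical spacing at or below zero
degrees (possible when an observer's true threshold lies far below the
lowest tested level, so the fit extrapolates) is likewise returned as
missing. The orchestration layer drops subjects with any flagged cell and
says so; at the default trial counts this affects roughly one subject per
cohort or fewer.

## 2. The observer population

`sample_observers()` draws per-subject parameters from truncated normals
(lower bound 0.1°, upper bound twice the group mean). Group means follow
the study endpoints: pre-training critical spacing 2.16° radial / 1.61°
tangential, post-training 1.46° / 1.05°. The quoted dispersions (0.20,
0.15, 0.13, 0.11°) are used directly as **between-subject SDs**. They
could alternatively be read as SEMs (implying SDs $\sqrt{17}$ times
larger), but that population would place many observers outside the
0.75–2.75° constant-stimuli range — unmeasurable by the design that
produced the numbers — and a design-time check showed badly biased
tangential recovery under that reading. The SD reading is the only one
consistent with the measurement procedure.

Radial elongation is enforced by redrawing a pre-training pair until
$C_{r,\text{pre}} \ge C_{t,\text{pre}}$ (a mild truncation; it shifts the
realised means by well under one group SE).

Training is summarised by a latent per-subject **gain** $g_i$
(mean 1, SD 0.35, truncated to $[0.1, 1.9]$):

* radial shrinkage: $C_{r,\text{post}} = C_{r,\text{pre}} - g_i\,\Delta_r$
  with $\Delta_r = 0.70°$ (the configured mean pre–post difference);
* tangential shrinkage uses
  $g_{t,i} = 1 + \kappa\,(g_i - 1) + \varepsilon_i$, with
  $\kappa = 2$ (`coupling_kappa`) and independent noise
  $\varepsilon_i \sim N(0, 0.15)$, applied to $\Delta_t = 0.56°$;
* day-by-day thresholds interpolate exponentially,
  $C(d) = C_\text{post} + (C_\text{pre} - C_\text{post})
  e^{-(d-1)/\tau}$ with $\tau \sim N(1, 0.3)$ days truncated positive, so
  day 1 is exactly $C_\text{pre}$. The exponential shape is the
  generator's choice; the source only constrains the endpoints and a
  decreasing day-by-day mean.

Post-training values are clamped to stay positive and not exceed the
pre-training value, so learning never worsens performance in this world.

### Why $\kappa$ exists, and its value

A single gain scaling both axes *equally* nearly cancels in the anisotropy
index $A_\text{psy} = (C_r - C_t)/(C_r + C_t)$: the between-subject spread
of $\Delta A_\text{psy}$ it induces (~0.008) is smaller than the
threshold-estimation noise on the same quantity (~0.02), so the
behaviour–BOLD correlation would be diluted to ~0.1–0.3 regardless of how
cleanly the BOLD arm is measured. (An early variant with an *independent*
tangential gain even makes the correlation negative, because radial
learning alone moves $A_\text{psy}$ and $A_\text{BOLD}$ in opposite
directions.) $\kappa$ tilts the tangential shrinkage to covary
super-linearly with the common gain, which is what makes
$\Delta A_\text{psy}$ a usable per-subject signal. The default
$\kappa = 2$ (together with `gain_sd = 0.35` and the scanner noise below)
was calibrated once, by design-time Monte Carlo on seeds disjoint from
every test seed, so that the coupled replicate-level Spearman correlation
at $n = 17$ is near 0.5 — the order of the published effect this design
was built to detect. It was not adjusted afterwards.

### A known inconsistency in the stated endpoints

The endpoint group means imply a pre-training ratio of means
$2.16/1.61 = 1.34$ and a post-training $1.46/1.05 = 1.39$, while the
narrative reports the mean radial/tangential *ratio* decreasing from 1.42
to 1.18. Both cannot hold (mean of ratios ≠ ratio of means, and the
implied within-subject covariance is not available). The generator follows
the endpoint means; consequently its group-mean $A_\text{psy}$ and ratio
change are near zero or slightly positive rather than negative. The
coupling analysis is unaffected — rank correlation uses per-subject
deviations, not the group mean direction.

## 3. The BOLD model

Each run alternates 16-s fixation and stimulation blocks (9 + 8; TR = 2 s;
136 volumes), each stimulation block carrying one of the four conditions
(radial/tangential × target present/absent), each condition twice per run
in random order; 8 runs per session.

The condition response model is shared verbatim between the generator and
the design matrix: a 0/1 boxcar convolved with the gamma-variate HRF

$$h(t) = \left(\frac{t - \delta}{\tau}\right)^{\alpha}
 e^{-(t - \delta)/\tau}, \quad t \ge \delta,$$

sampled at the TR and normalised so the convolved regressor has unit peak.
With $\delta = 2.25$ s, $\tau = 1.25$ s, $\alpha = 2$ the kernel peaks at
$\delta + \alpha\tau = 4.75$ s. These parameters are described in the
source toolkit's vocabulary as a "cumulative gamma"; the impulse response
implemented is the gamma variate above — an actually cumulative
distribution function never returns to baseline and cannot serve as an
HRF. Unit-peak normalisation makes betas live in signal units, so percent
signal change is simply $100\,\beta_c/\beta_0$; the alternative (unit-area
kernels) was rejected because it makes PSC depend on block length.

The generated signal is

$$y(t) = B\Big(1 + \textstyle\sum_c \frac{a_c}{100}\, x_c(t)\Big)
 + b\,(t - \bar t) + \eta(t),$$

with baseline $B = 1000$, condition amplitudes $a_c$ in PSC units, linear
drift $b = 0.05$ units/volume, and stationary AR(1) Gaussian noise
($\phi = 0.3$, SD 3 — a temporal SNR of ~330, at the optimistic end of a
multi-voxel ROI average; chosen jointly with the coupling calibration
above). Because generator and GLM share $x_c(t)$, the zero-noise round
trip is exact to numerical precision — that identity is a test, not an
assumption, and with noise the OLS estimates are unbiased (also tested).

Default amplitudes encode the qualitative pre/post pattern: pre-training
radial present 0.60 / absent 0.90 ($C_\text{BOLD,rad} = -0.30$, crowding
suppression), tangential present 0.95 / absent 0.75 ($+0.20$,
enhancement); post-training radial 0.90 / 0.86 ($+0.04$, suppression
released), tangential 0.92 / 0.78 ($+0.14$). They are configuration, not
ground truth. When coupling is on, an observer's post-training *radial*
amplitudes interpolate between the configured pre and post values with
weight $g_i$, so subjects who learn more release more suppression; with
coupling off an independent gain replaces $g_i$, which severs the
behaviour–BOLD association while leaving every marginal distribution
intact. A post-training decrease of the radial target-absent response is
present in the default configuration only as the small 0.90 → 0.86 step;
the source observes (without explaining) such a decrease, and the
generator makes no attempt to model a mechanism for it.

Per-run GLMs (intercept, mean-centred linear drift, four condition
regressors) are fitted by OLS and betas averaged across runs; fitting the
concatenated session with per-run nuisance columns is available behind
`concatenate = TRUE`. There is no prewhitening and no high-pass filter
beyond the linear drift: the AR(1) noise in the generator tests the
estimator's robustness, not its optimality, and OLS with temporally
correlated noise remains unbiased (its p-values are not used — inference
happens at the group level on per-subject summaries).

## 4. Group statistics

`rm_anova()` implements the classical univariate within-subject
decomposition (margin-totals inclusion–exclusion; each effect tested
against its effect × subject interaction), for 1–3 within factors with
exactly one observation per subject × cell. No sphericity correction is
applied by default, matching integer-df reporting conventions;
Greenhouse–Geisser is available behind `gg_correction = TRUE`. No
multiple-testing correction is applied anywhere, matching the analysis
being emulated; this is a reporting choice, not a recommendation.

`spearman_cor()` uses midranks. The two-sided p-value is exact by full
enumeration for $n < 8$, Monte-Carlo permutation for $n$ of 8–9, and the
$t$ approximation $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ for $n \ge 10$ (so the
study-size case $n = 17$ uses the same approximation as standard
software). Degenerate inputs (zero variance) yield flagged undefined
results rather than errors; the same policy applies to zero-variance
paired t-tests and all-constant ANOVA tables.

The tests verify the engine against independent routes: `aov()` with
`Error()` strata, an explicit projection-matrix oracle, a brute-force
permutation enumerator, $10^5$ sign-flip permutations for the paired t,
and Kolmogorov–Smirnov uniformity of null p-values.

## 5. Orchestration, seeding, reproducibility

A single master seed fans out to per-stage child seeds through a
counter-based linear-congruential map (`child_seed()`), so the observer
draw, the trial noise, and every BOLD run have independent but
reproducible streams, and any stage can be rerun alone. `run_simulate()`
writes raw data plus a manifest (configuration snapshot, seed, MD5 of
every output); re-running with the same configuration and seed reproduces
identical bytes. `run_replicate()` runs the full chain and writes
`report.json`/`report.md`; any stage failure aborts with the stage named,
preserving files already written.

## 6. What a green test establishes — and what it does not

The generator emulates the *statistical structure* the analysis assumes:
binomial 4AFC outcomes on a monotone psychometric curve, block-design BOLD
with HRF dynamics, AR(1) noise and drift, endpoint-anchored learning
curves, and a latent-gain coupling between arms. It does not emulate:
sequential/order effects within a session (trial order is exchangeable),
eye movements or fixation breaks, image-space fMRI (no voxels, motion, or
registration — ROI-averaged series only), non-stationary or physiological
noise spectra beyond AR(1)+drift, asymmetric learning-curve shapes, or any
mechanism for the unexplained post-training change in the radial
target-absent response. Green acceptance tests therefore establish that
the implementation correctly recovers what this generative world contains
at the study's scale — not that the real experiment's conclusions are
correct, and not that the analysis would be robust to artefacts this world
cannot produce.

Known limitations: the behavioural recovery criterion inherits a small
selection effect from dropping (rare) non-converged fits; extrapolation
beyond the tested spacing range is noisy by construction; and the
coupling-strength default is a calibrated quantity (Section 2), so worlds
with much weaker coupling will show proportionally weaker correlations.
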