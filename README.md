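# crowdaniso

Simulation and analysis of training-induced changes in the
radial–tangential anisotropy of visual crowding.

## The scientific problem

Visual crowding is the breakdown of object recognition in peripheral
clutter: a target (here a Landolt C whose gap orientation must be reported,
4AFC) becomes unidentifiable when flanking rings fall within a *critical
spacing*. Crowding is anisotropic — flankers placed **radially** (along the
line from fixation) interfere over larger distances than **tangential**
flankers, so the interference zone is a radially elongated ellipse.
Perceptual training shrinks this zone, mostly along the radial axis, and
the BOLD response of early visual cortex mirrors the change: before
training, adding a target to radial flankers *suppresses* the ROI response,
and training releases that suppression.

The package provides a fully seeded generative model of such a training
study and the complete analysis chain, so every stage is testable without
any data download:

* **Psychophysics.** 17 observers, 4 training days, method of constant
  stimuli (spacings 0.75°–2.75° in 0.5° steps), 337 trials per flanker
  axis per day (1348 per condition in total). Accuracy follows the 4AFC
  cumulative-normal model
  `P(correct | s) = γ + (1 − γ − λ) Φ((s − μ)/σ)` with guess rate
  `γ = 0.25`. Maximum-likelihood fitting recovers the critical spacing,
  defined as the 68%-correct point, `s* = μ + σ Φ⁻¹((0.68 − γ)/(1 − γ − λ))`.
  The behavioural anisotropy index is `A_psy = (C_r − C_t)/(C_r + C_t)`.
* **fMRI.** Block design: 8 stimulation + 9 fixation blocks of 16 s
  (TR = 2 s, 136 volumes per run), four stimulus conditions
  (radial/tangential × target present/absent), 8 runs per session, sessions
  before and after training. Regressors are boxcars convolved with the
  gamma-variate HRF `h(t) = ((t − δ)/τ)^α e^{−(t − δ)/τ}`
  (δ = 2.25 s, τ = 1.25 s, α = 2), fit by OLS; percent signal change is
  `100·β_c/β_intercept`. The BOLD crowding index per axis is
  `C_BOLD = R_Tp − R_Ta` and the anisotropy index
  `A_BOLD = (C_BOLD,rad − C_BOLD,tan)/(R_Ta,rad + R_Ta,tan)`.
* **Group statistics.** Paired t-tests, classical repeated-measures ANOVA
  (2×4 on critical spacing, 2×2×2 on PSC, uncorrected df), and the Spearman
  rank correlation between per-subject changes in `A_psy` and `A_BOLD`,
  which the generator couples through a latent per-subject training gain.

## Worked example

```r
library(crowdaniso)
report <- run_replicate(seed = 1, outdir = "crowdaniso-out")
print(report)
```

At seed 1 this simulates the full study (one subject is dropped because one
of its 136 psychometric fits is flagged non-converged) and prints, among
other sections:

```
## Behaviour: day-by-day mean critical spacing (deg)
| axis | day 1 | day 2 | day 3 | day 4 |
|---|---|---|---|---|
| radial | 2.195 | 1.743 | 1.616 | 1.577 |
| tangential | 1.616 | 1.266 | 1.205 | 1.157 |

### 2 (axis) x 4 (day) repeated-measures ANOVA on critical spacing
| effect | df | F | p |
|---|---|---|---|
| axis | (1, 15) | 45.67 | 6.44e-06 |
| day | (3, 45) | 57.30 | 2.09e-15 |
| axis:day | (3, 45) | 9.51 | 5.57e-05 |

## Behaviour-BOLD coupling
Spearman correlation of anisotropy-index changes: rs = 0.362, n = 16, p = 0.169
```

Reading: critical spacings start near 2.2° (radial) / 1.6° (tangential) and
shrink with training toward 1.5°/1.1°; the radial advantage (main effect of
axis) and the learning curve (main effect of day) are both strong, and the
axis × day interaction reflects the larger radial improvement. The final
line is the behaviour–BOLD coupling estimate for this realisation;
replicate-level `rs` is stochastic (mean ≈ 0.5 under the default coupled
generator — individual seeds vary widely at n = 17).

`run_simulate(seed, outdir)` writes the raw synthetic data instead
(trial CSV, one CSV + JSON sidecar per BOLD run, and a `manifest.json` with
MD5 hashes; identical seed and configuration reproduce identical bytes).
A command-line front end with `simulate` / `replicate` subcommands is
installed at `inst/cli/crowdaniso.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/crowdaniso.R", package="crowdaniso"))')" \
    replicate --seed 1 --outdir out
```

Configuration is a YAML file mirroring `default_config()` (all study,
observer-population and scanner parameters), passed via `--config`.

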