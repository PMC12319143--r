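# stopreach

Analysis toolkit for studies of **late-stage inhibitory control measured
from 3D hand trajectories** — immersive reach-to-grasp stop-signal tasks in
which participants reach for food or neutral objects, occasionally receive
a stop signal after movement onset, and whose biometric stopping behaviour
is then related to ad-libitum food intake (kcal). It is written for
researchers in movement-based cognition and eating behaviour who need the
full measurement chain as tested, reusable code.

## What it computes

**Direct stopping parameters** from per-trial trajectories (120 Hz): after
centring and segmenting each trial from stimulus onset to the earliest
attainment of maximal depth displacement, the package extracts peak
velocity and acceleration (PV, PA) with their times, maximal approach
displacement (maxZ), initiation time, and — on stop trials — the direct
stopping latency **TTS = t(maxZ) − stop-signal onset**, the braking
distance **BD = x₁(maxZ) − x₁(stop onset)**, and stop success. Gaze enters
as per-sample area-of-interest collisions, summarised as first and total
dwell times with single-frame dropout bridging.

**Indirect stopping latency** from web-based stop-signal sessions by the
integration method with replacement of response omissions:

> SSRT = *n*th fastest go RT − mean SSD, with *n* = ⌈p(respond | stop) · N_go⌉,

withheld when p(respond | stop) ∉ [0.25, 0.75] or when signal-respond RT
exceeds go RT (race-model violation).

**Implicit chocolate approach** as the single-category IAT D-score
(improved-algorithm conventions; negative D = faster avoidance pairing).

**Group statistics**: paired t with Cohen's *d* = *t*/√*n*, 2×2
repeated-measures ANOVA (Category × Trial-type) with
η²ₚ = *F*·df₁/(*F*·df₁ + df₂), Pearson correlations with intake.

**Intake prediction**: OLS, elastic net (α grid 0.1–0.9) and Lasso on the
standardized 16-predictor set, hyperparameters selected by 5-fold
cross-validated MAE with fold-wise standardization; `intake_fit()` returns
a classed object with `print`, `summary`, `coef`, `predict` and `plot`
methods.

**Synthetic cohorts with ground truth**: minimum-jerk reaches
(x₁(t) = D(10τ³ − 15τ⁴ + 6τ⁵)) with an adaptive stop-signal-delay
staircase, gaze streams, race-model web sessions, SC-IAT sessions, and
intake from a known sparse linear model — so every stage is testable
against known truth without any data download.

## Worked example

```r
library(stopreach)

cfg <- study_config(rng_seed = 42)        # 72 participants, 400 VR trials
ft  <- generate_feature_table(cfg)        # participant-level features + truth
fit <- intake_fit(ft$features, seed = 42)
print(fit)
#> Intake prediction fits (n = 72, 16 predictors, 5-fold CV)
#>   ols         in-sample MAE  143.8 kcal, out-of-sample  197.9 kcal, 16 feature(s)
#>   elastic_net in-sample MAE  151.7 kcal, out-of-sample  171.9 kcal, 12 feature(s) (alpha = 0.1, lambda = 83.7)
#>   lasso       in-sample MAE  154.3 kcal, out-of-sample  173.3 kcal, 6 feature(s) (alpha = 1.0, lambda = 17.7)
```

The OLS fit memorises (low in-sample, poor out-of-sample MAE); the
penalized fits generalise better, and only the Lasso produces a sparse
model — here 6 of 16 predictors. The category effect on peak velocity
(slower reaches toward chocolate) is detected by the within-participant
ANOVA:

```r
rm_anova_2x2(ft$cell_means, value = "pv")
#>                effect        F df_num df_den        p  eta_p2  n
#> 1            category  37.0523      1     71 5.27e-08 0.34291 72
#> 2          trial_type 229.3774      1     71 6.22e-24 0.76363 72
#> 3 category:trial_type   0.0966      1     71 7.57e-01 0.00136 72
```

F is the ANOVA statistic with its degrees of freedom, p the two-sided
p-value, and η²ₚ the proportion of effect-plus-error variance attributable
to the effect. For the full per-sample chain use `run_pipeline()` (or the
CLI at `inst/cli/stopreach.R` with subcommands `simulate`, `extract`,
`gaze`, `score-sst`, `score-iat`, `stats`, `fit`, `run-all`), which writes
every stage artifact plus a digest manifest; identical config and seed
reproduce identical digests.

See `vignettes/stopreach-methods.Rmd` for the models, their assumptions,
parameter defaults, and known limitations.

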