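---
title: "Measuring late-stage inhibitory control from reach trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring late-stage inhibitory control from reach trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopreach)
```

## The measurement problem

Late-stage inhibitory control is the ability to cancel an action that has
already been launched. The classical stop-signal task measures it
*indirectly*: a covert stop process races an overt go process, and the stop
latency (SSRT) is inferred from go reaction times, stopping probabilities,
and stop-signal delays. Immersive reach-to-grasp stopping tasks measure it
*directly*: a participant reaches for a 3D target (here a chocolate or a
neutral object), a stop signal is issued after the movement has started
(the dynamic starting line), and the continuously recorded hand trajectory
shows exactly when and where the arm came to rest.

`stopreach` implements the full measurement-and-analysis chain for such
studies: a synthetic cohort generator with known ground truth, per-trial
biometric parameter extraction, gaze dwell analysis, scoring of the two
web-based control tasks (stop-signal task and single-category implicit
association test), group-level inference, and penalized-regression
prediction of ad-libitum chocolate intake in kcal. Because participant
recordings from such studies are rarely redistributable, the generator is a
first-class, tested component: every downstream stage can be validated
against the generator's ground truth without any data download.

## The synthetic cohort

### Reach kinematics

Go reaches follow a minimum-jerk profile along the depth axis $x_1$,

$$x_1(t) = D\,\bigl(10\tau^3 - 15\tau^4 + 6\tau^5\bigr), \qquad
  \tau = \frac{t - \mathrm{IT}}{T},$$

where $D$ is the object depth (default 0.5705 m), $\mathrm{IT}$ the
initiation time and $T$ the reach duration. The minimum-jerk model was
chosen because it is the standard smooth point-to-point model in motor
control and admits closed forms that serve as independent oracles: the
peak speed is $1.875\,D/T$ at $\tau = 1/2$ and the peak of the speed
derivative is $(10/\sqrt 3)\,D/T^2$. A small lateral arc (2 cm) and a net
height rise (4 cm; the start position sits below the target) make the path
genuinely three-dimensional, and Gaussian positional noise (default
SD 1 mm per axis and sample at 120 Hz) emulates tracker jitter.

On stop trials the stop signal is scheduled at $\mathrm{IT} +
\mathrm{SSD}$. The depth velocity then decays linearly to zero over the
trial's stop latency $L$, so the braking distance is $v_0 L / 2$ with
$v_0$ the depth velocity at signal onset. The stop *succeeds* when the
hand halts before entering a 2 cm collision radius around the object —
consistent with movements that terminate a couple of centimetres short of
the target — otherwise the reach completes (failed stop). The SSD follows
an adaptive staircase (start 200 ms, steps of 50 ms). A classical
staircase converges to 50% stopping success; dynamic-starting-line VR
tasks empirically yield much higher success, so the staircase is bounded
at [50, 260] ms, which places cohort-level success near 70–76% while
preserving per-participant variation (roughly 50–100%). The bound was
chosen by simulating the closed-form success condition over the latent
participant distribution.

### The latent participant model

Each participant carries latent means for reach speed (hence $T$),
initiation time, VR stop latency, web-task go RT and stop latency, gaze
dwell, implicit-association effect, and questionnaire scores. Population
means and between-participant SDs were set to the descriptive level
reported for normal-weight female high chocolate cravers in this paradigm
(e.g. peak velocity 2.11 ± 0.28 m/s, stopping latency 260 ± 62 ms, web
SSRT 320 ± 65 ms, D-score −0.14 ± 0.22). Category effects are additive
chocolate-minus-neutral shifts applied to reach speed (default −0.02 m/s),
stop latency (−13 ms), and dwell times (+107 / +216 ms); slower, more
controlled reaching toward chocolate with faster stopping and longer
looking. Candidates are drawn from a wider population and screened exactly
as the recruitment rules demand (trait-craving score strictly above the
pilot median of 37, BMI 18.5–29.9 kg/m², age 18–35, right-handedness
score above 50), so the screening stage is exercised, not assumed.

### Intake

Ad-libitum chocolate intake is generated from a known sparse linear model
over the 16-predictor feature set:

$$\mathrm{kcal}_i = \beta_0 + \sum_j w_j\, z\bigl(f_{ij}\bigr) +
  \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

floored at 0 kcal. Defaults: intercept 529 kcal, three nonzero weights of
60 kcal/SD on trait craving, (negative) web SSRT in chocolate trials, and
total chocolate dwell, and $\sigma = 206$ kcal — chosen so the linear
signal explains roughly $R^2 \approx 0.2$ of an intake distribution with
an SD near 230 kcal, the regime in which feature selection is genuinely
hard but not hopeless. The true weights are recorded in the ground truth,
so support recovery by the Lasso is a testable claim rather than an
anecdote.

### Two generation modes

`generate_cohort()` produces full per-sample trajectories, gaze streams
and web-task trial tables. `generate_feature_table()` samples the same
latent participant model but returns participant-level quantities directly
(true features, measured features with trial-averaged extraction noise,
2×2 cell means). Simulation studies that only need participant-level data
(Lasso support recovery over 20 replications, ANOVA power) use the feature
path; trajectory-level validation (kinematic oracles, stopping-parameter
recovery, pipeline determinism) uses the trial path at small cohort sizes
(8 participants × 400 trials, or 500 standalone stop trials). These
problem sizes keep each check in the seconds-to-a-minute range while
leaving the estimates stable across seeds.

## Trajectory preprocessing and parameters

Each trial is centred to its first sample and segmented from stimulus
onset to the *earliest* attainment of the maximal depth displacement (the
first movement phase, before grasping or return movements). Degenerate
trials without forward displacement keep all samples; trials with fewer
than three samples are flagged unusable.

Movement initiation is the linearly interpolated time at which 3D
displacement first exceeds 1 cm. The original task's exact displacement
threshold is not public; 1 cm is a configurable default, and detected
initiation times therefore carry the analytic threshold-crossing lag of
the minimum-jerk profile (about 60 ms at study-typical speeds), which the
tests account for explicitly.

Speed is the magnitude of the central-difference derivative of the
(smoothed) position vector; acceleration is the derivative of the speed
series — a *change in speed*, not the acceleration-vector magnitude, which
matches the biometric parameter definitions. Positions are smoothed with a
centred 5-sample moving average before differentiation; at 120 Hz this
attenuates the minimum-jerk peaks by well under 1%, and the millimetre
tracker noise biases extracted peak velocity by under 2% at study-typical
speeds. Peak acceleration is less forgiving: double differentiation
amplifies noise, so absolute PA values on noisy data sit above the
noise-free truth. Within-study contrasts (chocolate vs. neutral) are
unaffected because the bias is common to both conditions, but absolute PA
should not be compared across recording setups.

Per-trial parameters follow the standard biometric definitions: PV/PA and
their times, maximal depth displacement (maxZ), trial RT (time of the
segment's last sample), and for stop trials the direct stopping latency
TTS = t(maxZ) − stop-signal onset, the braking distance BD =
x₁(maxZ) − x₁(stop onset), and the success flag ACC (the hand never
entered the collision radius). TTS and BD are aggregated over successful
stop trials only. With positional noise, the plateau after the halt means
the argmax lands a few tens of milliseconds into the plateau; noiseless
recovery is exact to within one sample period, and the noisy-case bias is
again condition-common. Aggregation applies a single-pass 2.5 SD outlier
filter per participant × category × trial-type cell and variable (sample
SD, n−1; zero-SD cells remove nothing) before averaging; cells with fewer
than 5 usable trials are flagged.

Time-standardised trajectories (101 points by default, linear
interpolation) are provided for averaging and plotting; kinematic peaks
are always computed on the unstandardised recordings.

One deliberate omission mirrors the deviation such studies report: SSRT is
*not* estimated from the VR task, because the adaptive starting procedure
makes stopping success far exceed the 25–75% band the integration method
requires. The VR task contributes direct measures only.

## Gaze dwell

Gaze enters as per-sample boolean collisions between the gaze vector and
the stimulus area of interest. The initial dwell is the first contiguous
hit-run (ending at the first detachment); total dwell sums all hit-runs;
dropouts of at most one sample (configurable) are bridged into the
surrounding fixation. Whether the first dwell must start exactly at
stimulus onset is ambiguous in the field's definitions; by default leading
misses are allowed before the first fixation, and `from_onset_only = TRUE`
switches to the stricter reading.

## Scoring the control tasks

**SSRT (integration method with omission replacement).** Go omissions are
replaced with the maximum observed go RT; go RTs are sorted; the estimate
is the $n$th go RT minus mean SSD with $n = \lceil p \cdot N_{go} \rceil$
clamped to $[1, N_{go}]$, where $p$ is the probability of responding on a
stop trial. The ceiling convention gives deterministic tie handling.
Estimates are withheld when $p \notin [0.25, 0.75]$ or when the mean
signal-respond RT exceeds the mean go RT (race-model violation). SSRT is
computed separately per stimulus category; go choice errors are retained
with their RTs by default (configurable).

**D-score.** The single-category IAT contrasts chocolate + approach
(compatible) with chocolate + avoidance (incompatible) test blocks. The
improved-algorithm conventions are adopted: trials above 10 s dropped;
participants with more than 10% of trials under 300 ms, or overall
accuracy below 70%, rejected; error RTs replaced by the block's
correct-RT mean plus 600 ms; D = (incompatible − compatible mean) divided
by the pooled SD of all correct-plus-penalised RTs across both test
blocks. Negative D means the avoidance pairing was answered faster. The
exact variant used by any given study's supplement may differ in details
(practice-block inclusion, penalty); every threshold is exposed in
`sciat_rules()` and the defaults are documented choices, not
reproductions.

## Inference

Paired comparisons use dependent-sample t-tests with Cohen's
$d = t/\sqrt{n}$ (mean difference over the SD of differences) — the
convention that reproduces printed effect sizes from their $(t, n)$ pairs.
The 2×2 within-participant ANOVA (Category × Trial-type) is fitted with
classical error strata; in a 2×2 design each effect's F equals the squared
paired t on the corresponding difference contrast, and the test suite
verifies this equivalence to 1e−8 against an independently computed
oracle. Effects carry partial eta squared,
$\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$. Correlations with
intake are Pearson product-moment coefficients with pairwise deletion
(matching the varying dfs such studies report); the ANOVA uses listwise
deletion. No multiplicity correction is applied (conventional
$\alpha = 0.05$).

One reported-value caveat: a dependent-sample $d$ of 0.13 alongside
$t(64) = 0.75$ is not consistent with $d = t/\sqrt n$ (which gives 0.09);
the package reproduces only the self-consistent conversions.

## Intake prediction

`intake_fit()` fits three models to predict intake (kept in kcal so MAE is
interpretable) from the standardized 16-predictor set: OLS, elastic net
with the mixing parameter selected over $\alpha \in \{0.1, \dots, 0.9\}$,
and the Lasso ($\alpha = 1$). The penalty path is 50 log-spaced values
from the null-model penalty down by a factor of $10^{-4}$. Hyperparameters
are selected by K-fold (default 5) cross-validated mean absolute error
with a fixed fold seed; standardization is recomputed inside each training
fold and applied to the held-out fold, so no test information leaks into
the scaler. The reported out-of-sample MAE is the mean held-out MAE at the
selected hyperparameters; the in-sample MAE is measured on the full data.
Complete-case analysis: participants with any invalid or missing predictor
(rejected D-score, withheld SSRT, empty kinematic cell) are excluded
before fitting. Exactly collinear predictors are tolerated in OLS (aliased
columns get zero weight).

Numerical notes: the elastic-net and Lasso paths come from coordinate
descent on pre-standardized predictors (`standardize = FALSE`), so weights
are directly on the kcal-per-SD scale; at vanishing penalty the
elastic-net weights agree with OLS to under 1e−4 on well-conditioned
problems, and along the Lasso path the active set grows monotonically as
the penalty decreases (both verified in tests).

## What the synthetic validation does and does not show

Passing tests establish that the chain is *internally correct*: the
extraction recovers what the generator put in, the scoring algorithms
agree with hand-worked and brute-force oracles, selection recovers a known
sparse signal at realistic noise, and the pipeline is bit-reproducible
under a fixed seed. They do not establish that real hands move like
minimum-jerk profiles with linear stop decay, that real gaze dropouts span
a single frame, or that real intake is linear in the predictors. Known
idealisations: trial clocks restart at stimulus onset (no inter-trial
structure is modelled); gaze is generated directly as collision booleans
(no saccade physiology); the trial-level stop model halts earlier in the
reach than the feature-level stop-point summary assumes, so the two modes'
`maxz` scales differ; and absolute PA on noisy data exceeds the noise-free
truth as discussed above.

## Reference problem sizes

The acceptance computations use: a single noiseless minimum-jerk trial
(D = 0.6 m, T = 1 s, 120 Hz) for the closed-form peaks; 500 noiseless
stop trials for TTS/BD/maxZ recovery; 10 replications of a 400-trial
race-model session for SSRT recovery; 20 replications of the 72-participant
feature table for Lasso support recall and MAE; and an 8-participant ×
400-trial full cohort (run twice) for pipeline determinism and the
stop-success rate. Each was chosen as the smallest size at which the
corresponding estimate is stable to well within its stated tolerance.
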