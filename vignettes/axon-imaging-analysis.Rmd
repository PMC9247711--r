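---
title: "Quantifying frontal-axon activity during visual discrimination: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying frontal-axon activity during visual discrimination: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axontools)
```

This vignette is the package's account of the science it implements: the
models and procedures, the assumptions behind them, the parameters that
matter, what the synthetic data generator does and does not emulate, and
the numerical decisions taken where the underlying methods left room.

## The experimental setting

A head-fixed mouse performs a go/no-go visual discrimination: a brief tone
(0.1 s) announces a trial, the grating appears 1 s after tone onset and
drifts for 4 s, and the animal is rewarded for licking during the 2–4 s
window after go-stimulus onset. Licks in the first 2 s are disregarded
(animals lick impulsively at stimulus onset), false alarms trigger an
airpuff and a 10 s timeout, and trials are separated by a 2–10 s quiescent
period that restarts if the animal licks. Meanwhile, a two-photon
microscope images fluorescent calcium indicator signals from axonal
boutons — the synaptic varicosities of long-range frontal-cortex axons —
in layer 1 of V1 at ~10 Hz. Separately, passive sessions present drifting
gratings at 8 directions while axons (green channel) and V1 somas (red
channel) are imaged together.

The scientific questions the statistics serve: are these axons recruited
by the task, does their activity track behavioral or neural
discrimination accuracy, and is the activity better explained by licking
and reward?

## ΔF/F and trace pre-processing

Raw fluorescence `F` is converted to `ΔF/F = (F − F0)/F0` with `F0` the
5th percentile of the smoothed trace within a 20 s window centered on each
sample (truncated at session edges). The slow percentile baseline tracks
drift (bleaching, slow focus changes) while ignoring transients, which for
a slow indicator like GCaMP6s can last seconds.

Decisions where the procedure is underdetermined:

- *Smoothing before the percentile.* A 1 s centered boxcar (`smooth_s`,
  default 1 s). Mild smoothing stops single-frame noise minima from
  dragging the percentile down; 1 s is short against the 20 s window.
- *Baseline floor.* `F0` is clamped at `1e-3 ×` the trace median. Real
  fluorescence has a positive offset, so the floor should never engage;
  if it does, the ROI is flagged (`floored` attribute) rather than
  silently producing huge ratios. The clamp threshold scales with the
  trace, so ΔF/F remains exactly invariant to multiplicative gain (in
  exact arithmetic; floating point leaves ulp-level residue, and the tests
  check equality at 1e-12).
- *Percentile definition.* Type-7 sample quantiles, matching R's default,
  so the implementation can be checked against an independent brute-force
  recomputation to 1e-12.

Boutons on the same axon show near-identical calcium signals, so boutons
with trace correlation above 0.7 are combined. Grouping uses the
transitive closure (connected components) of the `r > 0.7` graph — "same
axon" is an equivalence relation, so if A goes with B and B with C, all
three are one axon even if `r(A, C)` is lower. Correlation is computed on
ΔF/F, not raw F, so shared baseline drift cannot create spurious merges;
members are combined by a pixel-count-weighted average (larger ROIs
contribute proportionally more). A zero-variance trace has no defined
correlation; it stays a singleton and is flagged. Merging is idempotent.

Dual-color experiments risk red-channel signal bleeding into the green
detector. The QC regresses each ROI's green trace on its red trace (OLS)
and reports per-ROI slope and R² plus the fraction of positive slopes and
the mean R²; bleed-through is negligible when the mean R² is well below
0.01 even if slopes skew positive.

## Task modulation

Per trial, the *within* activity is the mean ΔF/F from the trial-onset
tone to stimulus offset; the *between* activity is the mean over the final
2 s of the immediately preceding quiescent period, and only when that
window contains no lick ("properly executed") — this guarantees a
comparison window free of licking behavior. Trials failing the no-lick
requirement, or lacking frame coverage, drop out of the paired set.

Each bouton gets a two-sided paired t-test (within vs between) at
p < 0.01 and a task modulation index
`TMI = (mean within − mean between)/(mean within + mean between)`: +1
means active only inside trials, −1 only between them. With nonnegative
activity TMI is confined to [−1, 1]; strongly negative ΔF/F can push it
outside, in which case the value is reported as-is and flagged — clipping
would hide a pathology worth seeing. The test is two-sided because the
classification is bidirectional (increased/decreased/ns).

Event-triggered responses (tone, go stimulus, no-go stimulus, reward,
airpuff) compare mean ΔF/F in the 0.5 s before onset against the 1 s
after, one-sided for increases, with Benjamini–Hochberg correction across
boutons within each event type and a flag at adjusted p < 0.05. Windowed
means, not a deconvolution GLM, are used deliberately: with a slow
indicator and this trial structure, windowed contrasts are the
transparent, assumption-light choice.

## Behavioral accuracy and the correctness model

`d′ = qnorm(hit rate) − qnorm(false-alarm rate)`. Rates of exactly 0 or 1
make the quantile infinite; the default policy replaces them with
`1/(2n)` and `1 − 1/(2n)` using the relevant trial counts (a log-linear
Hautus adjustment is available, and `"none"` returns the infinite value
with a warning). The sliding version computes rates and d′ over 20-trial
windows stepped by one trial, dropping windows that lack either trial
type.

The correctness model is, per bouton, an OLS fit of per-trial activity on
`correct` (0/1), `trial_type` (go = 1), and their interaction — ordinary
treatment coding, with coefficient t-tests and BH adjustment across
boutons per coefficient. Gaussian identity-link OLS is exactly what a
default GLM fit reduces to. The activity window is selectable (full
trial, 1 s post-tone, first 2 s of stimulus, pre-trial 1 s, response
period) because supplementary analyses probe event-window-specific
effects; `previous_correct` swaps in the preceding trial's correctness to
test post-error effects. Rank-deficient designs (e.g. a session with no
incorrect trials of one type) skip the bouton with a recorded reason. The
correct modulation index `CMI = (R_c − R_i)/(R_c + R_i)` comes from
condition-mean activity.

The d′-activity association is assessed per session by a least-squares
line of windowed population ΔF/F on sliding d′, then a two-sided
one-sample t-test on the per-session slopes.

## Licking, reward, and hemispheric targeting

The lick rate is the count of licks in a centered 1 s window around each
frame time — a sliding sum over the binary lick raster. Because ΔF/F and
lick rate are both autocorrelated, a naive correlation p-value would be
wildly anticonservative; significance instead comes from a circular-shift
permutation null: the lick-rate trace is circularly shifted 1,000 times by
a uniform random offset of at least 10 s in either direction (whole
frames, both directions folded into one circular index), preserving the
autocorrelation of both series while destroying their alignment. A bouton
is significant when its observed correlation exceeds the 95th percentile
of its own null. The criterion is one-sided by construction; boutons with
`r > 0.2` are additionally labelled "highly lick-correlated". The
permutation p-value is reported as `(1 + #{null ≥ obs})/(n_perm + 1)`,
bounded away from zero as a permutation p must be.

Rewarded licking is compared with unrewarded licking within go trials:
rewarded periods run from reward delivery to stimulus offset (the 2–4 s
response window means reward always lands inside the stimulus), and
unrewarded periods are the initial 2 s of the stimulus, where licking is
common but never rewarded. Only periods actually containing a lick
contribute — the comparison is between licking states, not between epochs.
Because rewarded licking is longer and more rhythmic than unrewarded
licking, a frequency- and count-matched comparison restricts to lick
*bouts*: at least 3 licks, the first three within 0.5 s, preceded by ≥1 s
of silence, analyzing only the first three licks of each bout. The bout
window is half-open at the start and closed at the third lick so the
third lick's frame is always included; "within 0.5 s" is strict, matching
the package-wide half-open convention.

In the bilateral task variant the reward targeting index
`RTI = (C_reward − I_reward)/(C_reward + I_reward)` quantifies whether
reward-period activity is biased toward the hemisphere processing the
stimulus; the population test is a two-tailed one-sample t against zero.
In the generator, the hemispheric gain `g` multiplies only the
reward-coupled component on contralateral trials, which makes the analytic
recovery target `(g − 1)/(g + 1)` exact for reward-dominated boutons.

## Passive tuning

Responses are mean ΔF/F over 1 s post-onset, per presentation.
Responsiveness is a one-way ANOVA over all stimulus conditions at
p < 0.05. Direction tuning is modeled as
`R(θ) = offset + A1·G(θ − θp) + A2·G(θ − θp − 180°)` with a shared
Gaussian width in wrapped angular distance, amplitudes constrained
nonnegative, and the preferred direction `θp` fixed at the empirically
largest mean response — the "preferred stimulus" is an empirical notion,
and freeing θp with only 8 directions invites degeneracy. Fitting uses
bounded Levenberg–Marquardt (with a bounded quasi-Newton fallback for
degenerate geometries such as an exactly vanishing second peak, where LM's
step can fail); σ is bounded to [3°, 180°]. Start values: `A1` from the
response range, `A2` from the response opposite the peak, σ = 30°, offset
at the minimum. OSI and DSI are evaluated from the *fitted* curve —
`OSI = (R_pref − R_ortho)/(R_pref + R_ortho)` at θp vs θp + 90°, and
`DSI` at θp vs θp + 180°.

Design choices here: the 8 grating "orientations" are treated as 8
directions spanning 360° (orientation = direction mod 180°), without
which DSI is meaningless; the position grid is collapsed by taking each
neuron's best position (largest mean response) before direction fitting,
since receptive-field coverage, not position tuning, is what the grid
exists for.

The activity split ranks presentations by the concurrent axon-population
mean (same 1 s windows), cuts at the median (order-based, so the halves
differ by at most one presentation and the split is deterministic), fits
each half separately, and retains neurons that are responsive with fit
R² > 0.3 in both halves. OSI (and DSI) distributions are compared with a
Kruskal–Wallis test, and the change in preferred direction is reported
per neuron.

## Pupil geometry

Twelve landmarks per frame: four eyelid corners (medial, lateral,
superior, inferior) and eight points around the pupil. The eye shape is
the region between two parabolas through (medial, superior, lateral) and
(medial, inferior, lateral). The parabolas are constructed in a rotated
frame whose abscissa is the medial→lateral axis — in image coordinates a
tilted eye would make "a parabola through the two corners" ill-posed.
Sanity checks invalidate a frame entirely (all pupil markers discarded):
the medial marker must be strictly medial of the lateral one (coordinates
are Cartesian with y up; medial has the smaller x), the superior marker
strictly above the corner chord, the inferior strictly below; collinear
configurations give a zero-height contour and are invalid. Pupil markers
on or outside the boundary are discarded — during blinks the landmark
network still places markers, and they land outside the collapsed eye
shape.

With ≥6 valid markers an ellipse is fitted by direct algebraic least
squares with the ellipse constraint (`4AC − B² = 1`), after centering the
markers for conditioning: a closed-form, deterministic fit appropriate to
"minimize the least-squared error" read algebraically. With 5 or fewer
markers the fit abstains — never extrapolate a conic from too few points.
The reported diameter is the major-axis length, and eye velocity is the
frame-to-frame ellipse-center displacement over Δt, left missing across
invalid frames.

## The synthetic session generator

The generator produces sessions with the statistical structure the
analyses assume, plus the ground truth needed for recovery tests.

*Task and agent.* The trial clock follows the defaults quoted above. The
agent licks on go trials with probability `hit_rate` (default 0.8) and on
no-go trials with `fa_rate` (default 0.2) — values typical of a trained
animal at d′ ≈ 1.7; rewarded bouts are rhythmic at `reward_lick_freq`
(default 7 Hz, matching the observation that rewarded licking is
typically > 6 Hz) lasting 1–2 s; unrewarded and impulsive licking are
short 2–4 lick bursts; sparse spontaneous licks fill the intertrial
periods. Optionally the hit/fa rates follow a bounded logit-scale random
walk (`accuracy_drift_sd`) to create the slow within-session accuracy
fluctuations that the sliding-d′ analyses need.

*Bouton traces.* Each bouton is a weighted sum of task regressors
convolved with a difference-of-exponentials kernel (rise 0.2 s, decay
1.5 s — a GCaMP6s stand-in; the analyses never model the indicator, but
the traces must show its temporal blurring). Sustained regressors (lick
rate, in-trial, correctness boxcars) are normalized by the kernel mass so
a coupling weight reads as ΔF/F per unit of sustained input; impulse
events (reward, tone, stimulus onsets) use the peak-normalized kernel, so
the weight is the transient's peak. Impulse responses carry multiplicative
per-event amplitude jitter (`response_jitter`, default 0.25), the
trial-to-trial response variability real boutons show; without it,
bouton-level statistics would be unrealistically dominated by the
session-shared regressor structure. Background activity is a Poisson
train of kernel transients plus white noise. By default traces are
emitted as raw fluorescence `F = f_base(1 + signal)` so the ΔF/F stage is
exercised; `emit = "dff"` skips that for analyses that start downstream.

*What it does not emulate:* pixel-level imaging (no movies, no
neuropil), biophysical calcium dynamics and indicator saturation,
correlated noise across boutons beyond shared task structure, eye images
(landmarks only), and reward-prediction or learning dynamics. Passing
recovery tests therefore demonstrates that the analyses measure what they
claim under the stated statistical structure — not that they are robust
to every artifact of real microscopy.

## Calibration and test scale

The test suite checks calibration at the scale the analyses are used at,
chosen so the whole suite runs in about a minute: the permutation-test
specificity uses a ~2,000 s session at 10 Hz with 400 null boutons and
1,000 shifts (the binomial 99% band around 95% is then ±2.8 points); the
paired-test type-I error uses 5,000 null boutons × 250 trials (band
±0.36 points around 1%); the null calibrations of the Kruskal–Wallis
split comparison and the RTI t-test each use 100 replicate simulated
experiments; oracle-equivalence fuzzing uses 1,000 random lick rasters
and over 1,000 random pupil markers. Parameter-recovery checks
(double-Gaussian fits to 1e-3, ellipse fits to 1e-6, ΔF/F against a
brute-force oracle to 1e-12) are run on noiseless constructions where
exactness is meaningful.

## Known limitations

- Windowed-mean event responses cannot unmix events closer together than
  the indicator kernel; that is a property of the method, preserved
  deliberately.
- The TMI and CMI are ratio indices: near-zero denominators (silent
  boutons) make them unstable, which is why degenerate statistics are
  flagged rather than clipped.
- The permutation test is one-sided for positive lick correlations;
  strongly *anti*-correlated boutons are not flagged (their `r_obs` is
  still reported).
- Within one session, boutons share the trial sequence and lick raster,
  so across-bouton tests (e.g. the population RTI t-test) inherit some
  dependence; the generator's per-event response jitter reproduces the
  realistic regime in which bouton-level variability dominates.
- The pupil module post-processes landmarks; it cannot rescue frames
  where the landmark detector failed in ways that keep markers inside a
  plausible eye shape.
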