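---
title: "Methods: reward modulation of superior colliculus subtypes and saccade vigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reward modulation of superior colliculus subtypes and saccade vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Saccades to objects associated with large rewards are more vigorous: they
start earlier (shorter reaction time, RT) and move faster (higher peak
velocity, PV). The superior colliculus (SC) contains functionally distinct
neuron classes — visual, visuomotor, motor, and tonically active units — that
together convert a visual target into a saccade command. `scvigor`
implements an analysis pipeline that asks *where in the sensorimotor
transformation* value signals act: it classifies units, quantifies per-unit
reward modulation, dissects the population response into an early visual
(E~VIS~, 30–80 ms post-target), a late visual (L~VIS~, 80–130 ms) and a
pre-saccadic (Pre~SAC~, beyond 130 ms target-aligned; −40–0 ms
saccade-aligned) epoch with a pseudo-population bootstrap, and correlates
per-neuron value modulation with per-neuron influence on RT and PV.

Because no public recording of this task is available, the package ships a
synthetic-session generator that emulates the study conditions with known
ground truth. Every pipeline stage is tested against that generator, against
closed-form oracles, or against exhaustive enumeration.

# The synthetic-session generator

`generate_session()` produces a complete session: a trial event table,
a continuous 1 kHz eye trace, and spike trains for a configurable number of
units per subtype. The generator's defaults *are* the study conditions; they
are set once from the quantities the analysis is designed to recover and are
not per-experiment dials.

## Behavior

* **Reaction times** are truncated normal draws per value condition
  (good 186 ± 25 ms, bad 211 ± 36 ms) with a 150 ms floor enforced by
  rejection sampling. The floor excludes express-saccade-range latencies,
  which a visually guided single-target task with overtrained animals
  essentially never produces; it also keeps pre-saccadic bursts out of the
  late-visual analysis window, consistent with the epoch timings the
  analysis is meant to exhibit. The quoted RT spreads are treated as trial
  SDs, so the synthetic trial distribution is somewhat wider than a single
  real session's.
* **Amplitude**: targets sit at the receptive field of the recorded
  population, so one eccentricity per session is drawn uniformly from
  4–25°, with 3% per-trial jitter. Across sessions amplitudes are uniform;
  within a session they are nearly constant, which is what makes the
  PV-vs-rate correlation identifiable at all (otherwise amplitude would
  dominate PV variance through the main sequence).
* **Peak velocity** follows the saturating main sequence
  $PV = V_{max}(1 - e^{-A/C})$ with $V_{max} = 870$ deg/s and $C = 8$°,
  calibrated so the across-session mean good-object PV lands near
  740 deg/s, plus a 5% multiplicative bonus on good trials (the value effect
  on saccade execution).
* **Eye traces** are minimum-jerk displacement profiles whose analytic peak
  velocity equals the drawn PV, embedded in a continuous session trace with
  fixation, target hold and return saccades, plus Gaussian positional noise
  (SD 0.005°, the RMS noise of a good video eye tracker). Substantially
  larger noise (e.g. 0.05°) is incompatible with a 30 deg/s detection
  threshold at 1 kHz: differentiation noise alone would then cross the
  threshold continuously. The movement is placed so that its *30 deg/s
  crossing* occurs at the drawn RT — reaction time is defined operationally
  at the velocity threshold, matching what the detector measures.

## Spike trains

Each unit has a rate template `rate_function()` built from four components
on a 1 ms grid:

* a **visual transient** (Gaussian, peak 42 ms post-target);
* a **late visual component**: a mixture of a bump peaking at 106 ms and a
  sustained plateau that rises after the transient and releases after the
  saccade. Visual units are plateau-only; visuomotor units are mostly bump;
  motor units carry a weak prelude bump at 120 ms;
* a **saccadic burst** locked 11 ms before saccade onset, with a sharp rise
  (SD 6 ms) and slower decay (SD 8–9 ms). The asymmetry is deliberate: a
  symmetric burst of realistic width leaks backward into the 80–130 ms
  window on short-RT trials and would pin the late-visual peak at the
  window edge, which contradicts the temporal dissociation the epochs show;
* **tonic suppression**: tonic units start from a 22 spikes/s baseline that
  is suppressed to ~12 spikes/s from ~60 ms after target onset, deepens to a
  trough 33 ms before saccade onset, and recovers after the saccade.

Value modulation is a multiplicative gain on the late and motor components
(divided into the suppression for tonic units) that engages 95 ms after
target onset. The default per-modulated-unit gain is 1.5; each unit draws a
modulation sign from per-subtype proportions (visual 53/23/24%
positive/negative/none, visuomotor 70/12/18, motor 75/4/21, tonic 38/43/19),
so the *population-level* good/bad rate ratios come out near 1.2–1.5 as the
mixture average.

A shared per-trial latent gain $g \sim N(1, 0.15)$ multiplies the late/motor
components of *all* units and shifts the trial RT by
$-2\,(g-1)\,\sigma_{RT}$: trials where the population fires harder are
initiated earlier. This one knob produces the within-condition negative
rate–RT correlation. The gain SD is a calibration: it must be large enough
to carry the coupling but small enough that the mean gain of a ~15-trial
tertile-by-condition cell does not swamp the value contrast; 0.15 (a 15%
trial-to-trial gain CV) satisfies both.

Spikes are drawn by thinning a homogeneous Poisson process against the rate
envelope — exact for bounded rates and directly testable against Poisson
closed forms.

**What the generator does not emulate**: between-session heterogeneity of
templates, bursting/refractory spike statistics, recording artifacts, RF
misalignment across channels, and drift. Passing tests therefore demonstrate
that the *pipeline* recovers what it should under its own assumptions, not
that those assumptions exhaust real SC data.

# Kinematics

`detect_saccades()` computes radial speed from central differences of the
(x, y) trace, smooths it with a 5 ms boxcar, and marks onset/offset where
the smoothed speed rises above / falls below 30 deg/s. Smoothing exists only
for thresholding: peak velocity is measured on the *raw* central-difference
speed with a local quadratic fit (±3 ms around the argmax) plus an
analytic correction for the ±1 ms averaging inherent in central
differencing; without these, narrow velocity peaks are underestimated by
1–4% and single-sample noise is of the same order as the 1% recovery target.
Events whose peak speed exceeds `blink_threshold` are flagged as
blink-contaminated.

The detector default for that threshold is 700 deg/s. At the pipeline level
(`pipeline_config()`) the default is 1200 deg/s: large-amplitude saccades
legitimately exceed 700 deg/s on the main sequence (the mean PV itself is
~740), so a literal 700 cutoff would systematically discard the largest
saccades and bias every downstream statistic toward small amplitudes.

One saccade per trial is selected: the first detected event with RT in
[50, 600] ms; earlier events mark the trial anticipatory, none marks it
no-response. Validity additionally requires post-saccadic gaze within 8° of
the target. Invalid trials are excluded from all downstream statistics.

`normalize_profile()` re-estimates displacement at 20 equally spaced
fractions (5%…100%) of the saccade duration via natural cubic-spline
interpolation and differentiates the interpolant for the velocity profile;
20 points is used throughout (a 21-point "every 5% from 0" grid would be the
other reading; the stated count of 20 wins).

# Spike tools

`sdf()` convolves spikes with a unit-mass Gaussian kernel; *bandwidth means
the kernel SD* (10 ms), not FWHM. The estimate is computed on a span padded
by 6 SD and cropped, so a trial's integral equals its interior spike count
to 1e-6. Analysis windows are half-open `[start, end)` to avoid double
counting. Units enter the analysis only with ≥5 valid trials per condition
and more than 20 spikes in the −300 to +400 ms window around target onset
(the exact counting window is a package choice; nothing else in the
pipeline depends on it).

# Functional classification

`classify_unit()` works on per-trial rates in five windows: baseline
(−200–0 ms), phasic #1 (0–80 ms), phasic #2 (80–160 ms) target-aligned, and
pre- (−100–−50 ms) / peri-saccadic (−50–20 ms) saccade-aligned. A
Kruskal–Wallis omnibus over the five windows (p ≥ α ⇒ no task response) is
followed by pairwise directional rank-sum tests at the same α = 0.05,
deliberately without multiplicity correction (single-α criteria).

Two guards handle rank-test pathologies at low spike counts. First, every
directional call must agree with the direction of the sample means: windows
of unequal duration have different zero-count masses, and a rank test can
otherwise declare the shorter window "significantly below" a baseline of
equal rate. Second, a phasic-1-only reduction counts as tonic only if the
phasic-2 mean is also on the suppressed side — a unit whose phasic-2 is
strongly elevated is not target-suppressed.

Precedence is: tonic first (suppression); then units with visual activation
(both phasic windows above baseline) are visuomotor if the pre-vs-peri
contrast is significant and visual otherwise; a significant motor contrast
with phasic #1 below phasic #2 (and no visual activation) is motor;
everything else is unclassified. This resolves the overlap in the verbal
definitions deterministically.

# Reward modulation

`value_comparison()` compares good and bad trials with a Wilcoxon
signed-rank test on the 80–240 ms rates; pairs are formed at the object
level when at least five objects per condition exist, otherwise (the default
with 4 + 4 objects, where a signed-rank over 4 pairs could never reach
p < 0.05) good and bad trials are paired in chronological order truncated to
the smaller count. The signed-rank test itself (`signed_rank_exact()`)
enumerates all 2^n sign assignments on midrank-tied absolute ranks for
n ≤ 14, so tied differences are handled exactly.

`auroc()` is Mann–Whitney U/(n₁n₂) on the 80–160 ms rates — the probability
that a random good trial out-fires a random bad trial, ties counting ½.
Internally 0.5→1 means positive modulation; a `figure_convention` flag emits
1 − AUROC for displays where values below 0.5 denote positive modulation.
Significance is a label-permutation test (default 1000 permutations,
add-one corrected), deterministic under a fixed RNG state.

`modulation_onset()` thresholds the difference of condition-averaged SDFs at
its baseline (−300–0 ms) mean + 3 SD and requires 20 consecutive
suprathreshold milliseconds. When single-trial data are available the rule
is applied to the difference standardized by its across-trial SE: spike
count variance grows with rate, so a threshold calibrated on the quiet
baseline misreads response-period noise as modulation (on value-neutral
units the raw rule fires ~45% of the time; the standardized rule stays
under 10%). The degenerate all-zero case (zero baseline variance, zero
difference) returns "absent". Negative-going onsets use the mirrored trace.

# Pseudo-population bootstrap

Trials are split into RT tertiles at the empirical 1/3 and 2/3 quantiles
(stable ties, remainders to the earlier groups). One pseudo-trial pools one
random same-tertile trial from each of 25 units drawn with replacement
(per-session subtype counts can be below 25); 25 pseudo-trials per tertile
are averaged per repeat, and the per-epoch extremum time and rate of the
averaged trace are extracted on both alignments — peaks for
visual/visuomotor/motor populations, troughs for tonic. Means and
2.5/97.5-percentile CIs are taken over repeats (10 000 by default; reduced
repeat counts only widen the Monte-Carlo jitter of the summary, not the CI
width itself, which reflects pseudo-trial resampling). Extrema are
extracted per repeat, not from the grand-mean trace — that is what gives
the CIs their meaning.

The open-ended target-aligned pre-saccadic epoch is bounded at 130 ms plus
the median RT of the long tertile, preventing post-saccadic contamination.
Value-conditioned runs (`condition = "good"` / `"bad"`) recompute tertiles
within condition so both conditions contribute comparably to each tertile.

# Behavior-link indices

Per unit: the value index (good − bad mean rate, 80–160 ms), and the RT /
PV indices (Pearson correlation of the 80–160 ms rate with trial RT / PV,
good and bad trials pooled — pooling is what lets per-unit value modulation
express itself as a rate–behavior correlation). Trials need ≥5 spikes in
the window; units need ≥15 such trials, and constant inputs raise an
explicit undefined-correlation error rather than a silent zero.
Cross-neuron `index_correlation()` fits all units with defined indices,
significant or not. `modulation_overlap()` partitions each subtype into the
eight reward × RT × PV significance cells.

Type-I calibration of these indices is meaningful only on units without a
saccade-locked component: a motor burst moving in and out of a fixed window
correlates rate with RT mechanically, whatever the value coupling. The null
tests therefore use visual-subtype units with the value gain and latent
coupling switched off.

# Numerical choices and problem sizes

Tolerances: SDF mass conservation 1e-6 (interior spikes); AUROC equals the
exhaustive pair-count oracle to 1e-12; detector timing ±1 sample against
the analytic Gaussian-speed crossing. Tie-breaks: first index wins epoch
extremum ties; stable sort in the tertile split. Degenerate inputs (flat
traces, zero rates, constant windows) return empty/absent/unclassified
rather than erroring, except where an error is the contract
(undefined correlations, too-few trials).

The shipped tests and the acceptance script use one 200-unit session
(50 per subtype, 56 good + 43 bad trials), 100-unit single-subtype sessions
for onset and null calibrations, and 1000 bootstrap repeats — sizes chosen
so the entire battery runs on a laptop in a few minutes while leaving every
statistical margin wide (classification recovery ~97% against a 90%
requirement, null calibrations within binomial error of α).

# Known limitations

* Template shapes and all generator constants are modeling choices; the
  ground truth in `truth.json` records them with each synthetic session.
* The pipeline analyzes one session at a time; multi-session hierarchies
  (session-level random effects, cross-session pseudo-populations) are out
  of scope.
* The tonic subtype's E~VIS~/L~VIS~ "peaks" are not modeled as distinct
  components; only its suppression dynamics are.
* Motor units' late-window statistics depend strongly on the overlap
  between the burst and the fixed 80–160 ms window; with realistic RT
  distributions this overlap is partial, and the RT-index estimates for
  motor units are correspondingly noisier than for visuomotor units.
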