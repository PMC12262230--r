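# scvigor

Analysis of how reward value modulates superior colliculus (SC) neuron
subtypes and saccade vigor.

When a monkey makes a visually guided saccade to an object it has learned to
associate with a large reward, the movement is more vigorous: reaction time
(RT) drops and peak velocity (PV) rises. The SC contains visual, visuomotor,
motor, and tonically active neurons that jointly convert the visual target
into a saccade command. `scvigor` implements the full analysis chain for
asking *which stage* of that transformation carries the value signal:

* **Kinematics** — saccade detection from 1 kHz eye traces (30 deg/s
  velocity threshold, 700 deg/s blink rejection), RT / PV / amplitude, and
  duration-normalized velocity profiles (20-point grid) for the main-sequence
  relation `PV = Vmax (1 − exp(−A/C))`.
* **Spike tools** — event-aligned rasters, spike density functions (SDF,
  Gaussian kernel with 10 ms SD), half-open window firing rates, and the
  unit inclusion rule (≥5 valid trials per condition, >20 spikes).
* **Classification** — rule-based visual / visuomotor / motor / tonic
  labels from Kruskal–Wallis plus directional rank-sum contrasts across
  baseline (−200–0), phasic 1 (0–80), phasic 2 (80–160 ms) target-aligned
  and pre (−100–−50) / peri (−50–20 ms) saccade-aligned windows.
* **Value modulation** — per-unit good-vs-bad comparison (exact, tie-aware
  Wilcoxon signed-rank on 80–240 ms rates), AUROC = Mann–Whitney
  U/(n₁n₂) on 80–160 ms rates with a permutation test, and modulation-onset
  latency (baseline mean + 3 SD threshold held for 20 consecutive ms).
* **Pseudo-population bootstrap** — RT-tertile split, pooling of one
  same-tertile trial from each of 25 randomly drawn units per pseudo-trial,
  and per-repeat extraction of epoch extrema: early visual (E_VIS,
  30–80 ms), late visual (L_VIS, 80–130 ms) and pre-saccadic (PRE_SAC,
  >130 ms target-aligned; −40–0 ms saccade-aligned), with percentile CIs
  over repeats. Tonic populations are summarized by their pre-saccadic
  trough.
* **Behavior link** — per-neuron value / RT / PV indices (Pearson
  correlations of single-trial 80–160 ms rates with behavior), cross-neuron
  index correlations, and reward × RT × PV overlap counts.
* **Synthetic sessions** — a generator (`generate_session()`) that emulates
  the study conditions (RT distributions per value condition, the main
  sequence, subtype rate templates with a 42 ms visual transient, a 106 ms
  late component, an 11 ms pre-saccadic burst lead and a 33 ms tonic trough
  lead, value gain engaging ~95 ms post-target, and a shared latent gain
  coupling firing rates to RT) with full ground truth for recovery tests.

## Worked example

```r
library(scvigor)

params  <- generator_params(n_units_per_subtype = 10, seed = 42)
session <- generate_session(params)
session
#> <sc_session syn0042: 99 trials (56 good / 43 bad), 40 units, 183.7 s eye trace>

saccades <- session_saccades(session, blink_threshold = 1200)
good <- saccades$valid & saccades$condition == "good"
bad  <- saccades$valid & saccades$condition == "bad"
round(c(rt_good = mean(saccades$rt_ms[good]), rt_bad = mean(saccades$rt_ms[bad])))
#> rt_good  rt_bad
#>     189     216
```

Good-object saccades are initiated ~27 ms earlier. Classify the units and
check against the generator's ground truth:

```r
classes <- classify_session(session, saccades)
table(classes$subtype)
#>      motor      tonic     visual visuomotor
#>         10         10          8         12
mean(classes$subtype == session$truth$units$subtype)
#> [1] 0.95
```

Quantify reward modulation of one visuomotor unit:

```r
u <- session$units[[which(classes$subtype == "visuomotor")[1]]]
raster <- align_spikes(u, session$trials, saccades, "target_on", span = c(-400, 400))
set.seed(1)
unit_modulation(raster)[c("value_index", "auroc", "auroc_p", "sign")]
#> $value_index            $auroc          $auroc_p        $sign
#> [1] 24.5                [1] 0.699       [1] 0.000999    [1] "positive"
```

This unit fires 24.5 spikes/s more for good objects in the 80–160 ms
window; AUROC 0.70 means a random good trial out-fires a random bad trial
70% of the time, and no label permutation reached that separation.

Dissect the population response into epochs:

```r
ids  <- classes$unit_id[classes$subtype == "visuomotor"]
bank <- pseudo_population(session, saccades, unit_ids = ids)
summ <- bootstrap_population(bank, bootstrap_config(n_repeats = 1000, seed = 1))
subset(as.data.frame(summ), select = c(quantile, epoch, alignment, mean_time))
#>    quantile       epoch  alignment mean_time
#> 1     short        evis  target_on     43.48
#> 2    medium        evis  target_on     42.75
#> 3      long        evis  target_on     43.41
#> 4     short        lvis  target_on    109.39
#> 5    medium        lvis  target_on    109.06
#> 6      long        lvis  target_on    105.48
#> 7     short      presac  target_on    160.02
#> 8    medium      presac  target_on    184.09
#> 9      long      presac  target_on    216.93
#> 10    short presac_sacc saccade_on     -9.13
#> 11   medium presac_sacc saccade_on     -9.97
#> 12     long presac_sacc saccade_on     -9.38
```

The two visual epochs peak at fixed latencies (~43 and ~107 ms) regardless
of RT tertile, while the target-aligned pre-saccadic peak moves with RT
(160 → 184 → 217 ms) and collapses to a fixed ~10 ms lead once aligned on
saccade onset — the signature that E_VIS / L_VIS are visual stages and
PRE_SAC is a motor stage.

The whole chain (simulate → saccades → classify → modulate → bootstrap →
indices), with every artifact persisted and byte-reproducible under a fixed
seed, is available as `run_pipeline(pipeline_config(...))`.

See `vignettes/scvigor-methods.Rmd` for the model, assumptions, parameter
choices and limitations.

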