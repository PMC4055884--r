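---
title: "Models and methods behind tailflip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tailflip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailflip)
```

`tailflip` implements the analysis chain of a behavioral nociception assay
in zebrafish — event detection from an impedance biosensor, baseline
normalization, robust summaries, rank-based longitudinal inference, and
simulation-based power analysis — together with a ground-truthed generator
of the data the chain consumes. This vignette explains the models, the
parameter choices, and the limits of what the package's own simulations can
demonstrate.

## The behavioral model

Zebrafish swim in bursts: short bouts of consecutive tail-flips at an
instantaneous rate of 2–5 flips per second, separated by glides. The
generator formalizes this as a marked point process:

* Bout initiations follow a Poisson process with intensity
  `baseline_burst_rate` (default 20 bouts/min — roughly one bout every
  3 s, about 120 flips/min with the default bout size, a typical
  beat-and-glide cadence for adult zebrafish in a small chamber).
* Each bout carries a geometric number of flips (mean 6), and the
  inter-flip intervals inside a bout are drawn uniformly on the reciprocal
  of the 2–5 flips/s rate band, i.e. 0.2–0.5 s.
* A fish has one tail, so bouts cannot overlap: candidate initiations that
  would fall inside an ongoing bout are deferred until it ends (a queueing
  construction). This preserves the nominal bout count at realistic rates
  while guaranteeing that every inter-flip gap is at least 0.2 s, which is
  what makes exact noise-free detection a meaningful benchmark.

Heterogeneity enters at three levels, all lognormal:

* a per-fish baseline gain (CV 0.5) — untreated fish differ severalfold in
  absolute activity, which is why all analysis is performed on normalized
  values;
* minute-to-minute intensity noise within a fish (CV 0.15), the
  within-fish overdispersion beyond counting noise;
* a per-fish post-treatment response multiplier (CV 0.05), fish-level
  heterogeneity in how strongly an individual responds to a treatment.

### Acclimation trend

Fish are more active at the start of a recording session and settle over
tens of minutes. The generator models this as a multiplicative elevation of
the bout intensity, decaying exponentially with a 15-min time constant, with
a per-fish amplitude drawn lognormally (mean 0.65, CV 0.9), and a parallel
inflation of the minute-to-minute noise CV (factor 2 at the start, decaying
with the same time constant). The amplitude was calibrated once, by
simulation of a 27-fish cohort, so that activity over the first 40 min of a
60-min baseline averages about 20% above the median of the last 20 min —
the magnitude of the early decline this assay reports — and the early
across-fish error bars come out severalfold larger than stable-window ones.
These two features are exactly what motivates the stable-window
normalization rule.

### Treatment effect curves

Treatment arms differ only in their effect curve, a function of time since
injection returning a multiplicative activity factor. The shipped presets
use a logistic onset (half-maximal 15 min after injection, 8-min time
scale) to an asymptote: saline 0.80 (controls recover most but not all of
their baseline activity), 5% acid 0.65, 10% acid 0.45 (robust sustained
suppression), morphine 3 mg/kg + acid 0.58, morphine 6 mg/kg + acid 0.70
(the analgesic largely protects activity), morphine + naloxone + acid 0.48
(the antagonist removes that protection, leaving near acid-alone levels).
The 0.70 and 0.80 asymptotes are anchored to levels the assay reports;
the others interpolate the reported ordering. Only the morphine+acid value
is asserted quantitatively by the acceptance checks; the rest shape
qualitative orderings.

## The measurement model and detector

Each flip contributes a biphasic transient (positive then negative half,
zero mean, 40 ms wide) whose sharp central edge carries spectral content
well beyond the 20 Hz needed to resolve flips inside a bout. On top of the
superposed transients the channel adds white Gaussian noise (SD 0.1 of the
unit kernel amplitude), a slow multiplicative gain drift (log-amplitude
0.3, 10-min period), and sporadic artifact spikes (0.5/min, twice the flip
amplitude).

Detection mirrors the biosensor's processing chain:

1. **Band-pass 0.2–40 Hz**, zero-phase so event times are not shifted: the
   spectrum is multiplied by the squared magnitude response of a
   second-order Butterworth high-pass cascaded with an eighth-order
   low-pass — the forward–backward response of that cascade — with
   zero-padding against wrap-around. Choosing the filter order was driven
   by the band edges: at 100 Hz sampling the upper edge (40 Hz) is close
   to Nyquist, and an eighth-order low-pass is the lowest that attenuates
   a 48 Hz tone more than tenfold while leaving 10 Hz untouched.
2. **Automatic gain control**: the trace is divided by its running robust
   scale (MAD over 10-s blocks, interpolated). The gain is floored at 25%
   of the loudest block, capping the correction range at 4× — ample for
   instrument drift, while quiet or noise-free stretches, whose robust
   scale collapses to the filter-ripple level, are not amplified without
   bound. Because the floor scales with the trace, constant rescaling
   cancels exactly.
3. **Sharpness detection**: candidates are local maxima of the absolute
   first difference exceeding an adaptive threshold of 6 running MADs of
   the differenced signal. Six MADs (≈4 Gaussian SDs) is the lowest round
   multiple at which a band-limited pure-noise trace yields well under one
   false candidate per minute; at the default signal-to-noise ratio real
   flips sit several times higher, so recall is not sacrificed. Two
   floors keep noise-free traces exact: 15% of the running high quantile
   of sharpness (rejects filter ringing next to events) and 1% of the
   global maximum (rejects numerical ripple far from events).
4. **Refractory period** 0.15 s (just under the 0.2 s implied by the
   5 flips/s ceiling), resolved greedily in favor of sharper peaks.
5. **Burst context**: real swimming comes in bouts, so an isolated
   candidate with no neighbor within ±1 s is rejected as an artifact —
   unless it is strong (at least twice threshold), since genuine
   single-flip bouts do occur under the geometric bout-size law and are
   unambiguous at that amplitude. The rule removes isolated near-threshold
   noise; strong artifact spikes do survive it, costing about half a
   percent of precision at default rates.

On default-noise synthetic studies this detector achieves per-fish recall
and precision above 0.99 (events matched within ±50 ms), and it is exact on
noise-free renders. Normalization makes the downstream analysis insensitive
to any residual flat detection inefficiency, because it cancels between the
post-treatment counts and the pre-treatment baseline of the same fish.

## Normalization and summaries

The timeline is fixed by the assay protocol: 30 min unrecorded acclimation,
60 min baseline, injection, 30 min unrecorded anesthesia recovery, 80 min
post-treatment recording (so recording ends 110 min after injection).

Each fish's reference is the **median of the last 20 min** of its baseline
(`stable_window()`), the window in which average activity has stabilized;
the window length is exposed as a parameter (the assay's own reporting
wavers between 20 and 25 min). Post-treatment minutes are expressed as
percentages of that median and averaged in 15-min bins (10 min for the
video arm) timestamped by start time since injection; an 80-min recording
at 15-min bins leaves a 5-min remainder, and the trailing partial bin is
dropped with a message. Fish whose baseline median is not positive, or
whose recordings are incomplete, are excluded and reported — the
tested-versus-analyzed distinction.

Group-by-bin summaries use the **20% Winsorized mean**: with
`g = floor(0.10 · n)` per tail, the g smallest values are replaced by the
(g+1)-th smallest and symmetrically at the top. Its standard error uses the
Tukey–McLaughlin form `s_w / ((1 − 2g/n) √n)`, where `s_w` is the SD of the
winsorized sample; the estimator family reduces to the ordinary mean and
`s/√n` at γ = 0. Note that for n below 10 (common per-bin group sizes
here), `g = 0` and the "Winsorized" mean is simply the mean — plotted error
bars are reproducible only if this convention is stated, which is why it is
fixed in code.

## Rank-based longitudinal inference

Behavioral activity data are heavy-tailed (occasional extreme bursts) and
heteroscedastic, so the group × time analysis is a nonparametric marginal
model on ranks. All N observations are pooled and mid-ranked once; the
relative effect of cell (i, j) is `p̂ = (mean cell rank − ½)/N`, the
probability that a random observation from that cell exceeds a random
observation from the pooled reference distribution. Hypotheses (no group
effect, no time effect, no interaction) are projections `T p = 0`, tested
with the ANOVA-type statistic

```
F = p̂' T p̂ / tr(T V̂)
```

where `V̂` is block-diagonal over groups, each block the empirical
covariance of that group's per-fish rank vectors divided by the group size
— this is how within-fish dependence across bins enters, with no
parametric covariance model. `F` is referred to an F distribution with
numerator df `tr(TV̂)²/tr((TV̂)²)` (Box moment matching); the denominator
df is moment-matched over groups for the whole-plot (group) effect and
infinite for the sub-plot effects (time, interaction), the standard
convention for this family. Pairwise comparisons re-rank within the two
groups; window-restricted tests re-rank within the selected bins. No
multiplicity correction is applied by default (pairwise p-values are
reported raw, as the assay reports them); `stats::p.adjust(method =
"holm")` is the recommended companion when a familywise guarantee is
wanted.

Properties verified by the test suite: invariance under strictly monotone
transformations; exact centring of relative effects (n-weighted across
cells, unweighted in balanced designs); type-I error within [0.03, 0.07]
at nominal 0.05 for n = 10 per group (1000 null replicates); and ≥95%
accept/reject agreement at α = 0.05 with a 10,000-draw subject-relabeling
permutation test across 100 small datasets (n = 4 per group, 3 bins)
spanning null to strong effects. At such sizes the F approximation is
known to be slightly liberal right at the decision boundary — for
confirmatory analysis of very small groups a permutation p-value is the
safer choice, and the guard in `ats_test()` warns below 4 fish per group.
Fish with missing bins are removed case-wise (the assay excluded rather
than imputed).

Whether a reported "slopes differ" claim is best formalized as a
group × time interaction or a slope regression is ambiguous; the package
takes the interaction reading (`ats_test(..., "interaction")`), which is
the assumption-free version of the same question.

## Power analysis

`estimate_power()` simulates the full two-group design at the series level
(per-minute counts drawn directly from the compound-Poisson law implied by
the bout process; the detector is bypassed because normalization cancels
detection efficiency), runs each replicate through normalization, binning
and the rank-based pairwise test, and reports the rejection fraction.
`minimal_n()` walks an ascending grid of group sizes and returns the
smallest reaching the target power (default 0.80, the usual design
convention, exposed as a parameter) together with the whole curve.

The default variability — between-fish CV 0.5, within-fish CV 0.15,
response CV 0.05, a 20-min median baseline — was fixed from the behavioral
calibration above, with the response CV chosen once so that the design's
power profile reproduces the assay's published design guidance that
roughly 20 fish per treatment are needed to detect a sustained 10-point
difference in normalized activity. Under these defaults the power curve
for a 10-point difference crosses 80% between 20 and 25 fish per group. A
sizeable share of the per-fish variance comes from estimating the baseline
median from 20 noisy minutes — a design fact worth noting: lengthening the
stable window is as valuable as adding fish.

## Reproducibility and problem sizes

Every generator function takes a seed; studies derive independent per-fish
streams from the study seed, so adding a group or fish leaves existing
fish's data unchanged, and `run_study()` outputs are bit-identical under a
fixed configuration (each output carries the configuration hash, seed and
package version). The shipped acceptance script uses 20 replicates of a
27-fish cohort for the baseline statistics, 500 replicates per grid point
for power, and 20 replicates of a 9-fish trace-level study for the
morphine arm — sizes chosen so the whole script completes in a few minutes
on a single core while keeping Monte-Carlo error well inside the
tolerances of interest.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analysis relies on:
burst-patterned events, large between-fish gain differences, an early
settling trend with inflated early variance, fish-level response
heterogeneity, gain drift and artifacts in the measurement channel. It does
not model hydrodynamics or biomechanics, anesthesia recovery physiology,
inter-day effects, tank-position preferences, or freezing behavior, and its
effect curves are smooth parametric stand-ins for pharmacology. Passing
tests therefore demonstrate that the pipeline is correct and well
calibrated under the stated model — they cannot certify detector accuracy
on real impedance recordings, for which no public ground truth exists.
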