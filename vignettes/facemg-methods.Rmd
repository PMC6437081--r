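---
title: "Methods: simulating and analysing facial EMG empathy-for-pain experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing facial EMG empathy-for-pain experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemg)
```

## The experimental paradigm

`facemg` implements the analysis chain of a classic psychophysiology design:
participants watch short movies of actors in everyday painful situations
while surface EMG is recorded from two facial muscles tied to negative
affect and pain empathy — the corrugator supercilii (CS, brow furrowing) and
the orbicularis oculi (OO, eye ring). Each ~5.7 s movie is a fixed sequence
of four scenes (neutral face 520 ms, action leading to the pain 1960 ms, the
pain stimulus itself 240 ms, the painful facial expression 3000 ms), and
each of 16 clips (4 situations x 2 actor genders x 2 attractiveness levels)
is seen twice, once under an imagine-self and once under an imagine-other
instruction, giving 32 trials per participant. A jittered 3500–7500 ms
fixation cross precedes every movie and provides the baseline. After each
movie the participant rates the observed pain on a 0–10 graphic rating
scale (GRS); trait empathy is measured once with the IRI subscales
(empathic concern EC, personal distress PD, perspective taking PT).

Raw data of such studies are rarely deposited, so the package pairs the
analysis chain with a synthetic-experiment generator with known ground
truth. Every downstream stage is therefore testable end to end: the
generator's scene factors are exactly the baseline-relative quantities the
pipeline estimates.

## The synthetic signal model

Each channel is a band-limited Gaussian carrier: white noise band-passed to
the analysis band (30–400 Hz by default). For a zero-mean Gaussian signal
the expected rectified amplitude is `E|x| = sigma * sqrt(2/pi)`, so the
carrier's standard deviation is calibrated so that the expected rectified
envelope during fixation equals the nominal baseline amplitude (8 uV per
muscle by default). Inside scene `s` of a trial the carrier is multiplied by

```
gain = (1 + responsiveness * (factor(s, condition) - 1)) * trial_jitter
```

* `factor` is the ground-truth baseline-relative scene amplitude (1 = no
  change). The defaults emulate a realistic corrugator profile rising from
  1.032 to 1.103 across scenes, shifted by ±0.0095 with actor
  attractiveness and by ±0.0135 with actor gender in the pain-expression
  scene only, and a flat-then-rising orbicularis profile
  (0.987/0.985/0.994/1.083).
* `responsiveness` is a per-participant, per-muscle lognormal multiplier
  with mean exactly 1 (meanlog `-sd^2/2`), scaling each participant's
  *deviation* from baseline; it creates realistic between-participant
  variance and is the quantity the EC trait score can be coupled to.
* `trial_jitter` is a mean-one lognormal factor applied to the whole movie
  window of a trial, creating trial-to-trial variability that survives
  baseline division (a jitter applied to the entire trial, baseline
  included, would cancel exactly).

Because the carrier occupies the analysis band, the conditioning chain is
transparent to this ground truth and scene factors map one-to-one onto the
recovered baseline-relative scene means in expectation. On top of the
carrier the generator adds mains interference (50/100/150 Hz sinusoids) and
occasional movement artifacts: 200–800 ms transients at ten times the
baseline amplitude mixing a low-frequency (~6 Hz) sway with an in-band
burst, so that they are conspicuous both before and after band filtering,
as frowning or yawning artifacts are in practice.

What the generator does *not* model: physiological motor-unit statistics
(the amplitude distribution of real EMG is only approximately Gaussian),
nonstationary baselines, electrode drift, cross-talk between muscles, or
any dependence of the GRS/trait scores on the simulated signals beyond the
explicitly injected couplings. Passing tests demonstrate that the analysis
chain recovers the stated generative structure, not that real EMG satisfies
this model.

Determinism: one master seed fans out into fixed per-participant,
per-stage substreams (`participant_seed()`), so identical configurations
are byte-identical and adding participants never perturbs existing ones.

## The conditioning chain

The chain follows the conventional facial-EMG recipe, in this order:

1. **Band filtering** of the continuous signal: Butterworth low-pass at
   400 Hz, high-pass at 30 Hz, and narrow band-stop notches at
   49.9–50.1, 99–101 and 149–151 Hz. The convention fixes family and
   cutoffs; the order (4th for LP/HP, 2nd per notch) and the phase mode are
   configurable. By default every filter is applied forward and backward
   (zero phase), which squares the magnitude response and avoids delaying
   the envelope relative to the scene windows; a single causal pass is
   available via `filter_spec(zero_phase = FALSE)`. Edges are handled with
   odd (point-symmetric) reflection padding, so DC offsets do not ring.
   The 0.2 Hz-wide notches have settling times of several seconds; this is
   irrelevant in practice because epochs start at least 1 s into the
   recording, but any steady-state attenuation measurement must use a long
   probe signal.
2. **Artifact screening**, replacing visual inspection with an automated
   criterion: a trial is excluded for a muscle when any filtered sample of
   its epoch exceeds `k = 8` times the robust scale (1.4826·MAD over that
   participant's whole recording). MAD makes the threshold insensitive to
   the artifacts being detected; `k` is configurable and recorded in the
   provenance sidecar.
3. **Epoching** into 8720 ms windows: 2500 ms pre-movie + 5720 ms movie +
   500 ms post. Milliseconds map to samples by round-half-to-even on
   `ms * rate / 1000` with half-open `[start, end)` windows — necessary
   because several durations (520 ms at 1024 Hz) are non-integer in
   samples. Scene boundaries are rounded cumulatively, so the four scene
   windows always partition the movie window exactly.
4. **Envelope extraction** per epoch: absolute value, then a 20 Hz
   Butterworth low-pass.
5. **Baseline division**: the scalar baseline is the mean envelope over the
   2000 ms immediately preceding movie onset (the final 2000 ms of the
   2500 ms pre-movie segment — the "immediately preceding" reading of a
   baseline "2000 ms before the movie"). Every epoch sample is divided by
   it; baselines below 1e-6 uV exclude the trial instead of producing
   infinities.
6. **Scene means**: the normalized envelope is averaged within each scene
   window, giving the per-trial "EMG indicators" that all statistics
   consume.

Two readings in this chain were genuinely open and are settled as follows.
The "phase-unlocked response" is interpreted as the induced rectified
amplitude (rectify-then-smooth), not a stimulus-locked average. And a
stimulus duration printed elsewhere as "5720 s" is treated as a
typographical error for 5720 ms, since the scene durations sum to 5720 ms.

## Aggregation

Retained trials are averaged into participant x muscle x perspective x
actor-gender x attractiveness x scene cells (up to four situation trials
per cell; three is accepted). Participants missing an entire cell are
dropped *per muscle* (listwise within each muscle's analysis). This
reconstruction is what produces different error degrees of freedom across
analyses of the same study — ratings retain everyone while each muscle
loses its own artifact-stricken participants — and the roster of drops is
always reported. GRS ratings are averaged into 8 cells per participant
(scene is not a rating factor; one rating is given per movie).

## The inferential layer

`mixed_rm_anova()` implements the classical univariate mixed-design
repeated-measures ANOVA on cell means (the two-stage approach; no
trial-level mixed models). For each within-subject effect an orthonormal
contrast basis is applied to the per-subject cell-mean matrix, and the
resulting contrast scores are fitted against the between-subjects design
with sum-to-zero coding; general-linear-hypothesis sums of squares for the
intercept give the within effect, those for the group rows give its
interaction with the between factor, and the residuals give the
interaction-with-subjects error stratum. The between effect is tested
against subjects-within-groups. This reproduces the textbook mixed-model
table exactly on balanced data (verified against `stats::aov()` to 1e-8 in
the tests) and yields unweighted-means (SPSS-style Type III) hypotheses
when group sizes are unequal, as with 27 female / 24 male participants.

Effect sizes are partial eta squared, `SS_eff / (SS_eff + SS_err)`,
recoverable from any reported F as `F df1 / (F df1 + df2)` — the arithmetic
the package's worked-example checks exploit: all printed effect sizes of
the reference results reproduce from their printed F and dfs under the
*partial* formula, which is how the package settles that the reported
"eta squared" values are partial. No sphericity correction is applied by
default (matching reported uncorrected dfs such as (3, 144));
Greenhouse–Geisser epsilon-corrected p-values are available as an option.

Post hoc machinery mirrors standard practice: Sidak-adjusted simple main
effects (`p_adj = 1 - (1-p)^m`, one family per simple-effects analysis —
e.g. the four per-scene actor-gender comparisons form one family of
`m = 4`), contrasts of each scene against the neutral-face scene
(`m = 3`), and paired t-tests with `d = mean(diff)/sd(diff) = t/sqrt(n)`.
Trait-empathy correlations are Pearson coefficients between each IRI
subscale and the per-participant scene response (collapsed over the actor
factors) for every muscle x scene x perspective combination, with
Benjamini–Hochberg step-up FDR adjustment. The FDR family is all
correlations of one muscle by default; the scope is configurable and
recorded, since the reference analyses do not state their family size. All
tests are two-sided.

## Numerical and design choices

* **IRI subscales** are modelled as 7-item subscales scored 0–28
  (integer-rounded, clamped). Only the correlation structure matters
  downstream, so the range is configurable.
* **GRS generation** adds Gaussian noise (SD 1 by default — a realistic
  rating scatter on a 0–10 scale) to condition cell means patterned like
  the reference results (female and low-attractiveness actors rated more
  painful, a small imagine-other advantage), clamped to the scale.
* **Artifact probability** defaults to 2% of trials, a typical facial-EMG
  attrition rate; the detector catches the injected 10x transients while
  leaving clean Gaussian trials untouched (an 8-sigma excursion has
  negligible probability over an epoch).
* **Envelope flatness**: for a constant-gain carrier the rectified,
  20 Hz-smoothed envelope retains roughly the below-20 Hz share of the
  rectified signal's fluctuation spectrum, giving a coefficient of
  variation near 0.16; the tests assert the Monte-Carlo-derived bound
  (< 0.22) rather than a nominal flatness.
* **Problem sizes**: the test suite exercises the full chain at the study
  scale it models — 50 participants for scene-factor recovery (20
  replicate seeds), 224 identity-configuration trials for pipeline unity,
  2000 simulated null experiments at 20 participants for type-I
  calibration (the 2x2x2x4 within-design with a gender between factor has
  31 effects; 2000 replicates put the ±0.02 tolerance at about four
  binomial standard errors per effect), and 100 seeds for the trait
  coupling. These sizes were chosen to make the Monte-Carlo bounds sharp at
  study-realistic dimensions.

## Known limitations

* The carrier is a stand-in: no published distributional description of the
  original signals exists, so recovery results quantify the pipeline, not
  biological variability.
* The artifact screen is amplitude-based; slow drifts that never exceed the
  threshold (or artifacts confined to notch bands) would pass it.
* Listwise-per-muscle deletion is a reconstruction of how per-analysis
  sample sizes diverge; other exclusion schemes (e.g. shared rosters across
  muscles) are plausible and would change error dfs.
* The ANOVA requires balanced within-cells after aggregation; designs with
  structurally missing cells need a different (mixed-model) approach, which
  is deliberately out of scope.
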