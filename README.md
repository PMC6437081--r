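# facemg

Simulation and analysis of facial surface-EMG empathy-for-pain experiments.

## The problem

Psychophysiology studies of pain empathy record surface EMG from facial
muscles — the corrugator supercilii (CS, brow furrowing, an index of
negative affect) and the orbicularis oculi (OO, eye ring) — while
participants watch movies of actors in painful situations under different
perspective-taking instructions (imagine-self vs imagine-other). The
analysis asks how the baseline-relative EMG amplitude during the movie's
scenes (neutral face → action → pain stimulus → pain expression) is
modulated by the actor's gender and attractiveness, the observer's gender
and perspective, and how it relates to pain-intensity ratings (GRS, 0–10)
and trait empathy (IRI subscales EC/PD/PT).

Raw recordings of such studies are rarely shared. `facemg` therefore
couples the full analysis chain with a synthetic-experiment generator with
known ground truth, so every stage — filtering, artifact screening,
epoching, envelope extraction, baseline normalisation, factorial
aggregation and the inferential layer — is testable end to end, and power
or calibration questions can be answered by simulation.

## What it computes

* **Signal conditioning**: Butterworth low-pass (400 Hz), high-pass
  (30 Hz) and mains notch comb (49.9–50.1 / 99–101 / 149–151 Hz), applied
  zero-phase by default; automated artifact screening at `k·1.4826·MAD`;
  8720 ms epochs (2500 pre + 5720 movie + 500 post); rectified envelope
  (|x| then 20 Hz low-pass); division by the mean envelope of the 2000 ms
  pre-movie fixation window; scene means over exact sample partitions of
  the movie window.
* **Mixed repeated-measures ANOVA** on condition cell means, with one
  between-subjects factor (participant gender) and crossed within factors
  (perspective × actor gender × attractiveness × scene). Every within
  effect is tested against its interaction-with-subjects stratum; effect
  sizes are partial eta squared,

      η²p = SS_eff / (SS_eff + SS_err) = F·df₁ / (F·df₁ + df₂)

* **Post hocs and effect sizes**: Sidák-adjusted simple main effects
  (`p_adj = 1 − (1 − p)^m`), contrasts of each scene against the
  neutral-face scene, paired t with Cohen's `d = mean(diff)/sd(diff) =
  t/√n`.
* **Trait correlation screen**: Pearson r between each IRI subscale and
  the per-participant scene responses for every muscle × scene ×
  perspective, Benjamini–Hochberg FDR-adjusted.
* **Synthetic experiments**: band-limited Gaussian carriers calibrated so
  scene gain factors map one-to-one to recovered baseline-relative means
  (`E|x| = σ√(2/π)`), plus mains interference, movement artifacts,
  condition-dependent modulation, GRS ratings and coupled trait scores.
  See `vignette("facemg-methods")` for the model and its limitations.

## Worked example

```r
library(facemg)
res <- run_pipeline(n_participants = 8, n_female = 4, seed = 1)

cs <- res$results$anova_cs
cs[cs$effect %in% c("attractiveness", "scene"), ]
#>           effect df1 df2      f        p   pes
#> 1 attractiveness   1   6   8.92 2.44e-02 0.598
#> 2          scene   3  18 107.79 1.08e-11 0.947

res$results$scene_contrasts_cs
#>          comparison mean_diff     t df    d        p m  p_sidak
#> 1 scene 2 - scene 1    0.0306  9.21  7 3.26 3.66e-05 3 1.10e-04
#> 2 scene 3 - scene 1    0.0507  9.65  7 3.41 2.71e-05 3 8.12e-05
#> 3 scene 4 - scene 1    0.0658 14.27  7 5.04 1.97e-06 3 5.92e-06
```

The corrugator scene means recovered by this 8-participant run are
1.033 / 1.063 / 1.084 / 1.099 against generative factors
1.032 / 1.064 / 1.092 / 1.103: the envelope rises from the neutral face to
the pain expression, attractiveness modulates the response, and the scene
contrasts separate every later scene from the neutral baseline. The GRS
analysis likewise shows the built-in actor gender × attractiveness pattern
with paired effect sizes labelled by conventional cutpoints:

```r
res$results$grs_effect_sizes[c("comparison", "t", "df", "p", "d", "label")]
#>         comparison     t df       p      d      label
#> 1   F low vs M low  2.72  7 0.02962  0.963      large
#> 2 F high vs M high  2.57  7 0.03689  0.909      large
#> 3  F high vs F low -4.31  7 0.00351 -1.525 very large
#> 4  M high vs M low -1.36  7 0.21672 -0.480      small
```

`run_pipeline(..., out_dir = "out")` writes every intermediate table
(events, trial-scene means, condition tables, ANOVA/post-hoc/correlation
TSVs), a provenance JSON and a plain-text report. A thin CLI with
`simulate` / `preprocess` / `aggregate` / `analyze` / `all` subcommands
lives at `inst/cli/facemg.R`, configured by a YAML file
(`inst/extdata/example-config.yaml`).

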