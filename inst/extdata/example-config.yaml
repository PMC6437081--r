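# Example facemg pipeline configuration.
# Unset keys fall back to the package defaults documented in
# ?modulation_spec, ?nuisance_spec, ?filter_spec and ?run_pipeline.

n_participants: 51
n_female: 27
seed: 1

grs_sd: 1            # rating noise SD on the 0-10 scale
trait_coupling_r: 0.42   # target EC / corrugator responsiveness correlation
artifact_k: 8        # MAD multiplier of the artifact screen

modulation:
  baseline_amp: {CS: 8.0, OO: 8.0}        # fixation envelope, microvolts
  cs_scene: [1.032, 1.064, 1.092, 1.103]  # baseline-relative scene factors
  oo_scene: [0.987, 0.985, 0.994, 1.083]
  cs_attractiveness_shift: 0.0095
  cs_actor_gender_scene4_shift: 0.0135
  responsiveness_sd: 0.2
  trial_noise_sd: 0.05

nuisance:
  mains_amp: {50: 10.0, 100: 3.0, 150: 1.0}  # microvolts
  artifact_prob: 0.02
  artifact_mult: 10
  artifact_dur_ms: [200, 800]
  passband: [30, 400]

filter:
  low_pass: 400
  high_pass: 30
  envelope_low_pass: 20
  order: 4
  notch_order: 2
  zero_phase: true
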