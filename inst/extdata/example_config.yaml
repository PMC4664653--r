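# Example gm1ims pipeline configuration: a small two-tract study
# (corpus callosum vs internal capsule) at reduced scale.
version: 1
seed: 42
species:
  - {name: "GM1d18:1", formula: C73H131N3O31, adduct: "[M-H]-"}
  - {name: "GM1d20:1", formula: C75H135N3O31, adduct: "[M-H]-"}
simulation:
  layout: pair
  dims: [16, 8]
  labels: [CC, IC]
  regions:
    CC: {total: 30, ratio: 5.506}
    IC: {total: 30, ratio: 3.56}
  mz_range: [1500, 1620]
  mz_bin: 0.02
  peak_sigma: 0.15
  baseline: {constant: 2, slope: -0.001, bump_amplitude: 3, bump_center: 1520, bump_sd: 60}
  gain_sdlog: 0.25
  noise_sd: 0.5
  animal_cv: 0.1
  n_animals: 6
  sections_per_animal: 2
quantification:
  search_halfwidth: 0.5
  integration_halfwidth: 0.4
  detection_floor_k: 3
  baseline: {method: linear, flank_width_da: 1.0}
stats:
  normality: dagostino
  posthoc: dunn
output:
  outdir: gm1ims_out
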