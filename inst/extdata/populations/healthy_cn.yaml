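# SYNTHETIC placeholder: healthy Chinese adult reference population.
# These values are plausibility-level stand-ins for a proprietary healthy
# population library and are intended to be replaced by the user with a
# validated healthy-volunteer parameter set. Units and functional forms as
# in mild_cn.yaml. gfr_band is null: no containment enforcement.
schema: renalpbpk-population/1
category: healthy
label: Healthy Chinese adults (synthetic placeholder)
sex_ratio_f: 0.5
gfr_band: null
kidney:
  baseline: 15.4
  bw_coeff: 2.04
  bh_coeff: 51.8
  density_g_L: 1050.0
male:
  age_range: [18.0, 60.0]
  height_age: [169.83, -0.0891, 0.0005]
  height_sd: 5.6
  weight_height: [2.13, 0.0128]
  scr_bands:
    - {age_min: 18.0, age_max: 60.0, mean: 80.0, cv: 0.15}
  hematocrit: {mean: 45.3, cv: 0.095}
  agp: {mean: 0.638, cv: 0.23}
  hsa: [50.34, -0.0575, -0.0738]
female:
  age_range: [18.0, 60.0]
  height_age: [155.95, 0.1158, -0.0016]
  height_sd: 4.6
  weight_height: [0.93, 0.0198]
  scr_bands:
    - {age_min: 18.0, age_max: 60.0, mean: 63.0, cv: 0.15}
  hematocrit: {mean: 40.5, cv: 0.109}
  agp: {mean: 0.575, cv: 0.24}
  hsa: [49.38, -0.037, 0.1286]
meta:
  synthetic: true
  user_replaceable: true
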