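# SYNTHETIC placeholder: healthy Caucasian adult reference population
# (template for the serum-creatinine-scaled derived mild renal impairment
# model). Plausibility-level stand-ins, user-replaceable. Units and
# functional forms as in mild_cn.yaml. gfr_band is null.
schema: renalpbpk-population/1
category: healthy
label: Healthy Caucasian adults (synthetic placeholder)
sex_ratio_f: 0.5
gfr_band: null
kidney:
  baseline: 20.0
  bw_coeff: 2.30
  bh_coeff: 60.0
  density_g_L: 1050.0
male:
  age_range: [18.0, 95.0]
  height_age: [178.0, -0.05, -0.0005]
  height_sd: 7.0
  weight_height: [2.0, 0.0135]
  scr_bands:
    - {age_min: 18.0, age_max: 95.0, mean: 88.0, cv: 0.15}
  hematocrit: {mean: 45.0, cv: 0.09}
  agp: {mean: 0.70, cv: 0.25}
  hsa: [48.0, -0.05, -0.07]
female:
  age_range: [18.0, 95.0]
  height_age: [165.0, -0.03, -0.0006]
  height_sd: 6.5
  weight_height: [1.55, 0.0155]
  scr_bands:
    - {age_min: 18.0, age_max: 95.0, mean: 70.0, cv: 0.15}
  hematocrit: {mean: 40.0, cv: 0.10}
  agp: {mean: 0.65, cv: 0.25}
  hsa: [47.0, -0.04, -0.07]
meta:
  synthetic: true
  user_replaceable: true
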