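# Chinese moderate renal impairment population parameters.
# Units and functional forms as in mild_cn.yaml.
schema: renalpbpk-population/1
category: moderate
label: Chinese moderate renal impairment
sex_ratio_f: 0.42
gfr_band: [30.0, 59.0]
kidney:
  baseline: 8.4
  bw_coeff: 1.64
  bh_coeff: 32.8
  density_g_L: 1050.0
male:
  age_range: [22.0, 83.0]
  height_age: [172.56, -0.1205, 0.0003]
  height_sd: 5.44
  weight_height: [2.8, 0.0082]
  scr_bands:
    - {age_min: 22.0, age_max: 50.0, mean: 200.0, cv: 0.23}
    - {age_min: 50.0, age_max: 83.0, mean: 156.0, cv: 0.23}
  hematocrit: {mean: 39.7, cv: 0.065}
  agp: {mean: 0.793, cv: 0.23}
  hsa: [47.1, -0.0575, -0.0738]
female:
  age_range: [22.0, 83.0]
  height_age: [168.69, -0.4967, 0.0046]
  height_sd: 4.67
  weight_height: [2.89, 0.0071]
  scr_bands:
    - {age_min: 22.0, age_max: 40.0, mean: 185.0, cv: 0.22}
    - {age_min: 40.0, age_max: 60.0, mean: 150.0, cv: 0.24}
    - {age_min: 60.0, age_max: 83.0, mean: 125.0, cv: 0.24}
  hematocrit: {mean: 36.5, cv: 0.071}
  agp: {mean: 0.715, cv: 0.24}
  hsa: [44.9, -0.037, -0.1286]
meta:
  observed_counts: {male: 191, female: 85}
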