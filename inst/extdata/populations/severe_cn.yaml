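# Chinese severe renal impairment population parameters.
# Units and functional forms as in mild_cn.yaml.
schema: renalpbpk-population/1
category: severe
label: Chinese severe renal impairment
sex_ratio_f: 0.42
gfr_band: [15.0, 29.0]
kidney:
  baseline: 5.7
  bw_coeff: 1.04
  bh_coeff: 29.8
  density_g_L: 1050.0
male:
  age_range: [18.0, 83.0]
  height_age: [176.04, -0.2536, 0.0015]
  height_sd: 5.40
  weight_height: [1.72, 0.0146]
  scr_bands:
    - {age_min: 18.0, age_max: 50.0, mean: 411.0, cv: 0.23}
    - {age_min: 50.0, age_max: 83.0, mean: 304.0, cv: 0.24}
  hematocrit: {mean: 33.2, cv: 0.065}
  agp: {mean: 1.14, cv: 0.35}
  hsa: [43.08, -0.0575, -0.0738]
female:
  age_range: [18.0, 83.0]
  height_age: [155.86, 0.0672, -0.001]
  height_sd: 4.75
  weight_height: [2.10, 0.0122]
  scr_bands:
    - {age_min: 18.0, age_max: 30.0, mean: 412.0, cv: 0.22}
    - {age_min: 30.0, age_max: 60.0, mean: 300.0, cv: 0.23}
    - {age_min: 60.0, age_max: 83.0, mean: 229.0, cv: 0.20}
  hematocrit: {mean: 31.3, cv: 0.071}
  agp: {mean: 1.03, cv: 0.35}
  hsa: [37.8, -0.0575, -0.1286]
meta:
  observed_counts: {male: 265, female: 162}
  note: >
    Observed-cohort male count is reported as 266 in the summary table and
    265 in the parameter table of the source data; the parameter-table value
    is carried here and the discrepancy documented.
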