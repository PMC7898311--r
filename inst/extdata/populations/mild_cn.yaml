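# Chinese mild renal impairment population parameters.
# Height in cm, weight in kg, serum creatinine in umol/L, hematocrit in %,
# AGP in g/L, HSA in g/L, kidney volume in mL.
# height_age: BH = c0 + c1*Age + c2*Age^2
# weight_height: BW = exp(a + b*BH_cm)
# hsa: HSA = C0 + C1*Age + C2*(Age/10)^2
# kidney: V = baseline + bw_coeff*BW(kg) + bh_coeff*BH(m)
schema: renalpbpk-population/1
category: mild
label: Chinese mild renal impairment
sex_ratio_f: 0.22
gfr_band: [60.0, 89.0]
kidney:
  baseline: 15.4
  bw_coeff: 2.04
  bh_coeff: 51.8
  density_g_L: 1050.0
male:
  age_range: [18.0, 69.0]
  height_age: [169.83, -0.0891, 0.0005]
  height_sd: 5.58
  weight_height: [2.13, 0.0128]
  scr_bands:
    - {age_min: 18.0, age_max: 60.0, mean: 118.0, cv: 0.13}
    - {age_min: 60.0, age_max: 69.0, mean: 95.0, cv: 0.10}
  hematocrit: {mean: 45.3, cv: 0.095}
  agp: {mean: 0.638, cv: 0.23}
  hsa: [50.34, -0.0575, -0.0738]
female:
  age_range: [18.0, 69.0]
  height_age: [155.95, 0.1158, -0.0016]
  height_sd: 4.59
  weight_height: [0.93, 0.0198]
  scr_bands:
    - {age_min: 18.0, age_max: 50.0, mean: 93.0, cv: 0.14}
    - {age_min: 50.0, age_max: 69.0, mean: 78.0, cv: 0.23}
  hematocrit: {mean: 40.5, cv: 0.109}
  agp: {mean: 0.575, cv: 0.24}
  hsa: [49.38, -0.037, 0.1286]
meta:
  observed_counts: {male: 67, female: 21}
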