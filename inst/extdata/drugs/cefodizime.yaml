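# Cefodizime drug parameters — literature-informed approximation.
schema: renalpbpk-drug/1
name: cefodizime
mw: 584.7
compound_class: monoprotic_acid
pka: [3.0]
logp: -0.8
fu_plasma: 0.14
bp_ratio: 0.55
vss_obs: 0.15
cl_iv: 2.9
clr: 2.1
kp_method: poulin_theil
kp_scalar: 0.356912
binding_protein: hsa
gfr_ref: 120.0
provenance:
  approximate: true
  source: >
    Literature-informed approximations assembled for testing: a third-
    generation cephalosporin, highly albumin-bound (~85%), t1/2 ~3-4 h,
    Vss ~0.15 L/kg, with a >25% non-renal elimination fraction. Not the
    unavailable supplementary input values of any specific study.
  note: substantial (>25%) non-renal elimination route
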