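# Cefuroxime drug parameters — literature-informed approximation.
schema: renalpbpk-drug/1
name: cefuroxime
mw: 424.4
compound_class: monoprotic_acid
pka: [2.45]
logp: -0.16
fu_plasma: 0.67
bp_ratio: 0.55
vss_obs: 0.19
cl_iv: 4.3
clr: 4.0
kp_method: poulin_theil
kp_scalar: 0.319246
binding_protein: hsa
gfr_ref: 120.0
provenance:
  approximate: true
  source: >
    Literature-informed approximations assembled for testing: a second-
    generation cephalosporin, ~33% protein bound, t1/2 ~1.2 h, Vss
    ~0.19 L/kg, predominantly renally excreted unchanged. Not the
    unavailable supplementary input values of any specific study.
  note: >
    ~28% of renal elimination is reported as active tubular secretion
    (MRP4 substrate); the model lumps renal elimination into a single
    GFR-proportional clearance.
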