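# Vancomycin drug parameters — literature-informed approximation.
schema: renalpbpk-drug/1
name: vancomycin
mw: 1449.3
compound_class: zwitterion
pka: {acid: 2.18, base: 8.89}
logp: -3.1
fu_plasma: 0.6
bp_ratio: 0.66
vss_obs: 0.5
cl_iv: 5.6
clr: 5.0
kp_method: rodgers_rowland
kp_scalar: 2.374547
binding_protein: hsa
gfr_ref: 120.0
provenance:
  approximate: true
  source: >
    Literature-informed approximations assembled for testing: a
    glycopeptide zwitterion, ~40-50% protein bound, Vss ~0.4-0.9 L/kg,
    clearance strongly correlated with creatinine clearance. Not the
    unavailable supplementary input values of any specific study.
  note: >
    ~25% renal tubular reabsorption is reported for this compound; the
    model lumps renal elimination into a single GFR-proportional clearance
    and does not represent reabsorption mechanistically.
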