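# Ceftazidime drug parameters — literature-informed approximation.
schema: renalpbpk-drug/1
name: ceftazidime
mw: 546.6
compound_class: monoprotic_acid
pka: [2.9]
logp: -1.6
fu_plasma: 0.85
bp_ratio: 0.55
vss_obs: 0.23
cl_iv: 6.9
clr: 6.2
kp_method: poulin_theil
kp_scalar: 0.369459
binding_protein: hsa
gfr_ref: 120.0
provenance:
  approximate: true
  source: >
    Literature-informed approximations assembled for testing: a third-
    generation cephalosporin eliminated ~90% unchanged by glomerular
    filtration, ~10-15% plasma protein bound, Vss ~0.2-0.25 L/kg, total
    clearance ~115 mL/min in healthy adults. Not the unavailable
    supplementary input values of any specific study.
  note: primarily cleared by passive glomerular filtration
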