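# renalpbpk tissue composition table (adult, literature-informed approximation
# of the standard published composition data used for tissue:plasma partition
# prediction; fractional volumes per g tissue, acidic phospholipids AP in mg/g,
# ar/lr are tissue:plasma albumin and lipoprotein concentration ratios,
# ph is intracellular-relevant tissue water pH used for ionization).
tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,ar,lr,ph_iw
adipose,0.135,0.017,0.790,0.0016,0.40,0.049,0.068,7.0
bone,0.100,0.346,0.017,0.0017,0.67,0.100,0.050,7.0
brain,0.162,0.620,0.039,0.0015,0.40,0.048,0.041,7.0
gut,0.282,0.475,0.038,0.0125,2.41,0.158,0.0141,7.0
heart,0.320,0.456,0.014,0.0111,2.25,0.157,0.0135,7.0
kidney,0.273,0.483,0.012,0.0240,5.03,0.130,0.0016,7.0
liver,0.161,0.573,0.014,0.0240,4.56,0.086,0.0010,7.0
lung,0.336,0.446,0.022,0.0128,3.91,0.212,0.0068,7.0
muscle,0.118,0.630,0.010,0.0072,1.53,0.064,0.0059,7.0
skin,0.382,0.291,0.060,0.0044,1.32,0.277,0.0962,7.0
spleen,0.207,0.579,0.0077,0.0113,3.18,0.097,0.0207,7.0
rest,0.210,0.505,0.023,0.0100,2.00,0.120,0.0200,7.0
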