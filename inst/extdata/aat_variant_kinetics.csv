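# Published apparent steady-state kinetic parameters for E. coli
# aspartate aminotransferase variants: l-aspartate and l-phenylalanine
# donor substrates (KM in mM, kcat in 1/s, kcat/KM in 1/(M s));
# selectivity = (kcat/KM Phe) / (kcat/KM Asp) as printed (2 s.f.).
enzyme,km_asp,kcat_asp,eff_asp,km_phe,kcat_phe,eff_phe,selectivity
WT,0.21,7.8,37000,NA,NA,400,0.01
HEX,0.059,1.32,22000,0.27,9.0,33000,1.5
IYIT,0.014,0.155,11000,0.34,10.1,30000,2.7
VFIT,0.027,0.90,33000,0.90,22.8,25000,0.8
VFIY,0.12,0.263,2200,0.42,17.3,41000,19
VYIT,0.08,0.37,4600,1.11,41.8,38000,8
VYIY,0.09,0.244,2700,0.58,20.9,36000,13
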