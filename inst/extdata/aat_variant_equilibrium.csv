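# Published conformational-equilibrium reference values for E. coli
# aspartate aminotransferase variants: Boltzmann-weighted design
# energies (kcal/mol, T = 300 K) and two-state thermodynamic parameters
# of closing (kcal/mol, kcal/mol/K; T_ref = 298 K). NA = not determined.
enzyme,e_closed,e_open,delta_e,dh,ds,dcp,dg_278K,dg_303K
WT,-358.0,-372.2,14.2,NA,NA,NA,NA,NA
HEX,-350.2,-273.4,-76.8,-9.9,-0.032,0.972,-1.72,-0.31
VFIT,-366.1,-320.6,-45.5,-10.7,-0.038,0.667,-0.59,0.78
VFIY,-357.8,-300.0,-57.8,-19.6,-0.070,0.369,-0.38,1.59
VFCS,-385.6,-389.7,4.2,NA,NA,NA,NA,NA
AIFS,-237.2,-364.4,127.2,NA,NA,NA,NA,NA
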