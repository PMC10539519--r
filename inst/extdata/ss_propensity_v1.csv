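# confdesign secondary-structure propensity table, version 1 (kcal/mol;
# lower = more favorable in that secondary-structure class).
resname,helix,strand,other
ALA,-0.30,0.10,0.00
ARG,-0.10,0.05,0.00
ASN,0.15,0.20,-0.05
ASP,0.10,0.25,-0.05
CYS,0.10,-0.10,0.00
GLN,-0.15,0.10,0.00
GLU,-0.25,0.15,0.00
GLY,0.45,0.35,-0.15
HIS,0.05,0.00,0.00
ILE,-0.05,-0.30,0.05
LEU,-0.25,-0.10,0.05
LYS,-0.10,0.05,0.00
MET,-0.20,-0.05,0.00
PHE,0.00,-0.25,0.05
SER,0.15,0.05,-0.05
THR,0.15,-0.20,0.00
TRP,0.00,-0.15,0.00
TYR,0.05,-0.25,0.05
VAL,0.00,-0.35,0.05
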