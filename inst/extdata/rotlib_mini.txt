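# confdesign mini backbone-dependent rotamer library (synthetic).
# Columns: restype phi psi prob chi1 sig1 chi2 sig2 chi3 sig3 chi4 sig4
# Absent chi angles are "-". One (phi,psi) bin per residue type; the
# reader falls back to the nearest available bin for other backbones.
# Probabilities are per-(restype,bin) and sum to 1. All 18 designable
# non-Pro/non-Gly types are covered; values are field-plausible
# (trans/gauche chi means, ~10 degree spreads), not measured statistics.
ALA -60 -40 1.000 - - - - - - - -
SER -60 -40 0.48 64.0 10.1 - - - - - -
SER -60 -40 0.31 -65.0 10.3 - - - - - -
SER -60 -40 0.21 180.0 10.9 - - - - - -
CYS -60 -40 0.51 -65.0 9.9 - - - - - -
CYS -60 -40 0.29 -178.0 10.2 - - - - - -
CYS -60 -40 0.20 63.0 10.0 - - - - - -
VAL -60 -40 0.73 175.0 8.9 - - - - - -
VAL -60 -40 0.20 -60.0 9.4 - - - - - -
VAL -60 -40 0.07 63.0 10.0 - - - - - -
THR -60 -40 0.49 62.0 8.8 - - - - - -
THR -60 -40 0.43 -61.0 9.1 - - - - - -
THR -60 -40 0.08 -175.0 10.5 - - - - - -
ILE -60 -40 0.60 -61.0 9.2 169.0 10.1 - - - -
ILE -60 -40 0.25 -59.0 9.5 -64.0 10.4 - - - -
ILE -60 -40 0.15 62.0 10.0 170.0 10.6 - - - -
LEU -60 -40 0.59 -65.0 9.4 175.0 9.8 - - - -
LEU -60 -40 0.29 -177.0 9.7 65.0 10.2 - - - -
LEU -60 -40 0.12 -85.0 10.8 60.0 11.0 - - - -
ASP -60 -40 0.51 -68.0 9.8 -25.0 14.9 - - - -
ASP -60 -40 0.33 -169.0 10.2 5.0 15.5 - - - -
ASP -60 -40 0.16 63.0 10.5 8.0 15.0 - - - -
ASN -60 -40 0.46 -67.0 10.1 -35.0 16.2 - - - -
ASN -60 -40 0.34 -174.0 10.4 -15.0 16.8 - - - -
ASN -60 -40 0.20 63.0 10.7 30.0 16.0 - - - -
HIS -60 -40 0.45 -64.0 10.0 -75.0 13.1 - - - -
HIS -60 -40 0.33 -175.0 10.3 65.0 13.4 - - - -
HIS -60 -40 0.22 62.0 10.6 80.0 13.0 - - - -
PHE -60 -40 0.49 -66.0 9.6 95.0 12.2 - - - -
PHE -60 -40 0.33 -178.0 9.9 80.0 12.5 - - - -
PHE -60 -40 0.18 62.0 10.2 90.0 12.0 - - - -
TYR -60 -40 0.50 -66.0 9.7 95.0 12.3 - - - -
TYR -60 -40 0.32 -177.0 10.0 80.0 12.6 - - - -
TYR -60 -40 0.18 62.0 10.3 90.0 12.1 - - - -
TRP -60 -40 0.42 -67.0 9.8 100.0 13.6 - - - -
TRP -60 -40 0.35 -178.0 10.1 -105.0 13.9 - - - -
TRP -60 -40 0.23 61.0 10.4 90.0 13.5 - - - -
MET -60 -40 0.44 -65.0 9.9 175.0 11.2 75.0 13.8 - -
MET -60 -40 0.35 -178.0 10.2 178.0 11.5 -75.0 14.1 - -
MET -60 -40 0.21 62.0 10.5 180.0 11.0 70.0 13.5 - -
GLU -60 -40 0.47 -65.0 10.0 178.0 11.3 -10.0 16.9 - -
GLU -60 -40 0.33 -178.0 10.3 178.0 11.6 5.0 17.2 - -
GLU -60 -40 0.20 63.0 10.6 -179.0 11.1 10.0 16.5 - -
GLN -60 -40 0.46 -66.0 10.1 177.0 11.4 -20.0 17.0 - -
GLN -60 -40 0.34 -177.0 10.4 179.0 11.7 15.0 17.3 - -
GLN -60 -40 0.20 62.0 10.7 -178.0 11.2 20.0 16.8 - -
LYS -60 -40 0.45 -65.0 10.2 179.0 11.5 178.0 12.7 179.0 13.2
LYS -60 -40 0.34 -178.0 10.5 178.0 11.8 179.0 13.0 178.0 13.5
LYS -60 -40 0.21 62.0 10.8 179.0 11.3 178.0 12.5 180.0 13.0
ARG -60 -40 0.44 -66.0 10.3 179.0 11.6 178.0 12.8 -178.0 13.3
ARG -60 -40 0.34 -177.0 10.6 178.0 11.9 179.0 13.1 179.0 13.6
ARG -60 -40 0.22 63.0 10.9 -179.0 11.4 177.0 12.6 90.0 13.1
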