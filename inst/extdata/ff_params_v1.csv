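# confdesign self-consistent nonbonded parameter table, version 1.
# Lookup by atom name first (rows with class "name"), then element fallback
# (class "element"). lj_radius is the unscaled R0/2 per-atom radius (A);
# the design energy function scales radii by 0.9 before combining.
# charge in elementary charges; donor/acceptor flag hydrogen-bond roles;
# solv_coeff (kcal/mol/A^3) and solv_refvol (A^3) parameterize the
# occlusion solvation kernel.
class,key,lj_radius,lj_eps,charge,donor,acceptor,solv_coeff,solv_refvol
name,N,1.83,0.16,-0.47,1,0,0.010,15.0
name,CA,2.05,0.095,0.07,0,0,0.004,20.0
name,C,1.95,0.12,0.51,0,0,0.004,16.0
name,O,1.66,0.21,-0.51,0,1,0.012,14.0
name,OXT,1.66,0.21,-0.57,0,1,0.012,14.0
name,CB,2.05,0.095,0.00,0,0,0.004,22.0
name,OG,1.70,0.21,-0.54,1,1,0.012,14.0
name,OG1,1.70,0.21,-0.54,1,1,0.012,14.0
name,OH,1.70,0.21,-0.54,1,1,0.012,14.0
name,OD1,1.66,0.21,-0.50,0,1,0.012,14.0
name,OD2,1.66,0.21,-0.50,0,1,0.012,14.0
name,OE1,1.66,0.21,-0.50,0,1,0.012,14.0
name,OE2,1.66,0.21,-0.50,0,1,0.012,14.0
name,ND1,1.83,0.16,-0.36,1,1,0.010,15.0
name,ND2,1.83,0.16,-0.47,1,0,0.010,15.0
name,NE,1.83,0.16,-0.45,1,0,0.010,15.0
name,NE1,1.83,0.16,-0.42,1,0,0.010,15.0
name,NE2,1.83,0.16,-0.42,1,1,0.010,15.0
name,NZ,1.83,0.16,-0.30,1,0,0.010,15.0
name,NH1,1.83,0.16,-0.45,1,0,0.010,15.0
name,NH2,1.83,0.16,-0.45,1,0,0.010,15.0
name,SD,2.09,0.32,-0.10,0,1,0.006,25.0
name,SG,2.09,0.32,-0.23,1,1,0.006,25.0
element,C,2.05,0.095,0.00,0,0,0.004,22.0
element,N,1.83,0.16,-0.40,1,1,0.010,15.0
element,O,1.66,0.21,-0.50,0,1,0.012,14.0
element,S,2.09,0.32,-0.10,1,1,0.006,25.0
element,H,0.90,0.02,0.30,0,0,0.000,4.0
element,P,2.10,0.30,0.80,0,0,0.004,26.0
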