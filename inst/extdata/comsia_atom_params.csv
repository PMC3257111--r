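# Per-element parameters for CoMSIA atomic property weights.
# vdw_radius (Angstrom, Bondi) feeds the steric weight (volume relative to
# carbon); hydrophobicity is a coarse element-based increment (sign convention:
# positive = lipophilic). Both tables are editable and overridable from code.
element,vdw_radius,hydrophobicity
H,1.20,0.12
C,1.70,0.36
N,1.55,-0.60
O,1.52,-0.40
F,1.47,0.22
P,1.80,-0.20
S,1.80,0.26
Cl,1.75,0.65
Br,1.85,0.85
I,1.98,1.05
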