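# Per-residue solvent interaction energies eps_{a,solv} (reduced units).
# Positive exactly for the nine hydrophobic residue types (the model
# definition of hydrophobicity), scaled as 0.95 * sigma_a from the same
# transfer scale as the pair table; calibrated together with it.
residue	epsilon_solv
A	0.2945
C	1.463
D	0
E	0
F	1.7005
G	0
H	0
I	1.71
K	0
L	1.615
M	1.1685
N	0
P	0
Q	0
R	0
S	0
T	0
V	1.159
W	2.1375
Y	0.912
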