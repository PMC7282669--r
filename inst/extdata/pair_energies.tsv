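# Pairwise contact energies eps_{a_i,a_j} (reduced units per side-chain-
# directed lattice contact).  Derived as eps_ij = -0.50 * sigma_i * sigma_j
# from an octanol-water side-chain transfer hydrophobicity scale restricted
# to the nine hydrophobic residue types {C,F,L,W,V,I,M,Y,A} (sigma = 0
# otherwise), so that eps_FF < eps_LL < 0.  The prefactor was calibrated
# once, together with the solvent scale and eps_hb, so that the TFTFTFT
# fibril is stable over an intermediate temperature window when the
# hydrophobic temperature dependence is switched off, heat-denatures into
# monomers at high temperature, and with alpha = 60 cold-denatures into
# monomers just below the stability window.  Editable.
aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.0481	-0.2387	0.0000	0.0000	-0.2775	0.0000	0.0000	-0.2790	0.0000	-0.2635	-0.1906	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-0.1891	-0.3488	-0.1488
C	-0.2387	-1.1858	0.0000	0.0000	-1.3783	0.0000	0.0000	-1.3860	0.0000	-1.3090	-0.9471	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-0.9394	-1.7325	-0.7392
D	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
E	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
F	-0.2775	-1.3783	0.0000	0.0000	-1.6020	0.0000	0.0000	-1.6110	0.0000	-1.5215	-1.1009	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-1.0919	-2.0138	-0.8592
G	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
H	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
I	-0.279	-1.386	0.000	0.000	-1.611	0.000	0.000	-1.620	0.000	-1.530	-1.107	0.000	0.000	0.000	0.000	0.000	0.000	-1.098	-2.025	-0.864
K	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
L	-0.2635	-1.3090	0.0000	0.0000	-1.5215	0.0000	0.0000	-1.5300	0.0000	-1.4450	-1.0455	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-1.0370	-1.9125	-0.8160
M	-0.1906	-0.9471	0.0000	0.0000	-1.1009	0.0000	0.0000	-1.1070	0.0000	-1.0455	-0.7564	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-0.7503	-1.3838	-0.5904
N	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
P	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Q	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
R	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
S	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
T	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
V	-0.1891	-0.9394	0.0000	0.0000	-1.0919	0.0000	0.0000	-1.0980	0.0000	-1.0370	-0.7503	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-0.7442	-1.3725	-0.5856
W	-0.3488	-1.7325	0.0000	0.0000	-2.0138	0.0000	0.0000	-2.0250	0.0000	-1.9125	-1.3838	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-1.3725	-2.5312	-1.0800
Y	-0.1488	-0.7392	0.0000	0.0000	-0.8592	0.0000	0.0000	-0.8640	0.0000	-0.8160	-0.5904	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	-0.5856	-1.0800	-0.4608
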