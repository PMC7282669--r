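# Default scalar model parameters (reduced units, k_B = 1), calibrated
# together with the pair and solvent tables (see their headers).
eps_hb -1.60         # energy per inter-strand hydrogen bond
n_beta 2.718281828459045   # beta-strand propensity; state penalty ln(N_beta) = 1 per beta residue
steric_penalty 2.0   # per pair of side chains pointing at the same site
alpha 0.0            # hydrophobic temperature-dependence strength (swept in analyses)
t0 0.4               # optimum temperature of the hydrophobic effect
box 20               # box edge length in lattice sites
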