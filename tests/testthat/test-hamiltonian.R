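single_chain_system <- function(seq_str = "TFTFTFT", dir = 4L, box = 20) {
  s <- peptide_sequence(seq_str)
  L <- length(s)
  ch <- fibrilMC:::new_chain(cbind(seq_len(L) + 1L, 2L, 2L), rep(dir, L),
                             rep(FALSE, L), FALSE)
  lattice_system(s, list(ch), box)
}

strand_pair_system <- function(dir2 = 4L, beta = TRUE) {
  s <- peptide_sequence("TFTFTFT")
  ch1 <- fibrilMC:::new_chain(cbind(1:7, 2L, 2L), rep(4L, 7),
                              rep(beta, 7), FALSE)
  ch2 <- fibrilMC:::new_chain(cbind(1:7, 3L, 2L), rep(dir2, 7),
                              rep(beta, 7), FALSE)
  lattice_system(s, list(ch1, ch2), box = 20)
}

test_that("solvation term sums exposure energies with the hydrophobic law", {
  sys <- single_chain_system()
  tb <- toy_tables(eps_f_solv = 1)
  expect_equal(phi_solvent(sys, tb, hydrophobic_params(0), 1), 3,
               tolerance = 1e-8)
  expect_equal(phi_solvent(sys, tb, hydrophobic_params(60, 0.4), 0.25),
               3 * (1 - 1.35), tolerance = 1e-8)
  # fully buried fibrillar reference: no exposure at all
  fib <- reference_fibrillar_state(build_seed(peptide_sequence("TFTFTFT")))
  expect_equal(phi_solvent(fib, tb, hydrophobic_params(60), 0.25), 0)
  expect_error(phi_solvent(sys, tb, hydrophobic_params(60), -1), "positive")
})

test_that("hydrogen bonds require beta, alignment and perpendicularity", {
  tb <- toy_tables(eps_hb = -1)
  expect_equal(hb_energy(strand_pair_system(dir2 = 4L), tb), -7)
  expect_equal(hb_energy(strand_pair_system(dir2 = 5L), tb), 0)  # anti-aligned
  expect_equal(hb_energy(strand_pair_system(dir2 = 4L, beta = FALSE), tb), 0)
  # dissociated free chains form no bonds: docking one layer adds exactly
  # 14 bonds (7 per strand to the seed layer below) over the seed-internal
  # constant
  sys <- build_seed(peptide_sequence("TFTFTFT"))
  mono <- reference_monomeric_state(sys)
  fib <- reference_fibrillar_state(sys)
  expect_equal(hb_energy(fib, tb) - hb_energy(mono, tb), -14)
})

test_that("beta-state penalty is ln(N_beta) per strand residue", {
  sysb <- strand_pair_system()  # 14 beta residues
  expect_equal(state_energy(sysb, toy_tables(n_beta = exp(1))), 14)
  expect_equal(state_energy(sysb, toy_tables(n_beta = 1)), 0)
  expect_equal(state_energy(single_chain_system(), toy_tables()), 0)
})

test_that("pair energy matches an independent contact-count oracle", {
  tb <- toy_tables(eps_ff = -1)
  expect_equal(pair_energy(single_chain_system(), tb), 0)
  sys <- build_seed(peptide_sequence("TFTFTFT"))
  for (s in list(reference_fibrillar_state(sys),
                 reference_monomeric_state(sys))) {
    expect_equal(pair_energy(s, tb), pair_energy_oracle(s, tb))
  }
  # every docked layer interface buries 3 F-F pairs: seed (4 layers) + the
  # docked free layer give 5 interfaces
  expect_equal(pair_energy(reference_fibrillar_state(sys), tb), -15)
  # table symmetry is enforced at construction
  m <- matrix(0, 20, 20); m[1, 2] <- 1
  expect_error(interaction_tables(m, stats::setNames(rep(1, 20),
               fibrilMC:::AA_ALPHABET)), "symmetric")
})

test_that("breakdown sums to the total and splits off the solvent term", {
  tb <- default_tables()
  hp <- hydrophobic_params(60)
  sys <- build_seed(peptide_sequence("TFTFTFT"))
  for (s in list(sys, reference_fibrillar_state(sys),
                 reference_monomeric_state(sys))) {
    e <- total_energy(s, tb, hp, t = c(0.2, 0.3, 0.5))
    expect_equal(e$total,
                 e$e_hb + e$e_steric + e$e_state + e$e_aa + e$phi_solvent)
    expect_equal(e$e_int, e$total - e$phi_solvent)
    # temperature enters only through the solvation term
    expect_equal(e$total[1] - e$total[3],
                 e$phi_solvent[1] - e$phi_solvent[3])
    expect_equal(e$e_int[1], e$e_int[2])
  }
})

test_that("energy is invariant under rigid translation of the system", {
  tb <- default_tables()
  sys <- reference_fibrillar_state(build_seed(peptide_sequence("TFTFTFT")))
  shifted <- sys
  for (i in seq_along(shifted$chains))
    shifted$chains[[i]]$pos <- shifted$chains[[i]]$pos +
      rep(c(-2L, 1L, 2L), each = 7)
  e1 <- total_energy(sys, tb, hydrophobic_params(40), 0.3)
  e2 <- total_energy(shifted, tb, hydrophobic_params(40), 0.3)
  expect_equal(e1$total, e2$total)
  expect_equal(e1$e_hb, e2$e_hb)
})

test_that("steric penalty counts side chains aimed at the same site", {
  s <- peptide_sequence("TT")
  # two chains whose first residues point at the same empty site
  ch1 <- fibrilMC:::new_chain(cbind(c(2L, 2L), c(2L, 3L), 2L),
                              c(0L, 4L), c(FALSE, FALSE), FALSE)
  ch2 <- fibrilMC:::new_chain(cbind(c(4L, 4L), c(2L, 3L), 2L),
                              c(1L, 4L), c(FALSE, FALSE), FALSE)
  sys <- lattice_system(s, list(ch1, ch2), box = 10)
  expect_equal(steric_energy(sys, toy_tables(steric = 2)), 2)
  expect_equal(steric_energy(sys, toy_tables(steric = 5)), 5)
})
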