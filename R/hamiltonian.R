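energy_raw <- function(system, tables, hparams = hydrophobic_params(0),
                       t = 1) {
  stopifnot(inherits(system, "lattice_system"),
            inherits(tables, "interaction_tables"))
  a <- sys_arrays(system)
  cpp_energy(a$pos, a$dir, a$beta, a$chain, a$frozen, a$aa, a$box,
             unname(tables$pair), unname(tables$solvent),
             tables$eps_hb, log(tables$n_beta), tables$steric_penalty,
             hparams$alpha, hparams$t0, as.numeric(t))
}

#' Temperature-dependent solvation energy
#'
#' The solvent term of the Hamiltonian:
#' `Phi_solvent(T) = sum_i (F_hydr(i) + eps_{a_i,solv}) K_{i,solv}`, where
#' `K_{i,solv} = 1` when residue `i`'s side chain points at an unoccupied
#' site and `F_hydr` is the parabolic hydrophobic free energy (only for
#' hydrophobic residues).
#'
#' @param system A [lattice_system()].
#' @param tables An [interaction_tables()].
#' @param hparams A [hydrophobic_params()].
#' @param t Temperature (`> 0`); vectorised.
#' @return Solvation energy at each temperature.
#' @export
phi_solvent <- function(system, tables, hparams, t) {
  check_temperature(t)
  e <- energy_raw(system, tables, hparams, t)
  e$phi_solvent
}

#' Hydrogen-bond energy
#'
#' `eps_hb` times the number of unordered residue pairs on different chains
#' at unit distance, both in the beta state, with identical side-chain
#' directions perpendicular to their separation vector.
#'
#' @inheritParams phi_solvent
#' @return Hydrogen-bond energy (scalar).
#' @export
hb_energy <- function(system, tables) {
  energy_raw(system, tables)$e_hb
}

#' Beta-state energy
#'
#' The temperature-independent chain-entropy penalty `log(N_beta)` per
#' residue in the beta-strand state (a beta residue gives up `N_beta`
#' coil-like substates).
#'
#' @inheritParams phi_solvent
#' @return State energy (scalar).
#' @export
state_energy <- function(system, tables) {
  energy_raw(system, tables)$e_state
}

#' Pairwise amino-acid contact energy
#'
#' Sum of `eps_{a_i,a_j}` over unordered residue pairs at unit lattice
#' distance that belong to different molecules or are non-adjacent along the
#' chain.
#'
#' @inheritParams phi_solvent
#' @return Contact energy (scalar).
#' @export
pair_energy <- function(system, tables) {
  energy_raw(system, tables)$e_aa
}

#' Side-chain steric energy
#'
#' `steric_penalty` per unordered pair of side chains pointing at the same
#' lattice site.  (Backbone excluded volume is a hard constraint of the
#' sampler, not an energy term.)
#'
#' @inheritParams phi_solvent
#' @return Steric energy (scalar).
#' @export
steric_energy <- function(system, tables) {
  energy_raw(system, tables)$e_steric
}

#' Full energy breakdown of a configuration
#'
#' Evaluates the five Hamiltonian terms
#' `H = E_hb + E_steric + E_state + E_aa + Phi_solvent(T)` and the
#' temperature-independent / temperature-dependent split
#' `H = E_int + Phi_solvent(T)`.  Temperature enters only through the
#' solvation term.
#'
#' @inheritParams phi_solvent
#' @return An object of class `energy_breakdown`: a list with `e_hb`,
#'   `e_steric`, `e_state`, `e_aa`, `phi_solvent`, `total`, `e_int`
#'   (`= total - phi_solvent`), the enthalpy estimator `e_est` and the
#'   temperature(s) used.
#' @export
total_energy <- function(system, tables, hparams = hydrophobic_params(0),
                         t = 1) {
  check_temperature(t)
  e <- energy_raw(system, tables, hparams, t)
  structure(list(e_hb = e$e_hb, e_steric = e$e_steric, e_state = e$e_state,
                 e_aa = e$e_aa, phi_solvent = e$phi_solvent,
                 total = e$total,
                 e_int = e$total - e$phi_solvent,
                 e_est = e$e_est,
                 c_h_exposed_all = e$c_h_exposed_all,
                 temperature = as.numeric(t)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "H = %g at T = %g  (hb %g, steric %g, state %g, aa %g, solvent %g)\n",
    x$total[1], x$temperature[1], x$e_hb, x$e_steric, x$e_state, x$e_aa,
    x$phi_solvent[1]))
  invisible(x)
}
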