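# shared fixtures: toy systems, toy tables and cached simulation runs

std_system <- function() build_seed(peptide_sequence("TFTFTFT"))

# a small frozen strand plus one free 3-mer in a tiny box; enumerable
toy_system <- function(box = 4, seq_str = "TFT") {
  s <- peptide_sequence(seq_str)
  L <- length(s)
  frozen <- fibrilMC:::new_chain(cbind(seq_len(L), 1L, 1L), rep(2L, L),
                                 rep(TRUE, L), TRUE)
  free <- fibrilMC:::new_chain(cbind(seq_len(L), box - 1L, box - 1L),
                               rep(4L, L), rep(FALSE, L), FALSE)
  lattice_system(s, list(frozen, free), box, native_max = L)
}

# toy interaction tables with a single tunable F-F contact and F solvation
toy_tables <- function(eps_ff = 0, eps_f_solv = 1, eps_hb = -1,
                       n_beta = exp(1), steric = 2) {
  pair <- matrix(0, 20, 20, dimnames = list(fibrilMC:::AA_ALPHABET,
                                            fibrilMC:::AA_ALPHABET))
  pair["F", "F"] <- eps_ff
  solv <- stats::setNames(rep(0, 20), fibrilMC:::AA_ALPHABET)
  solv[fibrilMC:::HYDROPHOBIC_SET] <- 1e-9   # flag hydrophobicity
  solv["F"] <- eps_f_solv
  interaction_tables(pair, solv, eps_hb = eps_hb, n_beta = n_beta,
                     steric_penalty = steric)
}

no_seed_moves <- function() {
  w <- fibrilMC:::default_move_weights()
  w[c("seed_translate", "seed_rotate")] <- 0
  w
}

# independent R oracle: count unit-distance residue pairs of a system that
# satisfy the side-chain-directed pair-interaction rule, weighted by the table
pair_energy_oracle <- function(system, tables) {
  chains <- system$chains
  L <- length(system$sequence)
  res <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    data.frame(chain = ci, idx = seq_len(L), x = ch$pos[, 1], y = ch$pos[, 2],
               z = ch$pos[, 3], dir = ch$dir,
               aa = system$sequence$residues)
  }))
  dv <- fibrilMC:::DIR_VECS
  e <- 0
  for (i in seq_len(nrow(res) - 1L)) for (j in (i + 1L):nrow(res)) {
    d <- c(res$x[j] - res$x[i], res$y[j] - res$y[i], res$z[j] - res$z[i])
    if (sum(abs(d)) != 1L) next
    if (res$chain[i] == res$chain[j] && abs(res$idx[i] - res$idx[j]) <= 1L)
      next
    ok_i <- all(dv[res$dir[i] + 1L, ] == d)
    ok_j <- all(dv[res$dir[j] + 1L, ] == -d)
    if (ok_i && ok_j) e <- e + tables$pair[res$aa[i], res$aa[j]]
  }
  e
}

# cached expensive simulation runs, shared across acceptance tests
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

strict_thresholds <- function()
  state_thresholds(mono_max_cext = 0, fib_native_fraction = 1)

restrained_curve <- function(alpha, temps = seq(0.225, 0.425, by = 0.05),
                             sweeps = 8000, seed = 101) {
  cached_run(sprintf("restr-%g", alpha), function() {
    sys <- std_system()
    tb <- default_tables()
    cfg <- mc_config(temperatures = temps, sweeps = sweeps,
                     equilibration_sweeps = sweeps %/% 4, rng_seed = seed)
    hp <- hydrophobic_params(alpha)
    fib <- run_elongation(sys, tb, hp, cfg, restrict = "fibrillar",
                          thresholds = strict_thresholds())
    mono <- run_elongation(sys, tb, hp, cfg, restrict = "monomeric",
                           thresholds = strict_thresholds())
    elongation_curves_restrained(fib, mono)
  })
}

diagram_run <- function(alpha, sweeps = 30000, seed = 11) {
  cached_run(sprintf("diag-%g", alpha), function() {
    run_elongation(std_system(), default_tables(), hydrophobic_params(alpha),
                   mc_config(sweeps = sweeps,
                             equilibration_sweeps = sweeps %/% 4,
                             rng_seed = seed))
  })
}

rigid_run <- function() {
  cached_run("rigid", function()
    run_elongation(std_system(), default_tables(), hydrophobic_params(0),
                   mc_config(temperatures = c(0.3, 0.5), sweeps = 3000,
                             equilibration_sweeps = 500, rng_seed = 4),
                   init = "current"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
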