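MOVE_TYPES <- c("end_rotation", "corner_flip", "crankshaft", "side_dir",
                "beta_flip", "chain_translate", "chain_jump", "chain_rotate",
                "seed_translate", "seed_rotate")

default_move_weights <- function() {
  stats::setNames(c(0.12, 0.12, 0.08, 0.22, 0.14, 0.10, 0.08, 0.06,
                    0.05, 0.03), MOVE_TYPES)
}

#' Monte Carlo sampling configuration
#'
#' Desk-scale defaults: 17 temperatures spanning the fibril stability window
#' and both denaturation transitions, 4e4 sweeps with the first quarter
#' discarded, parallel tempering on.  One sweep attempts `3 * n_free + 4`
#' moves, where `n_free` is the number of free-chain residues.
#'
#' @param temperatures Ascending grid of reduced temperatures (`> 0`).
#' @param sweeps Total sweeps per temperature.
#' @param equilibration_sweeps Initial sweeps discarded before sampling.
#' @param sample_interval Sweeps between recorded samples.
#' @param rng_seed Integer seed of the deterministic sampler RNG.
#' @param replica_exchange Attempt parallel-tempering swaps between adjacent
#'   temperatures.
#' @param pt_interval Sweeps between swap attempts.
#' @param move_weights Named numeric vector of proposal probabilities for the
#'   ten move types (normalised internally).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(temperatures = seq(0.15, 0.55, by = 0.025),
                      sweeps = 40000, equilibration_sweeps = 10000,
                      sample_interval = 10, rng_seed = 1,
                      replica_exchange = TRUE, pt_interval = 10,
                      move_weights = default_move_weights()) {
  temperatures <- as.numeric(temperatures)
  stopifnot(length(temperatures) >= 1, all(temperatures > 0),
            !is.unsorted(temperatures), sweeps > equilibration_sweeps,
            equilibration_sweeps >= 0, sample_interval >= 1,
            length(move_weights) == length(MOVE_TYPES),
            all(move_weights >= 0), sum(move_weights) > 0)
  structure(list(temperatures = temperatures, sweeps = as.integer(sweeps),
                 equilibration_sweeps = as.integer(equilibration_sweeps),
                 sample_interval = as.integer(sample_interval),
                 rng_seed = as.integer(rng_seed),
                 replica_exchange = isTRUE(replica_exchange),
                 pt_interval = as.integer(pt_interval),
                 move_weights = move_weights),
            class = "mc_config")
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf(
    "MC config: %d temperatures in [%g, %g], %d sweeps (%d equilibration), seed %d, PT %s\n",
    length(x$temperatures), min(x$temperatures), max(x$temperatures),
    x$sweeps, x$equilibration_sweeps, x$rng_seed,
    if (x$replica_exchange) "on" else "off"))
  invisible(x)
}

#' Run the elongation simulation
#'
#' Metropolis Monte Carlo of the free chains against the frozen seed at each
#' temperature of the grid (optionally coupled by parallel tempering).
#' Acceptance uses the full temperature-dependent Hamiltonian `H(T)` (the
#' solvation term is a potential of mean force); each recorded sample also
#' carries the enthalpy estimator `e_est`, the beta-derivative of `beta*H`,
#' which is the correct mean-energy observable when the Hamiltonian depends
#' on temperature (it equals `H` exactly when `alpha = 0`).
#'
#' @param system A [lattice_system()].
#' @param tables An [interaction_tables()].
#' @param hparams A [hydrophobic_params()].
#' @param config An [mc_config()].
#' @param init Replica initialisation. `"mixed"` (default for elongation
#'   runs) starts alternating replicas from the fibrillar and monomeric
#'   reference states, so that replica exchange supplies both basins to
#'   every temperature — a two-sided protocol for a strongly first-order
#'   transition whose spontaneous docking time exceeds any desk-scale run.
#'   `"current"` starts every replica from the system's current
#'   configuration (required for toy systems without a docked reference).
#' @param restrict Optional basin restraint: `"fibrillar"` (reject moves
#'   dropping below the fibrillar native-contact threshold) or
#'   `"monomeric"` (reject moves exceeding the monomeric contact
#'   threshold).  Restrained runs sample the conditional ensemble of one
#'   basin across the whole temperature grid, which is how the per-basin
#'   enthalpy means entering the elongation enthalpy difference are
#'   measured (see [elongation_curves_restrained()]).
#' @param thresholds [state_thresholds()] used by the basin restraint.
#' @return An object of class `mc_samples`: list with `samples` (data.frame:
#'   temperature, sweep, c_ext, native_contacts, native_fraction,
#'   c_h_exposed, the energy components, total and e_est), `move_stats`,
#'   `swap_rate`, `energy_drift`, `final_states`, and the inputs.
#' @export
run_elongation <- function(system, tables, hparams, config = mc_config(),
                           init = c("mixed", "current"),
                           restrict = c("none", "fibrillar", "monomeric"),
                           thresholds = state_thresholds()) {
  stopifnot(inherits(system, "lattice_system"),
            inherits(tables, "interaction_tables"),
            inherits(hparams, "hydrophobic_params"),
            inherits(config, "mc_config"))
  init <- match.arg(init)
  restrict <- match.arg(restrict)
  if (restrict == "fibrillar") {
    sys_a <- sys_b <- reference_fibrillar_state(system)
    use_b <- rep(FALSE, length(config$temperatures))
  } else if (restrict == "monomeric") {
    sys_a <- sys_b <- reference_monomeric_state(system)
    use_b <- rep(FALSE, length(config$temperatures))
  } else if (init == "mixed") {
    sys_a <- reference_fibrillar_state(system)
    sys_b <- reference_monomeric_state(system)
    use_b <- seq_along(config$temperatures) %% 2L == 0L
  } else {
    sys_a <- sys_b <- system
    use_b <- rep(FALSE, length(config$temperatures))
  }
  restrict_mode <- match(restrict, c("none", "fibrillar", "monomeric")) - 1L
  fib_native_min <- if (is.na(system$native_max)) 0L
                    else as.integer(ceiling(thresholds$fib_native_fraction *
                                            system$native_max))
  a <- sys_arrays(sys_a)
  b <- sys_arrays(sys_b)
  res <- cpp_run_mc(a$pos, a$dir, a$beta, a$chain, a$frozen, a$aa, a$box,
                    unname(tables$pair), unname(tables$solvent),
                    tables$eps_hb, log(tables$n_beta),
                    tables$steric_penalty, hparams$alpha, hparams$t0,
                    config$temperatures, config$sweeps,
                    config$equilibration_sweeps, config$sample_interval,
                    if (config$replica_exchange) config$pt_interval else 0L,
                    unname(config$move_weights), config$rng_seed,
                    b$pos, b$dir, b$beta, use_b, restrict_mode,
                    fib_native_min, as.integer(thresholds$mono_max_cext))
  samples <- as.data.frame(res$samples)
  samples$native_fraction <- if (is.na(system$native_max)) NA_real_
                             else samples$native_contacts / system$native_max
  move_stats <- data.frame(
    move = MOVE_TYPES,
    attempts = res$move_attempts,
    accepts = res$move_accepts,
    acceptance_rate = ifelse(res$move_attempts > 0,
                             res$move_accepts / res$move_attempts, NA_real_))
  structure(list(samples = samples, move_stats = move_stats,
                 swap_attempts = res$swap_attempts,
                 swap_rate = if (res$swap_attempts > 0)
                   res$swap_accepts / res$swap_attempts else NA_real_,
                 moves_per_sweep = res$moves_per_sweep,
                 energy_drift = res$energy_drift,
                 final_states = res$final_states,
                 config = config, hparams = hparams,
                 native_max = system$native_max),
            class = "mc_samples")
}

#' @export
print.mc_samples <- function(x, ...) {
  cat(sprintf(
    "MC samples: %d rows over %d temperatures (seed %d); swap rate %.2f; energy drift %.2e\n",
    nrow(x$samples), length(unique(x$samples$temperature)),
    x$config$rng_seed, x$swap_rate, x$energy_drift))
  invisible(x)
}

#' Enthalpy estimator of a configuration
#'
#' With a temperature-dependent Hamiltonian the mean energy is not `<H>` but
#' `d(beta H)/d(beta)`.  For the parabolic hydrophobic term this evaluates to
#' the temperature-independent part of the Hamiltonian plus
#' `e_hydr = -alpha (T0^2 - T^2)` per solvent-exposed hydrophobic side chain.
#' At `alpha = 0` the estimator equals the total energy exactly.
#'
#' @inheritParams phi_solvent
#' @return The enthalpy estimate at each temperature in `t`.
#' @export
enthalpy_estimator <- function(system, tables, hparams, t) {
  check_temperature(t)
  energy_raw(system, tables, hparams, t)$e_est
}

#' Sweep a model parameter over a grid of simulations
#'
#' Re-runs [run_elongation()] for each value of `alpha`, `eps_hb` or
#' `n_beta`, with a reproducible sub-seed per cell derived from the base
#' configuration seed.  Failures in individual cells are caught and reported
#' in the result rather than aborting the sweep.
#'
#' @inheritParams run_elongation
#' @param param One of `"alpha"`, `"eps_hb"`, `"n_beta"`.
#' @param values Numeric grid of parameter values.
#' @return An object of class `mc_sweep`: named list of `mc_samples` (or
#'   the error condition for failed cells) per value, with attributes
#'   `param` and `values`.
#' @export
sweep_parameters <- function(system, tables, hparams, config = mc_config(),
                             param = c("alpha", "eps_hb", "n_beta"),
                             values, init = c("mixed", "current")) {
  init <- match.arg(init)
  param <- match.arg(param)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  out <- vector("list", length(values))
  names(out) <- as.character(values)
  for (i in seq_along(values)) {
    tb <- tables
    hp <- hparams
    if (param == "alpha") hp <- hydrophobic_params(values[i], hparams$t0)
    else if (param == "eps_hb") tb$eps_hb <- values[i]
    else tb$n_beta <- values[i]
    cfg <- config
    cfg$rng_seed <- as.integer((config$rng_seed + 7919 * i) %% 2147483647L)
    out[[i]] <- tryCatch(run_elongation(system, tb, hp, cfg, init = init),
                         error = function(e) {
                           warning(sprintf("cell %s = %g failed: %s", param,
                                           values[i], conditionMessage(e)))
                           e
                         })
  }
  structure(out, param = param, values = values, class = "mc_sweep")
}

#' Exhaustively enumerate a one-free-chain toy system
#'
#' Enumerates every configuration (self-avoiding backbone placement,
#' side-chain directions and beta flags) of the single free chain in the
#' presence of the frozen chains, aggregated by energy components and order
#' parameters.  Serves as the exact reference distribution against which the
#' Monte Carlo sampler is validated.  Supports free chains of length
#' `<= 4`; intended for small boxes.
#'
#' @inheritParams phi_solvent
#' @return A data.frame with one row per distinct
#'   (energy components, order parameters) class and its `multiplicity`.
#' @export
enumerate_states <- function(system, tables, hparams = hydrophobic_params(0)) {
  stopifnot(inherits(system, "lattice_system"),
            inherits(tables, "interaction_tables"))
  a <- sys_arrays(system)
  cpp_enumerate(a$pos, a$dir, a$beta, a$chain, a$frozen, a$aa, a$box,
                unname(tables$pair), unname(tables$solvent),
                tables$eps_hb, log(tables$n_beta), tables$steric_penalty,
                hparams$alpha, hparams$t0)
}

#' Boltzmann probabilities from an enumeration
#'
#' Forms `P(state class) = multiplicity * exp(-H(T)/T) / Z` from the output
#' of [enumerate_states()], at the requested temperature.
#'
#' @param enum Output of [enumerate_states()].
#' @param hparams The [hydrophobic_params()] used for the enumeration.
#' @param t Temperature (`> 0`, scalar).
#' @return `enum` with additional columns `energy` and `prob`.
#' @export
enum_probabilities <- function(enum, hparams, t) {
  check_temperature(t)
  stopifnot(length(t) == 1L)
  H <- enum$e_hb + enum$e_steric + enum$e_state + enum$e_aa +
    enum$solvent_const -
    hparams$alpha * (t - hparams$t0)^2 * enum$c_h_exposed_all
  w <- enum$multiplicity * exp(-(H - min(H)) / t)
  enum$energy <- H
  enum$prob <- w / sum(w)
  enum
}
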