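STATE_LEVELS <- c("monomeric", "amorphous", "fibrillar", "fully_aggregated")

#' State-classification thresholds
#'
#' Concretisation of the contact-based state definitions: a configuration is
#' monomeric when the free chains make at most `mono_max_cext` external
#' contacts, fibrillar when at least a fraction `fib_native_fraction` of the
#' in-register reference contacts are formed, and fully aggregated when in
#' addition all reference contacts are present (both chains docked).
#' Everything else is amorphous.
#'
#' @param mono_max_cext Maximum `c_ext` of the monomeric state.
#' @param fib_native_fraction Minimum native fraction of the fibrillar state.
#' @param full_cext `c_ext` of the fully formed layer.
#' @return A list of thresholds.
#' @export
state_thresholds <- function(mono_max_cext = 1, fib_native_fraction = 18 / 21,
                             full_cext = 21) {
  list(mono_max_cext = mono_max_cext,
       fib_native_fraction = fib_native_fraction, full_cext = full_cext)
}

#' Classify configurations into the four elongation states
#'
#' @param c_ext Integer vector of external contact counts (or a list/
#'   data.frame with columns `c_ext` and `native_fraction`, in which case
#'   `native_fraction` is taken from it).
#' @param native_fraction Numeric vector of native-contact fractions.
#' @param thresholds A [state_thresholds()] list.
#' @return Factor with levels monomeric, amorphous, fibrillar,
#'   fully_aggregated.
#' @examples
#' classify_state(0, 0)        # monomeric
#' classify_state(21, 1)       # fully_aggregated
#' classify_state(10, 0.2)     # amorphous
#' @export
classify_state <- function(c_ext, native_fraction = NULL,
                           thresholds = state_thresholds()) {
  if (is.list(c_ext)) {
    native_fraction <- c_ext$native_fraction
    c_ext <- c_ext$c_ext
  }
  stopifnot(length(c_ext) == length(native_fraction))
  lab <- rep("amorphous", length(c_ext))
  fib <- !is.na(native_fraction) &
    native_fraction >= thresholds$fib_native_fraction
  lab[fib] <- "fibrillar"
  lab[fib & c_ext >= thresholds$full_cext &
        native_fraction >= 1 - 1e-9] <- "fully_aggregated"
  lab[c_ext <= thresholds$mono_max_cext] <- "monomeric"
  factor(lab, levels = STATE_LEVELS)
}

FIB_STATES <- c("fibrillar", "fully_aggregated")

samples_of <- function(x) {
  if (inherits(x, "mc_samples")) x$samples
  else as.data.frame(x)
}

#' Free-energy landscape over two order parameters
#'
#' `F(bin) = -T log P(bin)` from visitation counts at a single temperature;
#' unvisited bins are absent from the output and the minimum is shifted to
#' zero.
#'
#' @param samples An `mc_samples` object or its `samples` data.frame,
#'   restricted to one temperature (pass the temperature of interest via
#'   `t`).
#' @param t Temperature whose samples are histogrammed (must be present in
#'   the data; also sets the `T` of `-T log P`).
#' @param axes Character vector of two order-parameter column names.
#' @return A data.frame with the two axis values, `count`, `prob` and
#'   `free_energy` (minimum 0).
#' @export
free_energy_landscape <- function(samples, t,
                                  axes = c("c_ext", "c_h_exposed")) {
  df <- samples_of(samples)
  stopifnot(length(axes) == 2L, all(axes %in% names(df)))
  df <- df[abs(df$temperature - t) < 1e-9, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no samples at the requested temperature", call. = FALSE)
  tab <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df[axes], FUN = sum)
  tab$prob <- tab$count / sum(tab$count)
  tab$free_energy <- -t * log(tab$prob)
  tab$free_energy <- tab$free_energy - min(tab$free_energy)
  tab[order(tab[[1]], tab[[2]]), , drop = FALSE]
}

block_means <- function(x, n_blocks) {
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1L, n)
  idx <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  tapply(x, idx, mean)
}

#' Elongation thermodynamics from sampled trajectories
#'
#' Per temperature, the free-energy difference between the fibrillar basin
#' (native fraction above threshold) and the monomeric basin,
#' `dG = -T log(P_fib / P_mono)`, the enthalpy difference of the
#' beta-derivative estimator between the basins, and the entropic term as
#' their difference (`dG = dE + (-T dS)` by construction).  Errors are block
#' standard errors; temperatures where either basin has fewer than
#' `min_visits` samples are flagged `sampled = FALSE` and carry `NA`
#' estimates (mirroring the "state not observed" convention).
#'
#' @param samples An `mc_samples` object or its `samples` data.frame (must
#'   contain `native_fraction`).
#' @param thresholds A [state_thresholds()] list.
#' @param min_visits Minimum samples per basin for a temperature to be
#'   retained.
#' @param n_blocks Number of blocks for the error estimate.
#' @return An object of classes `thermo_curve`/`data.frame` with columns
#'   `temperature`, `delta_g`, `delta_e`, `minus_t_delta_s`, `se_delta_g`,
#'   `se_delta_e`, `n_fib`, `n_mono`, `sampled`.
#' @export
elongation_curves <- function(samples, thresholds = state_thresholds(),
                              min_visits = 50, n_blocks = 20) {
  df <- samples_of(samples)
  if (any(is.na(df$native_fraction)))
    stop("native_fraction undefined: system has no docked reference count",
         call. = FALSE)
  df$state <- classify_state(df$c_ext, df$native_fraction, thresholds)
  temps <- sort(unique(df$temperature))
  out <- lapply(temps, function(tt) {
    d <- df[df$temperature == tt, ]
    fib <- d$state %in% FIB_STATES
    mono <- d$state == "monomeric"
    n_fib <- sum(fib); n_mono <- sum(mono)
    row <- data.frame(temperature = tt, delta_g = NA_real_,
                      delta_e = NA_real_, minus_t_delta_s = NA_real_,
                      se_delta_g = NA_real_, se_delta_e = NA_real_,
                      n_fib = n_fib, n_mono = n_mono, sampled = FALSE)
    if (n_fib < min_visits || n_mono < min_visits) return(row)
    row$sampled <- TRUE
    row$delta_g <- -tt * log(n_fib / n_mono)
    e_fib <- mean(d$e_est[fib]); e_mono <- mean(d$e_est[mono])
    row$delta_e <- e_fib - e_mono
    row$minus_t_delta_s <- row$delta_g - row$delta_e
    # block errors (blocks over the time series)
    bf <- block_means(as.numeric(fib), n_blocks)
    bm <- block_means(as.numeric(mono), n_blocks)
    ok <- bf > 0 & bm > 0
    if (sum(ok) >= 2) {
      bg <- -tt * log(bf[ok] / bm[ok])
      row$se_delta_g <- stats::sd(bg) / sqrt(sum(ok))
    }
    ef <- block_means_cond(d$e_est, fib, n_blocks)
    em <- block_means_cond(d$e_est, mono, n_blocks)
    ok2 <- is.finite(ef) & is.finite(em)
    if (sum(ok2) >= 2) {
      be <- ef[ok2] - em[ok2]
      row$se_delta_e <- stats::sd(be) / sqrt(sum(ok2))
    }
    row
  })
  res <- do.call(rbind, out)
  class(res) <- c("thermo_curve", "data.frame")
  res
}

block_means_cond <- function(x, cond, n_blocks) {
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1L, n)
  idx <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  vapply(seq_len(n_blocks), function(b) {
    sel <- idx == b & cond
    if (any(sel)) mean(x[sel]) else NA_real_
  }, numeric(1))
}

#' Elongation enthalpy from basin-restrained runs
#'
#' The elongation enthalpy difference is the difference of the conditional
#' means of the enthalpy estimator between the fibrillar and monomeric
#' basins.  Restrained runs (see the `restrict` argument of
#' [run_elongation()]) sample each basin across the whole temperature
#' grid, so the difference is available at every temperature even deep in
#' one basin's stability region, where an unrestrained run never visits
#' the other basin.  The free-energy difference requires relative basin
#' weights and is not available from restrained runs (`delta_g = NA`).
#'
#' @param fib_run `mc_samples` from a `restrict = "fibrillar"` run.
#' @param mono_run `mc_samples` from a `restrict = "monomeric"` run over
#'   the same temperature grid.
#' @param n_blocks Number of blocks for the error estimate.
#' @return A `thermo_curve` data.frame with `delta_e` and `se_delta_e`
#'   per temperature (`delta_g`, `minus_t_delta_s` set to `NA`).
#' @export
elongation_curves_restrained <- function(fib_run, mono_run, n_blocks = 20) {
  df_f <- samples_of(fib_run)
  df_m <- samples_of(mono_run)
  temps <- sort(intersect(unique(df_f$temperature),
                          unique(df_m$temperature)))
  if (length(temps) == 0L)
    stop("runs share no temperatures", call. = FALSE)
  out <- lapply(temps, function(tt) {
    ef <- df_f$e_est[df_f$temperature == tt]
    em <- df_m$e_est[df_m$temperature == tt]
    bf <- block_means(ef, n_blocks)
    bm <- block_means(em, n_blocks)
    nb <- min(length(bf), length(bm))
    data.frame(temperature = tt, delta_g = NA_real_,
               delta_e = mean(ef) - mean(em),
               minus_t_delta_s = NA_real_, se_delta_g = NA_real_,
               se_delta_e = stats::sd(bf[seq_len(nb)] - bm[seq_len(nb)]) /
                 sqrt(nb),
               n_fib = length(ef), n_mono = length(em), sampled = TRUE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("thermo_curve", "data.frame")
  res
}

#' Heat capacity of elongation
#'
#' Centred finite-difference slope of the elongation enthalpy with respect to
#' temperature, `dCp = d(dE)/dT`, with propagated block errors.  Negative for
#' hydrophobically driven assembly (`-2 gamma T` for the parabolic model).
#'
#' @param curve A `thermo_curve` from [elongation_curves()] (or any
#'   data.frame with `temperature`, `delta_e` and optionally `se_delta_e`).
#' @return Data.frame with `temperature`, `delta_cp`, `se_delta_cp` at the
#'   interior grid points where both neighbours are sampled.
#' @export
heat_capacity <- function(curve) {
  d <- curve[!is.na(curve$delta_e), , drop = FALSE]
  if (nrow(d) < 3L)
    stop("heat capacity needs at least 3 sampled temperatures",
         call. = FALSE)
  d <- d[order(d$temperature), ]
  i <- 2:(nrow(d) - 1L)
  dt <- d$temperature[i + 1L] - d$temperature[i - 1L]
  slope <- (d$delta_e[i + 1L] - d$delta_e[i - 1L]) / dt
  se <- if ("se_delta_e" %in% names(d))
    sqrt(d$se_delta_e[i + 1L]^2 + d$se_delta_e[i - 1L]^2) / dt
  else rep(NA_real_, length(i))
  data.frame(temperature = d$temperature[i], delta_cp = slope,
             se_delta_cp = se)
}

#' State diagram from a parameter sweep
#'
#' Per (parameter value, temperature) cell, the modal state label of the
#' post-equilibration samples; cells with fewer than `min_samples` samples
#' are flagged unsampled, never interpolated.
#'
#' @param sweep An `mc_sweep` from [sweep_parameters()], or a named list of
#'   `mc_samples`.
#' @param thresholds A [state_thresholds()] list.
#' @param min_samples Minimum samples per cell.
#' @return An object of classes `state_diagram`/`data.frame` with columns
#'   `param`, `value`, `temperature`, `state`, `frac` (fraction of samples
#'   in the modal state), `n`, `sampled`.
#' @export
state_diagram <- function(sweep, thresholds = state_thresholds(),
                          min_samples = 10) {
  param <- attr(sweep, "param") %||% "value"
  values <- attr(sweep, "values") %||% seq_along(sweep)
  rows <- list()
  for (i in seq_along(sweep)) {
    run <- sweep[[i]]
    if (!inherits(run, "mc_samples")) {
      rows[[length(rows) + 1L]] <-
        data.frame(param = param, value = values[i],
                   temperature = NA_real_, state = NA_character_,
                   frac = NA_real_, n = 0L, sampled = FALSE)
      next
    }
    df <- run$samples
    df$state <- classify_state(df$c_ext, df$native_fraction, thresholds)
    for (tt in sort(unique(df$temperature))) {
      d <- df[df$temperature == tt, ]
      tab <- table(d$state)
      modal <- names(tab)[which.max(tab)]
      rows[[length(rows) + 1L]] <-
        data.frame(param = param, value = values[i], temperature = tt,
                   state = modal, frac = max(tab) / nrow(d), n = nrow(d),
                   sampled = nrow(d) >= min_samples)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("state_diagram", "data.frame")
  res
}

#' Cold-denaturation temperature of a simulated state profile
#'
#' Locates the fibrillar stability window of an elongation run and returns
#' the highest temperature below it at which the monomeric state is the
#' dominant (modal) state — the cold-denaturation temperature into
#' monomers.  The window is the contiguous temperature range, containing
#' the temperature of maximal fibrillar occupancy, over which the
#' fibrillar states outweigh the monomeric state; this is the occupancy
#' form of the stability criterion `dG = -T log(P_fib / P_mono) < 0`, and
#' it is insensitive to how much of the fibril basin's near-native fringe
#' the classification thresholds assign to the amorphous class.
#'
#' @param run An `mc_samples` object from [run_elongation()].
#' @param thresholds A [state_thresholds()] list.
#' @param t_max Upper end of the temperature grid considered.
#' @return The cold-denaturation temperature (`NA` if the fibrillar window
#'   or a monomer-dominated temperature below it does not exist), with the
#'   window bounds attached as attributes `window_lo` / `window_hi`.
#' @export
cold_denaturation_temperature <- function(run,
                                          thresholds = state_thresholds(),
                                          t_max = 0.45) {
  df <- samples_of(run)
  df <- df[df$temperature <= t_max + 1e-9, , drop = FALSE]
  df$state <- classify_state(df$c_ext, df$native_fraction, thresholds)
  occ_fib <- tapply(df$state %in% FIB_STATES, df$temperature, mean)
  occ_mono <- tapply(df$state == "monomeric", df$temperature, mean)
  tt <- as.numeric(names(occ_fib))
  stable <- occ_fib > occ_mono & occ_fib > 0.02
  if (!any(stable)) return(NA_real_)
  # contiguous block of fibril-stable temperatures around the occupancy peak
  peak <- which.max(occ_fib)
  lo_idx <- peak
  while (lo_idx > 1L && stable[lo_idx - 1L]) lo_idx <- lo_idx - 1L
  hi_idx <- peak
  while (hi_idx < length(tt) && stable[hi_idx + 1L]) hi_idx <- hi_idx + 1L
  lo <- tt[lo_idx]
  hi <- tt[hi_idx]
  ds <- dominant_states(run, thresholds)
  below <- ds$temperature[ds$temperature < lo - 1e-9 &
                            ds$temperature <= t_max + 1e-9 &
                            ds$state == "monomeric"]
  out <- if (length(below)) max(below) else NA_real_
  attr(out, "window_lo") <- lo
  attr(out, "window_hi") <- hi
  out
}

#' Dominant-state profile of a single run
#'
#' Convenience wrapper: modal state per temperature for one `mc_samples`
#' object.
#'
#' @inheritParams state_diagram
#' @param run An `mc_samples` object.
#' @return Data.frame with `temperature`, `state`, `frac`, `n`.
#' @export
dominant_states <- function(run, thresholds = state_thresholds()) {
  sw <- structure(list(run), param = "run", values = 1,
                  class = "mc_sweep")
  sd <- state_diagram(sw, thresholds)
  sd[, c("temperature", "state", "frac", "n")]
}
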