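#' Gas constant in kJ/(mol K)
#' @export
GAS_CONSTANT_KJ <- 8.314e-3

#' Calorimetric elongation-enthalpy curve
#'
#' Container for per-temperature molar elongation enthalpies (per-injection
#' heats already normalised per mole of monomer reacted).
#'
#' @param temperature Temperatures in kelvin (distinct).
#' @param delta_h Molar elongation enthalpy in kJ/mol.
#' @param sigma Optional per-point uncertainty (kJ/mol).
#' @return A data.frame of class `itc_curve`.
#' @export
itc_curve <- function(temperature, delta_h, sigma = NULL) {
  stopifnot(length(temperature) == length(delta_h),
            all(is.finite(temperature)), all(temperature > 0),
            !anyDuplicated(temperature))
  df <- data.frame(temperature = temperature, delta_h = delta_h)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(delta_h), all(sigma > 0))
    df$sigma <- sigma
  }
  class(df) <- c("itc_curve", "data.frame")
  df
}

#' Fit the hydrophobic temperature dependence to an enthalpy curve
#'
#' Weighted least squares of `dH(T) = gamma * (t0^2 - T^2) + e_int`, linear
#' in `(gamma, e_int)` with basis `{t0^2 - T^2, 1}` and solved exactly by the
#' normal equations (via [stats::lm()]).  The fitted heat capacity is
#' `dCp(T) = -2 gamma T`, negative whenever `gamma > 0`.
#'
#' @param curve An [itc_curve()] (or data.frame with `temperature`,
#'   `delta_h`, optional `sigma`) with at least 3 distinct temperatures.
#' @param t0 Optimum temperature of the hydrophobic effect in kelvin.
#' @return An object of class `enthalpy_fit`: `gamma` (kJ/(mol K^2)),
#'   `e_int` (kJ/mol), `t0`, `covariance` (2 x 2 for `(gamma, e_int)`),
#'   standard errors, and the input data with fitted values.
#' @examples
#' cu <- generate_synthetic_itc(gamma = 3.2e-3, e_int = -300, sigma = 0)
#' fit <- fit_enthalpy_vs_temperature(cu)
#' delta_cp(fit, 310)  # about -1.98 kJ/(mol K)
#' @export
fit_enthalpy_vs_temperature <- function(curve, t0 = 343.15) {
  stopifnot(is.data.frame(curve),
            all(c("temperature", "delta_h") %in% names(curve)))
  if (length(unique(curve$temperature)) < 3L)
    stop("need at least 3 distinct temperatures", call. = FALSE)
  x <- t0^2 - curve$temperature^2
  if (stats::sd(x) == 0) stop("degenerate design: all temperatures equal",
                              call. = FALSE)
  w <- if ("sigma" %in% names(curve)) 1 / curve$sigma^2 else NULL
  fit <- stats::lm(curve$delta_h ~ x, weights = w)
  cf <- stats::coef(fit)
  # zero-residual (noiseless) inputs are legitimate; silence lm's caveat
  vc <- suppressWarnings(
    stats::vcov(fit)[c("x", "(Intercept)"), c("x", "(Intercept)")])
  structure(list(gamma = unname(cf["x"]), e_int = unname(cf["(Intercept)"]),
                 t0 = t0,
                 se_gamma = sqrt(vc[1, 1]), se_e_int = sqrt(vc[2, 2]),
                 covariance = vc, data = curve,
                 fitted = unname(stats::fitted(fit)),
                 lm = fit),
            class = "enthalpy_fit")
}

#' @export
print.enthalpy_fit <- function(x, ...) {
  cat(sprintf(
    "Hydrophobic enthalpy fit (T0 = %.2f K):\n  gamma = %.4g +/- %.2g kJ/(mol K^2)\n  E_int = %.4g +/- %.2g kJ/mol\n  dCp(298 K) = %.3g kJ/(mol K)\n",
    x$t0, x$gamma, x$se_gamma, x$e_int, x$se_e_int, delta_cp(x, 298.15)))
  invisible(x)
}

#' Heat capacity implied by an enthalpy fit
#'
#' @param fit An `enthalpy_fit` (or a list with a `gamma` element).
#' @param temperature Temperature(s) in kelvin.
#' @return `dCp(T) = -2 * gamma * T`, in kJ/(mol K).
#' @export
delta_cp <- function(fit, temperature) {
  -2 * fit$gamma * temperature
}

#' Isodesmic free-monomer fraction
#'
#' The isodesmic (single equilibrium constant) linear-polymerisation model:
#' with `K = exp(-(dG0 + m D) / (R T))` per molar (1 M standard state) and
#' `x = K * total_conc`, the monomer fraction is
#' `y = (2x + 1 - sqrt(4x + 1)) / (2 x^2)`, continuous with `y -> 1` as
#' `x -> 0` and `0 < y <= 1` throughout.
#'
#' @param delta_g0 Free energy of adding a monomer to the fibril, kJ/mol.
#' @param m_value Denaturant m-value, kJ/(mol M).
#' @param d Denaturant concentration(s), M.
#' @param total_conc Total protein concentration, M.
#' @param temperature Temperature, K.
#' @return Monomer fraction(s) in (0, 1].
#' @examples
#' # x = 1 gives (3 - sqrt(5))/2
#' isodesmic_fraction(0, 0, 0, total_conc = 1, temperature = 298.15)
#' @export
isodesmic_fraction <- function(delta_g0, m_value, d, total_conc,
                               temperature) {
  stopifnot(total_conc > 0, temperature > 0)
  K <- exp(-(delta_g0 + m_value * d) / (GAS_CONSTANT_KJ * temperature))
  x <- K * total_conc
  y <- ifelse(x < 1e-6,
              1 - 2 * x + 5 * x^2,          # series expansion, stable at x ~ 0
              (2 * x + 1 - sqrt(4 * x + 1)) / (2 * x^2))
  pmin(y, 1)
}

#' Chemical depolymerisation curve
#'
#' @param denaturant Denaturant concentrations, M.
#' @param fraction_monomer Measured monomer fractions (noisy values may fall
#'   slightly outside `[0, 1]`).
#' @param total_conc Total protein concentration, M.
#' @param temperature Temperature, K.
#' @return A data.frame of class `depoly_curve` with attributes
#'   `total_conc` and `temperature`.
#' @export
depoly_curve <- function(denaturant, fraction_monomer, total_conc,
                         temperature = 298.15) {
  stopifnot(length(denaturant) == length(fraction_monomer),
            all(denaturant >= 0), total_conc > 0, temperature > 0)
  structure(data.frame(denaturant = denaturant,
                       fraction_monomer = fraction_monomer),
            total_conc = total_conc, temperature = temperature,
            class = c("depoly_curve", "data.frame"))
}

#' Fit the isodesmic model to a depolymerisation curve
#'
#' Nonlinear least squares over `(delta_g0, m_value)` of the
#' [isodesmic_fraction()] closed form at fixed total concentration and
#' temperature.  Starting values are derived from the mid-transition
#' denaturant concentration and the transition width; the fit uses
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param curve A [depoly_curve()].
#' @return An object of class `isodesmic_fit`: `delta_g0` (kJ/mol),
#'   `m_value` (kJ/(mol M)), standard errors, covariance, the data and
#'   fitted values.
#' @export
fit_isodesmic <- function(curve) {
  stopifnot(inherits(curve, "depoly_curve"))
  if (nrow(curve) < 4L) stop("need at least 4 points", call. = FALSE)
  mt <- attr(curve, "total_conc")
  temp <- attr(curve, "temperature")
  y <- curve$fraction_monomer
  d <- curve$denaturant
  if (max(y) < 0.2 || min(y) > 0.8)
    stop(paste0("no depolymerisation transition in the measured range ",
                sprintf("(monomer fraction spans %.2f-%.2f); ", min(y),
                        max(y)),
                "cannot fit the isodesmic model"), call. = FALSE)
  rt <- GAS_CONSTANT_KJ * temp
  d_mid <- stats::approx(y, d, xout = 0.5, ties = mean)$y
  if (is.na(d_mid)) d_mid <- stats::median(d)
  # x = K * [M]_T at the transition midpoint (y = 0.5)
  x_half <- stats::uniroot(function(x)
    (2 * x + 1 - sqrt(4 * x + 1)) / (2 * x^2) - 0.5, c(1e-6, 1e3))$root
  q <- stats::approx(y, d, xout = c(0.25, 0.75), ties = mean)$y
  width <- if (all(is.finite(q))) abs(diff(q)) else max(d) / 4
  m0 <- max(4 * rt / max(width, 1e-3), 0.1)
  dg0 <- -rt * log(x_half / mt) - m0 * d_mid
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fraction_monomer ~ isodesmic_fraction(dg, m, denaturant, mt, temp),
      data = curve, start = list(dg = dg0, m = m0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("isodesmic fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  structure(list(delta_g0 = unname(cf["dg"]), m_value = unname(cf["m"]),
                 se_delta_g0 = sqrt(vc["dg", "dg"]),
                 se_m_value = sqrt(vc["m", "m"]),
                 covariance = vc, total_conc = mt, temperature = temp,
                 data = curve, fitted = unname(stats::fitted(fit)),
                 nls = fit),
            class = "isodesmic_fit")
}

#' @export
print.isodesmic_fit <- function(x, ...) {
  cat(sprintf(
    "Isodesmic fit ([M]_T = %.3g M, T = %.2f K):\n  dG0 = %.4g +/- %.2g kJ/mol\n  m   = %.4g +/- %.2g kJ/(mol M)\n",
    x$total_conc, x$temperature, x$delta_g0, x$se_delta_g0, x$m_value,
    x$se_m_value))
  invisible(x)
}

#' Per-residue maximum solvent-accessible areas
#'
#' Shipped plain-text table of theoretical maximum SASA values per residue
#' (square angstroms); overridable by editing a copy.
#'
#' @param path Optional alternative table (TSV with `residue`, `area`).
#' @return Named numeric vector of areas.
#' @export
max_asa_table <- function(path = NULL) {
  p <- path %||% system.file("extdata", "max_asa.tsv", package = "fibrilMC",
                             mustWork = TRUE)
  df <- utils::read.table(p, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(df$area, df$residue)
}

#' Buried hydrophobic surface area of a fibril-core sequence
#'
#' `A_h = sum_i h_i * a_i` over the core region, with `h_i = 1` for the nine
#' hydrophobic residue types and `a_i` the per-residue area.
#'
#' @param core_sequence A [peptide_sequence()] (fibril-core region only) or
#'   a string.
#' @param area_table Named per-residue areas; defaults to
#'   [max_asa_table()].
#' @return Hydrophobic area in square angstroms.
#' @examples
#' hydrophobic_area("GNNQQNY")  # only the tyrosine contributes
#' @export
hydrophobic_area <- function(core_sequence, area_table = max_asa_table()) {
  if (!inherits(core_sequence, "peptide_sequence"))
    core_sequence <- peptide_sequence(core_sequence)
  res <- core_sequence$residues
  missing_aa <- !(res %in% names(area_table))
  if (any(missing_aa))
    stop(sprintf("no area for residue '%s' at position %d",
                 res[which(missing_aa)[1]], which(missing_aa)[1]),
         call. = FALSE)
  sum(area_table[res][core_sequence$hydrophobic])
}

#' Regress hydrophobic strength on buried hydrophobic area
#'
#' Least-squares fit of the per-system hydrophobic strengths `gamma` on
#' their buried hydrophobic surface areas `A_h`, constrained through the
#' origin (zero buried area implies no hydrophobic temperature dependence).
#'
#' @param records Data.frame with columns `a_h` (square angstroms) and
#'   `gamma` (kJ/(mol K^2)); optionally `label`.
#' @return An object of class `gamma_area_fit`: `slope`
#'   (kJ/(mol K^2 A^2)), `se_slope`, `residuals`, `records`.
#' @export
fit_gamma_vs_area <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("a_h", "gamma") %in% names(records)))
  if (all(records$a_h == 0))
    stop("all hydrophobic areas are zero; slope undefined", call. = FALSE)
  fit <- stats::lm(gamma ~ 0 + a_h, data = records)
  structure(list(slope = unname(stats::coef(fit)["a_h"]),
                 se_slope = unname(
                   suppressWarnings(sqrt(diag(stats::vcov(fit))))["a_h"]),
                 residuals = unname(stats::residuals(fit)),
                 records = records, lm = fit),
            class = "gamma_area_fit")
}

#' @export
print.gamma_area_fit <- function(x, ...) {
  cat(sprintf(
    "Through-origin fit of gamma on A_h over %d systems:\n  slope = %.4g +/- %.2g kJ/(mol K^2 A^2)\n",
    nrow(x$records), x$slope, x$se_slope))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic calorimetric enthalpy curve
#'
#' Evaluates the hydrophobic enthalpy model
#' `dH(T) = gamma (t0^2 - T^2) + e_int` on a temperature design and adds
#' optional Gaussian noise; deterministic given `rng_seed`, exact at
#' `sigma = 0`.
#'
#' @param gamma,e_int,t0 Truth parameters (kJ/(mol K^2), kJ/mol, K).
#' @param temperatures Temperature design, K.
#' @param sigma Gaussian noise standard deviation on `delta_h`, kJ/mol.
#' @param rng_seed Seed for the noise.
#' @return An [itc_curve()].
#' @export
generate_synthetic_itc <- function(gamma = 3.2e-3, e_int = -300,
                                   t0 = 343.15,
                                   temperatures = seq(278, 323, by = 5),
                                   sigma = 0, rng_seed = 1) {
  dh <- gamma * (t0^2 - temperatures^2) + e_int
  if (sigma > 0)
    dh <- dh + with_seed(rng_seed, stats::rnorm(length(dh), 0, sigma))
  itc_curve(temperatures, dh,
            sigma = if (sigma > 0) rep(sigma, length(dh)) else NULL)
}

#' Generate a synthetic depolymerisation curve
#'
#' Evaluates the isodesmic closed form on a denaturant design and adds
#' optional Gaussian noise on the monomer fraction; deterministic given
#' `rng_seed`, exact at `sigma = 0`.
#'
#' @param delta_g0,m_value Truth parameters (kJ/mol, kJ/(mol M)).
#' @param total_conc Total protein concentration, M.
#' @param temperature Temperature, K.
#' @param denaturant Denaturant design, M.
#' @param sigma Gaussian noise standard deviation on the fraction.
#' @param rng_seed Seed for the noise.
#' @return A [depoly_curve()].
#' @export
generate_synthetic_depoly <- function(delta_g0 = -37.5, m_value = 1.5,
                                      total_conc = 10e-6,
                                      temperature = 298.15,
                                      denaturant = seq(0, 8,
                                                       length.out = 25),
                                      sigma = 0, rng_seed = 1) {
  y <- isodesmic_fraction(delta_g0, m_value, denaturant, total_conc,
                          temperature)
  if (sigma > 0)
    y <- y + with_seed(rng_seed, stats::rnorm(length(y), 0, sigma))
  depoly_curve(denaturant, y, total_conc, temperature)
}

#' Export a fit as a JSON record
#'
#' Writes parameters, standard errors and covariance of an `enthalpy_fit`,
#' `isodesmic_fit` or `gamma_area_fit` to JSON.
#'
#' @param fit The fit object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  drop <- c("lm", "nls", "data", "records", "fitted")
  x <- fit[setdiff(names(fit), drop)]
  x$class <- class(fit)[1]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
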