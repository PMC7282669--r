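#' Parameters of the temperature-dependent hydrophobic effect
#'
#' The hydrophobic free energy per solvent-exposed hydrophobic contact is
#' modelled as a downward parabola in temperature,
#' \deqn{F_{hydr} = -\alpha\, C_h\, (T - T_0)^2,}
#' maximal (zero) at the optimum temperature `t0` and weakening on either
#' side.  In reduced simulation units (`k_B = 1`) the default optimum is
#' `t0 = 0.4`; in physical mode use kelvin (the calorimetric fits use
#' `t0 = 343.15` K) and alpha in kJ/(mol K^2 contact).
#'
#' @param alpha Strength of the hydrophobic temperature dependence
#'   (energy per squared temperature per contact). Must be `>= 0`.
#' @param t0 Temperature of the maximal hydrophobic effect. Must be `> 0`.
#' @return An object of class `hydrophobic_params`.
#' @examples
#' hp <- hydrophobic_params(alpha = 60, t0 = 0.4)
#' f_hydr(hp, c_h = 1, t = 0.25)
#' @export
hydrophobic_params <- function(alpha = 60, t0 = 0.4) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(t0), length(t0) == 1L, t0 > 0)
  structure(list(alpha = alpha, t0 = t0), class = "hydrophobic_params")
}

#' @export
print.hydrophobic_params <- function(x, ...) {
  cat(sprintf("Hydrophobic effect: alpha = %g, T0 = %g\n", x$alpha, x$t0))
  invisible(x)
}

check_temperature <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("temperature must be positive and finite", call. = FALSE)
  t
}

#' Hydrophobic free energy of exposure
#'
#' `F_hydr = -alpha * c_h * (t - t0)^2`: always `<= 0`, zero exactly at
#' `t = t0` or when no hydrophobic contact is exposed.
#'
#' @param params A [hydrophobic_params()] object.
#' @param c_h Number of solvent-exposed hydrophobic contacts (`>= 0`).
#' @param t Temperature(s), `> 0`; vectorised.
#' @return Free energy, same length as `t`.
#' @export
f_hydr <- function(params, c_h, t) {
  stopifnot(inherits(params, "hydrophobic_params"), c_h >= 0)
  check_temperature(t)
  -params$alpha * c_h * (t - params$t0)^2
}

#' Hydrophobic enthalpy of exposure
#'
#' The enthalpy is the beta-derivative of `beta * F_hydr` (with
#' `beta = 1/T`), which for the parabolic free energy evaluates to
#' `E_hydr = -alpha * c_h * (t0^2 - t^2)`.
#'
#' @inheritParams f_hydr
#' @return Enthalpy, same length as `t`.
#' @export
e_hydr <- function(params, c_h, t) {
  stopifnot(inherits(params, "hydrophobic_params"), c_h >= 0)
  check_temperature(t)
  -params$alpha * c_h * (params$t0^2 - t^2)
}

#' Hydrophobic entropic contribution
#'
#' `-T * S_hydr = F_hydr - E_hydr`, the exact thermodynamic identity.
#'
#' @inheritParams f_hydr
#' @return `-T S`, same length as `t`.
#' @export
minus_t_s_hydr <- function(params, c_h, t) {
  f_hydr(params, c_h, t) - e_hydr(params, c_h, t)
}

#' Parameters of the hydrophobic elongation estimate
#'
#' Bundles the effective hydrophobic strength of an elongation step,
#' `gamma = alpha * |dC_h|` in the lattice model (`dC_h = 6` for the default
#' seven-residue double layer) or `gamma = alpha * A_h` per unit hydrophobic
#' area in the atomistic interpretation, with the temperature-independent
#' internal-energy offset `e_int` and the optimum temperature `t0`.
#' The sign convention is `gamma >= 0` for burial-driven assembly, so that the
#' elongation enthalpy decreases with temperature (negative heat capacity).
#'
#' @param gamma Effective hydrophobic strength (finite; `>= 0` for
#'   burial-driven assembly).
#' @param e_int Temperature-independent internal-energy offset.
#' @param t0 Optimum temperature of the hydrophobic effect.
#' @return An object of class `elongation_params`.
#' @export
elongation_params <- function(gamma, e_int, t0 = 0.4) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(e_int), length(e_int) == 1L, is.finite(e_int),
            is.numeric(t0), t0 > 0)
  structure(list(gamma = gamma, e_int = e_int, t0 = t0),
            class = "elongation_params")
}

#' @export
print.elongation_params <- function(x, ...) {
  cat(sprintf("Elongation estimate: gamma = %g, E_int = %g, T0 = %g\n",
              x$gamma, x$e_int, x$t0))
  invisible(x)
}

#' Analytic hydrophobic estimate of the elongation thermodynamics
#'
#' Evaluates, on a temperature grid, the closed-form estimates for the change
#' in free energy, enthalpy and entropic term upon adding one layer to the
#' fibril, assuming the hydrophobic effect dominates:
#' \deqn{\Delta\hat G(T) = \gamma (T - T_0)^2 + E_{int}}
#' \deqn{\Delta\hat E(T) = \gamma (T_0^2 - T^2) + E_{int}}
#' \deqn{-T\Delta\hat S(T) = \Delta\hat G - \Delta\hat E}
#' Elongation buries hydrophobic contacts, so the free-energy penalty grows
#' quadratically away from `t0` on both sides (the origin of both cold and
#' heat destabilisation in the estimate), while the enthalpy decreases
#' monotonically in `T` for `gamma > 0` (slope `-2 gamma T`, a negative heat
#' capacity).
#'
#' @param params An [elongation_params()] object.
#' @param t_grid Temperatures (`> 0`); may be empty.
#' @return A data.frame with columns `temperature`, `free_energy`, `enthalpy`,
#'   `minus_t_entropy`; the identity
#'   `free_energy == enthalpy + minus_t_entropy` holds at every grid point.
#' @export
estimate_elongation <- function(params, t_grid) {
  stopifnot(inherits(params, "elongation_params"))
  if (length(t_grid) == 0L)
    return(data.frame(temperature = numeric(0), free_energy = numeric(0),
                      enthalpy = numeric(0), minus_t_entropy = numeric(0)))
  check_temperature(t_grid)
  g <- params$gamma * (t_grid - params$t0)^2 + params$e_int
  e <- params$gamma * (params$t0^2 - t_grid^2) + params$e_int
  data.frame(temperature = t_grid, free_energy = g, enthalpy = e,
             minus_t_entropy = g - e)
}

#' Exothermic-endothermic crossover temperature
#'
#' Temperature at which the estimated elongation enthalpy
#' `gamma (t0^2 - T^2) + e_int` changes sign: `T_x = sqrt(t0^2 + e_int/gamma)`.
#' For `e_int < 0` elongation is endothermic below `T_x` and exothermic above.
#'
#' @param params An [elongation_params()] object with `gamma > 0`.
#' @return The crossover temperature, or `NA_real_` when no real root exists
#'   (`t0^2 + e_int/gamma <= 0`, i.e. elongation endothermic everywhere).
#' @export
crossover_temperature <- function(params) {
  stopifnot(inherits(params, "elongation_params"))
  if (params$gamma <= 0)
    stop("no crossover defined for gamma <= 0", call. = FALSE)
  disc <- params$t0^2 + params$e_int / params$gamma
  if (disc <= 0) return(NA_real_)
  sqrt(disc)
}
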