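#' Physical constants for CBL calculations
#'
#' Bundles the molecular diffusion coefficient of O2 and the kinematic
#' viscosity of seawater used throughout the package. Defaults are the
#' values for seawater at 26 degrees C and practical salinity 35:
#' \code{D_O2 = 2.29e-5} cm^2 s^-1 and \code{nu = 9.23e-7} m^2 s^-1.
#'
#' @param D_O2 O2 diffusion coefficient, cm^2 s^-1.
#' @param nu kinematic viscosity of seawater, m^2 s^-1.
#' @param T temperature, degrees C (bookkeeping only; constants are not
#'   re-evaluated from T and S).
#' @param S practical salinity (bookkeeping only).
#' @return An object of class \code{"cbl_constants"}: a list with elements
#'   \code{D_O2}, \code{nu}, \code{T}, \code{S}.
#' @examples
#' cbl_constants()
#' cbl_constants(D_O2 = 2.4e-5)
#' @export
cbl_constants <- function(D_O2 = 2.29e-5, nu = 9.23e-7, T = 26, S = 35) {
  if (!is.numeric(D_O2) || D_O2 <= 0) stop("D_O2 must be > 0")
  if (!is.numeric(nu) || nu <= 0) stop("nu must be > 0")
  structure(list(D_O2 = D_O2, nu = nu, T = T, S = S),
            class = "cbl_constants")
}

#' Convert pH to hydrogen-ion concentration
#'
#' @param pH pH value(s), any scale. The returned concentration is on the
#'   same scale as the input pH.
#' @return [H+] in mol L^-1, i.e. \code{10^(-pH)}.
#' @examples
#' h_concentration(8)     # 1e-8
#' h_concentration(7.77)
#' @export
h_concentration <- function(pH) {
  if (!is.numeric(pH) || any(!is.finite(pH)))
    stop("pH must be finite numeric")
  10^(-pH)
}

# Hydrogen-ion activity coefficient fH(S, T) used to move NBS (activity)
# pH onto a concentration scale; Takahashi-style fit, T in Kelvin.
.fH <- function(S, T_c) {
  TK <- T_c + 273.15
  1.2948 - 0.002036 * TK + (0.0004607 - 0.000001475 * TK) * S^2
}

#' Convert pH from the NBS scale to the total hydrogen-ion scale
#'
#' Electrode pH calibrated against NBS buffers is an activity-based
#' quantity; carbonate-system work uses the total hydrogen-ion
#' concentration scale. The conversion applied here is a salinity- and
#' temperature-dependent offset: first the NBS activity is divided by the
#' hydrogen-ion activity coefficient fH(S, T) (giving the seawater scale),
#' then the sulfate and fluoride association equilibria move the value to
#' the total scale. Because the offset depends only on (S, T), differences
#' between two pH values converted together are preserved exactly.
#'
#' @param pH_nbs pH on the NBS scale.
#' @param S practical salinity, in (0, 50).
#' @param T temperature, degrees C, in (0, 40).
#' @param fh optional replacement for the activity-coefficient function;
#'   a function of (S, T) returning fH. Defaults to the built-in fit.
#' @return pH on the total scale.
#' @examples
#' ph_nbs_to_total(8.10, S = 35, T = 26)
#' @export
ph_nbs_to_total <- function(pH_nbs, S, T, fh = NULL) {
  if (!is.numeric(S) || S <= 0 || S >= 50)
    stop("salinity out of range (0, 50)")
  if (!is.numeric(T) || T <= 0 || T >= 40)
    stop("temperature out of range (0, 40) degrees C")
  fH <- if (is.null(fh)) .fH(S, T) else fh(S, T)
  # NBS -> seawater scale: [H]_sws = a_H / fH
  ph_sws <- pH_nbs + log10(fH)
  # seawater -> total scale via sulfate/fluoride speciation
  ph_sws - log10(.sws_to_total_factor(S, T))
}

#' Offset between total-scale and NBS-scale pH
#'
#' @inheritParams ph_nbs_to_total
#' @return The (S, T)-dependent offset \code{pH_T - pH_NBS} (negative in
#'   seawater; about -0.13 at S 35, 26 degrees C).
#' @export
ph_scale_offset <- function(S, T, fh = NULL) {
  ph_nbs_to_total(0, S = S, T = T, fh = fh)
}

#' Hydraulic diameter of a rectangular duct
#'
#' Uses the closed-conduit convention 4A/P with perimeter 2(width + depth).
#'
#' @param width duct width, m.
#' @param depth water depth, m.
#' @return Hydraulic diameter, m.
#' @examples
#' hydraulic_diameter(0.18, 0.19)  # 0.18486...
#' @export
hydraulic_diameter <- function(width, depth) {
  if (!is.numeric(width) || !is.numeric(depth) || width <= 0 || depth <= 0)
    stop("width and depth must be > 0")
  4 * (width * depth) / (2 * (width + depth))
}

#' Reynolds number
#'
#' Re = u W / nu, with u the bulk velocity, W the characteristic length
#' (hydraulic diameter of the working section, or organism height for the
#' flow experienced at the organism), and nu the kinematic viscosity.
#'
#' @param u bulk flow velocity, m s^-1.
#' @param W characteristic length, m.
#' @param nu kinematic viscosity, m^2 s^-1 (default: seawater at 26
#'   degrees C, S 35).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(0.02, hydraulic_diameter(0.18, 0.19))  # ~4006
#' reynolds(0.06, 0.03)                            # ~1950
#' @export
reynolds <- function(u, W, nu = 9.23e-7) {
  if (any(u <= 0) || any(W <= 0) || any(nu <= 0))
    stop("u, W and nu must all be > 0")
  u * W / nu
}
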