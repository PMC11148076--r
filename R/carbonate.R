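#' Seawater state for carbonate-system calculations
#'
#' @param S practical salinity, in (1, 50).
#' @param T temperature, degrees C, in (0, 40).
#' @param pH pH value.
#' @param ph_scale scale of \code{pH}: \code{"NBS"} or \code{"total"}.
#' @param TA total alkalinity, micromol kg^-1 (> 0).
#' @return Object of class \code{"seawater_state"}.
#' @export
seawater_state <- function(S, T, pH, TA, ph_scale = c("total", "NBS")) {
  ph_scale <- match.arg(ph_scale)
  if (!(S > 1 && S < 50)) stop("salinity out of range (1, 50)")
  if (!(T > 0 && T < 40)) stop("temperature out of range (0, 40)")
  if (!(TA > 0)) stop("TA must be > 0")
  structure(list(S = S, T = T, pH = pH, ph_scale = ph_scale, TA = TA),
            class = "seawater_state")
}

# --- equilibrium constants -------------------------------------------------
# All published fits below are evaluated at (T, S) and, where the native
# scale differs, converted onto the total hydrogen-ion scale for solving.

# sulfate and fluoride totals, mol kg^-1 (from chlorinity ratios)
.ST <- function(S) 0.14 / 96.062 * S / 1.80655
.FT <- function(S) 0.000067 / 18.998 * S / 1.80655

# bisulfate dissociation (Dickson 1990), free scale, mol kg-soln^-1
.KS <- function(S, TK) {
  I <- 19.924 * S / (1000 - 1.005 * S)
  lnK <- -4276.1 / TK + 141.328 - 23.093 * log(TK) +
    (-13856 / TK + 324.57 - 47.986 * log(TK)) * sqrt(I) +
    (35474 / TK - 771.54 + 114.723 * log(TK)) * I -
    2698 / TK * I^1.5 + 1776 / TK * I^2 + log(1 - 0.001005 * S)
  exp(lnK)
}

# hydrogen fluoride dissociation (Perez & Fraga 1987), total scale
.KF <- function(S, TK) exp(874 / TK - 9.68 + 0.111 * sqrt(S))

# factor [H]_total / [H]_sws
.sws_to_total_factor <- function(S, T_c) {
  TK <- T_c + 273.15
  ks <- .KS(S, TK); kf <- .KF(S, TK)
  st <- .ST(S); ft <- .FT(S)
  # KF is reported on the total scale; express F speciation via free H
  kf_free <- kf / (1 + st / ks)
  (1 + st / ks) / (1 + st / ks + ft / kf_free)
}

# CO2 solubility (Weiss 1974), mol kg^-1 atm^-1
.K0 <- function(S, TK) {
  exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
        S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2))
}

# boric acid (Dickson 1990), total scale
.KB <- function(S, TK) {
  lnK <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
            0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * log(TK) +
    0.053105 * sqrt(S) * TK
  exp(lnK)
}

# water (Millero 1995), seawater scale
.KW_sws <- function(S, TK) {
  exp(148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
        (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S)
}

# carbonic acid: Lueker et al. (2000), total scale
.K12_lueker <- function(S, TK) {
  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2
  list(K1 = 10^(-pK1), K2 = 10^(-pK2), scale = "total")
}

# carbonic acid: Mehrbach et al. refit by Dickson & Millero (1987),
# seawater scale
.K12_mehrbach_dickson <- function(S, TK) {
  pK1 <- 3670.7 / TK - 62.008 + 9.7944 * log(TK) -
    0.0118 * S + 0.000116 * S^2
  pK2 <- 1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2
  list(K1 = 10^(-pK1), K2 = 10^(-pK2), scale = "sws")
}

# calcite / aragonite solubility (Mucci 1983), mol^2 kg^-2
.Ksp_calcite <- function(S, TK) {
  10^(-171.9065 - 0.077993 * TK + 2839.319 / TK + 71.595 * log10(TK) +
        (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqrt(S) -
        0.07711 * S + 0.0041249 * S^1.5)
}
.Ksp_aragonite <- function(S, TK) {
  10^(-171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10(TK) +
        (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
        0.10018 * S + 0.0059415 * S^1.5)
}

#' Evaluate a carbonate-system constant set at (T, S)
#'
#' Builds the full set of equilibrium constants used by the solver, all
#' expressed on the total hydrogen-ion scale: the carbonic acid constants
#' of either the Mehrbach-refit (Dickson & Millero) or the Lueker
#' formulation, Weiss K0, Dickson boric acid, Millero water, Dickson
#' bisulfate, Perez & Fraga fluoride, Mucci solubility products, and the
#' Uppstrom borate-to-salinity ratio.
#'
#' @param T temperature, degrees C (formulation fit range roughly 2-35).
#' @param S practical salinity (fit range roughly 19-43).
#' @param tag \code{"lueker"} or \code{"mehrbach_dickson"}.
#' @return Object of class \code{"carb_constants"}: list with K0, K1, K2,
#'   KB, KW, KS, KF, Ksp_ar, Ksp_ca (total scale where applicable), BT,
#'   ST, FT, Ca (mol kg^-1), the native scale of K1/K2, and (T, S).
#' @export
carb_constants <- function(T, S, tag = c("lueker", "mehrbach_dickson")) {
  tag <- match.arg(tag)
  if (!(T >= 0 && T <= 40))
    stop("temperature outside carbonic-acid formulation range (", tag, ")")
  if (!(S >= 15 && S <= 45))
    stop("salinity outside carbonic-acid formulation range (", tag, ")")
  TK <- T + 273.15
  k12 <- switch(tag, lueker = .K12_lueker(S, TK),
                mehrbach_dickson = .K12_mehrbach_dickson(S, TK))
  f <- .sws_to_total_factor(S, T)
  K1 <- k12$K1; K2 <- k12$K2
  if (k12$scale == "sws") { K1 <- K1 * f; K2 <- K2 * f }
  structure(list(
    tag = tag, T = T, S = S,
    K0 = .K0(S, TK),
    K1 = K1, K2 = K2, native_scale = k12$scale,
    KB = .KB(S, TK),
    KW = .KW_sws(S, TK) * f,
    KS = .KS(S, TK), KF = .KF(S, TK),
    Ksp_ar = .Ksp_aragonite(S, TK), Ksp_ca = .Ksp_calcite(S, TK),
    BT = 0.0004157 * S / 35,
    ST = .ST(S), FT = .FT(S),
    Ca = 0.02128 / 40.087 * S / 1.80655,
    sws_to_total = f
  ), class = "carb_constants")
}

# total alkalinity (mol kg^-1) from DIC (mol kg^-1) and total-scale [H+],
# practical alkalinity: carbonate + borate + water - free H
.ta_from_dic_h <- function(dic, h, k) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh <- k$KW / h
  hfree <- h / (1 + k$ST / k$KS)
  hco3 + 2 * co3 + boh4 + oh - hfree
}

#' DIC from pH and total alkalinity
#'
#' Solves the alkalinity balance TA = [HCO3-] + 2[CO3--] + [B(OH)4-] +
#' [OH-] - [H+]free for carbonate alkalinity at the measured pH, then
#' inverts the carbonate speciation for DIC. Analytic (no iteration);
#' the recomputed TA matches the input to machine precision.
#'
#' @param state a \code{\link{seawater_state}} (NBS pH is converted to the
#'   total scale internally).
#' @param constants a \code{\link{carb_constants}}; defaults to the
#'   Mehrbach-refit set at the state's (T, S).
#' @return DIC in micromol kg^-1.
#' @export
dic_from_ph_ta <- function(state,
                           constants = carb_constants(state$T, state$S,
                                                      "mehrbach_dickson")) {
  ph_t <- if (state$ph_scale == "NBS")
    ph_nbs_to_total(state$pH, S = state$S, T = state$T) else state$pH
  h <- 10^(-ph_t)
  k <- constants
  ta <- state$TA * 1e-6
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh <- k$KW / h
  hfree <- h / (1 + k$ST / k$KS)
  ca_alk <- ta - boh4 - oh + hfree
  if (ca_alk <= 0)
    stop("infeasible state: non-positive carbonate alkalinity")
  dic <- ca_alk * (h^2 + k$K1 * h + k$K1 * k$K2) / (k$K1 * (h + 2 * k$K2))
  dic * 1e6
}

#' Full carbonate speciation from DIC and total alkalinity
#'
#' Root-finds the total-scale pH at which the alkalinity balance holds
#' (bracketed search on pH in [3, 12], tolerance 1e-8 pH), then returns
#' the full speciation: CO2*, HCO3-, CO3--, pCO2, fCO2 (Weiss virial
#' fugacity coefficient), and the aragonite/calcite saturation states.
#'
#' @param DIC dissolved inorganic carbon, micromol kg^-1.
#' @param TA total alkalinity, micromol kg^-1.
#' @param S salinity; \code{T} temperature, degrees C.
#' @param T temperature, degrees C.
#' @param constants a \code{\link{carb_constants}}; Lueker at (T, S) by
#'   default.
#' @return Object of class \code{"carb_speciation"}: list with pH (total
#'   scale), DIC, CO2, HCO3, CO3 (micromol kg^-1), pCO2, fCO2 (microatm),
#'   omega_ar, omega_ca, and the alkalinity residual (micromol kg^-1).
#' @export
speciate_from_dic_ta <- function(DIC, TA, S, T,
                                 constants = carb_constants(T, S, "lueker")) {
  if (!(DIC > 0 && TA > 0)) stop("DIC and TA must be > 0")
  k <- constants
  dic <- DIC * 1e-6; ta <- TA * 1e-6
  f <- function(ph) .ta_from_dic_h(dic, 10^(-ph), k) - ta
  lo <- f(3); hi <- f(12)
  if (sign(lo) == sign(hi))
    stop("infeasible state: no pH in [3, 12] balances the alkalinity")
  ph <- stats::uniroot(f, c(3, 12), tol = 1e-10)$root
  h <- 10^(-ph)
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  co2 <- dic * h^2 / denom
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  pco2_atm <- co2 / k$K0
  TK <- k$T + 273.15
  # Weiss (1974) virial coefficients, cm^3 mol^-1
  B <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  delta <- 57.7 - 0.118 * TK
  fugcoef <- exp((B + 2 * delta) * 1e-6 * 101325 / (8.31446 * TK))
  structure(list(
    pH = ph, DIC = DIC,
    CO2 = co2 * 1e6, HCO3 = hco3 * 1e6, CO3 = co3 * 1e6,
    pCO2 = pco2_atm * 1e6, fCO2 = pco2_atm * fugcoef * 1e6,
    omega_ar = co3 * k$Ca / k$Ksp_ar,
    omega_ca = co3 * k$Ca / k$Ksp_ca,
    ta_residual = abs(.ta_from_dic_h(dic, h, k) - ta) * 1e6,
    constants_tag = k$tag
  ), class = "carb_speciation")
}

#' @export
print.carb_speciation <- function(x, digits = 4, ...) {
  cat("Carbonate speciation (", x$constants_tag, " constants)\n", sep = "")
  cat(sprintf("  pH_T %.4f  DIC %.1f  pCO2 %.1f uatm  fCO2 %.1f uatm\n",
              x$pH, x$DIC, x$pCO2, x$fCO2))
  cat(sprintf("  CO2 %.2f  HCO3 %.1f  CO3 %.1f umol kg^-1\n",
              x$CO2, x$HCO3, x$CO3))
  cat(sprintf("  Omega_ar %.2f  Omega_ca %.2f\n", x$omega_ar, x$omega_ca))
  invisible(x)
}

#' Two-step carbonate-chemistry protocol
#'
#' Reproduces the two-program workflow used for the tank chemistry:
#' step 1 computes DIC from (pH, TA) with the Mehrbach-refit constant
#' set; step 2 computes the full speciation from (DIC, TA) with the
#' Lueker constant set.
#'
#' @param state a \code{\link{seawater_state}}.
#' @return A \code{"carb_speciation"} (Lueker step), with the step-1 DIC
#'   in its \code{DIC} element.
#' @export
two_step_protocol <- function(state) {
  dic <- dic_from_ph_ta(
    state, carb_constants(state$T, state$S, "mehrbach_dickson"))
  speciate_from_dic_ta(dic, state$TA, state$S, state$T,
                       carb_constants(state$T, state$S, "lueker"))
}

#' Carbonate chemistry of a diel seawater log
#'
#' Applies \code{\link{two_step_protocol}} to each timestamp of a daily
#' (pH, temperature) log with one (TA, S) value for the day, and returns
#' per-timestamp speciation plus daily mean/min/max summaries.
#'
#' @param log data frame with columns \code{pH} and \code{temp_C} (one row
#'   per timestamp), e.g. from \code{\link{synth_diel_seawater}}.
#' @param TA total alkalinity of the day, micromol kg^-1.
#' @param S salinity of the day.
#' @param ph_scale scale of the log's pH values.
#' @return List with \code{samples} (data frame: pH_T, DIC, pCO2, fCO2,
#'   CO2, HCO3, CO3, omega_ar, omega_ca per timestamp) and \code{summary}
#'   (data frame with mean/min/max per variable).
#' @export
carb_diel <- function(log, TA, S, ph_scale = c("total", "NBS")) {
  ph_scale <- match.arg(ph_scale)
  stopifnot(all(c("pH", "temp_C") %in% names(log)))
  rows <- lapply(seq_len(nrow(log)), function(i) {
    st <- seawater_state(S = S, T = log$temp_C[i], pH = log$pH[i],
                         TA = TA, ph_scale = ph_scale)
    sp <- two_step_protocol(st)
    data.frame(pH_T = sp$pH, DIC = sp$DIC, pCO2 = sp$pCO2, fCO2 = sp$fCO2,
               CO2 = sp$CO2, HCO3 = sp$HCO3, CO3 = sp$CO3,
               omega_ar = sp$omega_ar, omega_ca = sp$omega_ca)
  })
  samples <- do.call(rbind, rows)
  vars <- names(samples)
  summary <- data.frame(
    variable = vars,
    mean = vapply(samples, mean, 0),
    min = vapply(samples, min, 0),
    max = vapply(samples, max, 0),
    row.names = NULL)
  list(samples = samples, summary = summary)
}
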