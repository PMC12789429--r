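# Seawater carbonate system on the total pH scale at surface pressure.
# Constants: K1/K2 Lueker et al. 2000, KB Dickson 1990, KW Millero 1995,
# KS Dickson 1990, KF Perez & Fraga 1987, total boron Uppstrom 1974,
# K0 and CO2 fugacity Weiss 1974, aragonite Ksp Mucci 1983, Ca from
# salinity (Riley & Tongudai 1967).

CARB_CONSTANTS_ID <-
  "Lueker00-K1K2;Dickson90-KB,KS;Millero95-KW;PerezFraga87-KF;Uppstrom74-TB;Weiss74-K0;Mucci83-KspArag"

#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the dissociation/solubility constants used by [carb_solve()]
#' at a given temperature and salinity, on the total pH scale (KS on the
#' free scale, as conventional), in mol per kg of seawater, at 0 dbar.
#'
#' @param temp temperature, degrees C.
#' @param salinity practical salinity.
#' @return A list with `K0`, `K1`, `K2`, `KB`, `KW`, `KS`, `KF`, `KspA`,
#'   the totals `ST`, `FT`, `BT`, `Ca` (mol kg-1) and `TK` (kelvin).
#' @export
carb_constants <- function(temp, salinity) {
  TK <- temp + 273.15
  S <- salinity
  lnT <- log(TK)
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnT - 0.011555 * S +
    0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnT - 0.01781 * S +
    0.0001122 * S^2
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnT +
    0.053105 * sqrt(S) * TK
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnT +
    (-5.977 + 118.67 / TK + 1.0495 * lnT) * sqrt(S) - 0.01615 * S
  I <- 19.924 * S / (1000 - 1.005 * S)   # ionic strength
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnT +
    (-13856 / TK + 324.57 - 47.986 * lnT) * sqrt(I) +
    (35474 / TK - 771.54 + 114.723 * lnT) * I -
    2698 / TK * I^1.5 + 1776 / TK * I^2 + log(1 - 0.001005 * S)
  lnKF <- 874 / TK - 9.68 + 0.111 * sqrt(S)
  logKspA <- -171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
    0.10018 * S + 0.0059415 * S^1.5
  list(K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2), KB = exp(lnKB),
       KW = exp(lnKW), KS = exp(lnKS), KF = exp(lnKF), KspA = 10^logKspA,
       ST = 0.14 / 96.062 * S / 1.80655,
       FT = 0.000067 / 18.998 * S / 1.80655,
       BT = 0.0004157 * S / 35,
       Ca = 0.02128 / 40.087 * S / 1.80655,
       TK = TK)
}

# total alkalinity (mol/kg) from H+ (total scale, mol/kg) and DIC (mol/kg)
alk_from_h_dic <- function(H, DIC, k) {
  den <- H^2 + k$K1 * H + k$K1 * k$K2
  hco3 <- DIC * k$K1 * H / den
  co3 <- DIC * k$K1 * k$K2 / den
  Hfree <- H / (1 + k$ST / k$KS)
  hco3 + 2 * co3 + k$BT * k$KB / (k$KB + H) + k$KW / H -
    Hfree - k$ST * Hfree / (Hfree + k$KS) - k$FT * H / (H + k$KF)
}

check_carb_inputs <- function(temp, salinity, pH_T, A_T) {
  if (!is.finite(temp) || temp < -2 || temp > 45)
    stop("carb_solve: temperature out of range", call. = FALSE)
  if (!is.finite(salinity) || salinity <= 0 || salinity >= 45)
    stop("carb_solve: salinity must be in (0, 45)", call. = FALSE)
  if (!is.null(pH_T) && (!is.finite(pH_T) || pH_T <= 0 || pH_T >= 14))
    stop("carb_solve: pH_T must be in (0, 14)", call. = FALSE)
  if (!is.finite(A_T) || A_T <= 0)
    stop("carb_solve: total alkalinity must be positive", call. = FALSE)
}

build_carb_state <- function(temp, salinity, H, DIC, A_T, k) {
  den <- H^2 + k$K1 * H + k$K1 * k$K2
  co2 <- DIC * H^2 / den
  hco3 <- DIC * k$K1 * H / den
  co3 <- DIC * k$K1 * k$K2 / den
  fco2 <- co2 / k$K0
  # fugacity -> partial pressure (Weiss 1974 virial expansion, 1 atm)
  B <- -1636.75 + 12.0408 * k$TK - 0.0327957 * k$TK^2 +
    3.16528e-5 * k$TK^3
  delta <- 57.7 - 0.118 * k$TK
  fugfac <- exp((B + 2 * delta) / (82.057 * k$TK))
  residual <- alk_from_h_dic(H, DIC, k) - A_T * 1e-6
  structure(
    list(temp = temp, salinity = salinity, pH_T = -log10(H), A_T = A_T,
         hco3 = hco3 * 1e6, co3 = co3 * 1e6, co2_star = co2 * 1e6,
         dic = DIC * 1e6, fco2 = fco2 * 1e6, pco2 = fco2 / fugfac * 1e6,
         omega_arag = k$Ca * co3 / k$KspA,
         alk_residual = residual * 1e6,   # umol/kg
         constants_id = CARB_CONSTANTS_ID),
    class = "carb_state")
}

#' Solve the seawater CO2 system from pH (total scale) and total alkalinity
#'
#' Computes the full carbonate speciation at surface pressure (0 dbar) and
#' zero nutrients from temperature, salinity, total-scale pH and total
#' alkalinity. With pH known, the carbonate alkalinity follows directly by
#' subtracting borate, hydroxide, free proton, bisulfate and hydrogen
#' fluoride terms from the total alkalinity, and DIC follows in closed form;
#' no iteration is required for this input pair.
#'
#' @param temp temperature, degrees C.
#' @param salinity practical salinity, in (0, 45).
#' @param pH_T pH on the total scale.
#' @param A_T total alkalinity, umol kg-1.
#' @return An object of class `carb_state` with `hco3`, `co3`, `co2_star`,
#'   `dic` (umol kg-1), `pco2` and `fco2` (uatm), `omega_arag`, the
#'   alkalinity residual at the solution (umol kg-1) and the constants-set
#'   identifier.
#' @examples
#' carb_solve(26.80, 35.52, 7.97, 2179)
#' @export
carb_solve <- function(temp, salinity, pH_T, A_T) {
  check_carb_inputs(temp, salinity, pH_T, A_T)
  k <- carb_constants(temp, salinity)
  H <- 10^(-pH_T)
  Hfree <- H / (1 + k$ST / k$KS)
  CA <- A_T * 1e-6 - k$BT * k$KB / (k$KB + H) - k$KW / H + Hfree +
    k$ST * Hfree / (Hfree + k$KS) + k$FT * H / (H + k$KF)
  if (CA <= 0)
    stop("carb_solve: carbonate alkalinity non-positive; inputs ",
         "inconsistent", call. = FALSE)
  den <- H^2 + k$K1 * H + k$K1 * k$K2
  DIC <- CA * den / (k$K1 * H + 2 * k$K1 * k$K2)
  build_carb_state(temp, salinity, H, DIC, A_T, k)
}

#' Solve the seawater CO2 system from DIC and total alkalinity
#'
#' Finds the total-scale pH at which the alkalinity computed from `(H, DIC)`
#' matches the given total alkalinity, by damped Newton iteration on [H+]
#' with a bisection fallback (relative tolerance 1e-12 on [H+]), then
#' derives the full speciation.
#'
#' @param temp temperature, degrees C.
#' @param salinity practical salinity.
#' @param DIC total dissolved inorganic carbon, umol kg-1.
#' @param A_T total alkalinity, umol kg-1.
#' @return A `carb_state`, as for [carb_solve()].
#' @export
carb_solve_dic <- function(temp, salinity, DIC, A_T) {
  check_carb_inputs(temp, salinity, NULL, A_T)
  if (!is.finite(DIC) || DIC <= 0)
    stop("carb_solve_dic: DIC must be positive", call. = FALSE)
  k <- carb_constants(temp, salinity)
  dic <- DIC * 1e-6
  target <- A_T * 1e-6
  f <- function(H) alk_from_h_dic(H, dic, k) - target
  lo <- 1e-12; hi <- 1e-2          # pH 12 .. 2; f is decreasing in H
  if (f(lo) < 0 || f(hi) > 0)
    stop("carb_solve_dic: no root in pH range [2, 12]; diagnostics: f(pH12) = ",
         format(f(lo)), ", f(pH2) = ", format(f(hi)), call. = FALSE)
  H <- 1e-8
  for (it in 1:100) {
    fx <- f(H)
    if (fx > 0) lo <- max(lo, H) else hi <- min(hi, H)
    dH <- H * 1e-6
    dfdx <- (f(H + dH) - f(H - dH)) / (2 * dH)
    step <- -fx / dfdx
    Hn <- H + step
    damp <- 1
    while ((Hn <= lo || Hn >= hi) && damp > 1e-4) {   # keep inside bracket
      damp <- damp / 2
      Hn <- H + damp * step
    }
    if (Hn <= lo || Hn >= hi) Hn <- sqrt(lo * hi)     # bisect in log space
    if (abs(Hn - H) <= 1e-12 * H) { H <- Hn; break }
    H <- Hn
    if (it == 100)
      stop("carb_solve_dic: Newton iteration did not converge; last H = ",
           format(H), ", residual = ", format(f(H)), call. = FALSE)
  }
  build_carb_state(temp, salinity, H, dic, A_T, k)
}

#' Round-trip self-consistency check of a solved carbonate state
#'
#' Re-solves the system from the derived `(DIC, A_T)` pair of a solved
#' state and reports how well the input pH and pCO2 are recovered.
#'
#' @param state a `carb_state` from [carb_solve()].
#' @return A list with `pH_in`, `pH_recovered`, `dpH` (absolute pH
#'   difference), `pco2_in`, `pco2_recovered` and `pco2_rel_diff`.
#' @export
roundtrip_check <- function(state) {
  stopifnot(inherits(state, "carb_state"))
  rec <- carb_solve_dic(state$temp, state$salinity, state$dic, state$A_T)
  list(pH_in = state$pH_T, pH_recovered = rec$pH_T,
       dpH = abs(rec$pH_T - state$pH_T),
       pco2_in = state$pco2, pco2_recovered = rec$pco2,
       pco2_rel_diff = abs(rec$pco2 / state$pco2 - 1))
}

#' @export
print.carb_state <- function(x, ...) {
  cat(sprintf("Seawater CO2 system at T = %.2f C, S = %.2f (total scale, 0 dbar)\n",
              x$temp, x$salinity))
  cat(sprintf("  pH_T = %.3f   A_T = %.0f umol/kg\n", x$pH_T, x$A_T))
  cat(sprintf("  HCO3- = %.0f  CO3-- = %.0f  CO2* = %.1f  DIC = %.0f umol/kg\n",
              x$hco3, x$co3, x$co2_star, x$dic))
  cat(sprintf("  pCO2 = %.0f uatm   Omega_arag = %.2f\n", x$pco2,
              x$omega_arag))
  cat(sprintf("  alkalinity residual = %.2g umol/kg\n", x$alk_residual))
  invisible(x)
}

#' @export
as.data.frame.carb_state <- function(x, ...) {
  data.frame(temp_c = x$temp, salinity = x$salinity, pH_T = x$pH_T,
             A_T = x$A_T, hco3 = x$hco3, co3 = x$co3,
             co2_star = x$co2_star, dic = x$dic, fco2 = x$fco2,
             pco2 = x$pco2, omega_arag = x$omega_arag,
             alk_residual = x$alk_residual,
             stringsAsFactors = FALSE)
}
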