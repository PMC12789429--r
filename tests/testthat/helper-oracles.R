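# Independent oracles kept deliberately naive: a plain bisection
# root-finder over pH for the carbonate system, with the alkalinity sum
# written out from first principles rather than calling the package's
# internal solver path.

# total alkalinity (mol/kg) at a given total-scale pH and DIC
oracle_alkalinity <- function(pH, dic_mol, k) {
  H <- 10^(-pH)
  a0_den <- H^2 + k$K1 * H + k$K1 * k$K2
  hco3 <- dic_mol * k$K1 * H / a0_den
  co3 <- dic_mol * k$K1 * k$K2 / a0_den
  borate <- k$BT / (1 + H / k$KB)
  oh <- k$KW / H
  h_free <- H / (1 + k$ST / k$KS)
  hso4 <- k$ST / (1 + k$KS / h_free)
  hf <- k$FT / (1 + k$KF / H)
  hco3 + 2 * co3 + borate + oh - h_free - hso4 - hf
}

# bisection over pH in [2, 12]; alkalinity decreases with increasing H
oracle_ph_from_dic_alk <- function(temp, sal, dic_umol, at_umol,
                                   iters = 60) {
  k <- carb_constants(temp, sal)
  dic <- dic_umol * 1e-6
  at <- at_umol * 1e-6
  lo <- 2; hi <- 12
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_alkalinity(mid, dic, k) < at) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# pCO2 (uatm) at a given pH and DIC, Weiss fugacity correction included
oracle_pco2 <- function(temp, sal, pH, dic_umol) {
  k <- carb_constants(temp, sal)
  H <- 10^(-pH)
  dic <- dic_umol * 1e-6
  co2 <- dic * H^2 / (H^2 + k$K1 * H + k$K1 * k$K2)
  B <- -1636.75 + 12.0408 * k$TK - 0.0327957 * k$TK^2 +
    3.16528e-5 * k$TK^3
  delta <- 57.7 - 0.118 * k$TK
  co2 / k$K0 / exp((B + 2 * delta) / (82.057 * k$TK)) * 1e6
}
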