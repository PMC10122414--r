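# Independent carbonate-system oracle: plain bisection on total-scale pH
# over [2, 12], with the alkalinity residual written out from the species
# definitions (carbonate + borate + water - H).  Shares only the equilibrium
# constant values with the package; root-finding and speciation arithmetic
# are independent of the production code path.
oracle_speciate <- function(dic, alk, temperature = 15, salinity = 35,
                            pressure = 0, n_iter = 200) {
  k <- co2_constants(temperature, salinity, pressure)
  residual <- function(ph) {
    h <- 10^(-ph)
    co2aq <- dic / (1 + k$k1 / h + k$k1 * k$k2 / h^2)
    hco3 <- co2aq * k$k1 / h
    co3 <- hco3 * k$k2 / h
    boh4 <- k$boron_total / (1 + h / k$kb)
    hco3 + 2 * co3 + boh4 + k$kw / h - h - alk
  }
  lo <- 2; hi <- 12
  if (sign(residual(lo)) == sign(residual(hi)))
    stop("oracle: no sign change on [2, 12]")
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (sign(residual(mid)) == sign(residual(lo))) lo <- mid else hi <- mid
  }
  ph <- (lo + hi) / 2
  h <- 10^(-ph)
  co2aq <- dic / (1 + k$k1 / h + k$k1 * k$k2 / h^2)
  hco3 <- co2aq * k$k1 / h
  co3 <- hco3 * k$k2 / h
  list(ph = ph, pco2 = co2aq / k$k0 * 1e6, co2aq = co2aq, hco3 = hco3,
       co3 = co3,
       omega_arg = k$calcium * co3 / k$ksp_arg,
       omega_cal = k$calcium * co3 / k$ksp_cal)
}

# Independently coded aragonite solubility product (Mucci 1983, surface)
# for the saturation-state cross-check.
oracle_ksp_arg_surface <- function(temperature, salinity) {
  tk <- temperature + 273.15
  10^(-171.945 - 0.077993 * tk + 2903.293 / tk + 71.595 * log10(tk) +
        (-0.068393 + 0.0017276 * tk + 88.135 / tk) * sqrt(salinity) -
        0.10018 * salinity + 0.0059415 * salinity^1.5)
}
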