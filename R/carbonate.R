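#' Seawater CO2-system equilibrium constants
#'
#' Evaluates the thermodynamic constants needed to speciate the seawater
#' inorganic carbon system: the CO2 solubility `K0` (Weiss 1974), the carbonic
#' acid dissociation constants `K1`, `K2` (Lueker et al. 2000 by default, Roy
#' et al. 1993 as an alternative; both on the total pH scale), the boric acid
#' constant `KB` (Dickson 1990), the water dissociation constant `Kw` (DOE
#' handbook), and the stoichiometric solubility products of calcite and
#' aragonite (Mucci 1983).  Pressure corrections follow the compilation of
#' Millero (1995).  Total boron is salinity-proportional (Uppstrom 1974) and
#' calcium is conservative with salinity, `Ca = 0.01028 * S / 35` mol/kg.
#'
#' All constants are on the total pH scale in mol/kg-seawater units.
#'
#' @param temperature Temperature, degrees C.
#' @param salinity Practical salinity.
#' @param pressure Applied (gauge) pressure, bar; 0 at the surface.
#' @param formulation Character key selecting the K1/K2 set: `"lueker00"`
#'   (default) or `"roy93"`.
#' @return A list of numeric vectors: `k0`, `k1`, `k2`, `kb`, `kw`, `ksp_cal`,
#'   `ksp_arg`, `boron_total`, `calcium` (all mol/kg or products thereof),
#'   recycled to a common length.
#' @export
co2_constants <- function(temperature, salinity, pressure = 0,
                          formulation = c("lueker00", "roy93")) {
  formulation <- match.arg(formulation)
  n <- max(length(temperature), length(salinity), length(pressure))
  tc <- rep_len(as.numeric(temperature), n)
  s  <- rep_len(as.numeric(salinity), n)
  p  <- rep_len(as.numeric(pressure), n)
  if (any(!is.finite(tc)) || any(!is.finite(s)) || any(!is.finite(p)))
    stop("non-finite temperature/salinity/pressure")
  if (any(s <= 0 | s >= 50)) stop("salinity outside (0, 50)")
  if (any(tc < -2 | tc > 40)) stop("temperature outside [-2, 40] degC")
  tk <- tc + 273.15
  lnt <- log(tk)
  ss <- sqrt(s)

  # Weiss (1974), mol kg-1 atm-1
  k0 <- exp(-60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
              s * (0.023517 - 0.023656 * (tk / 100) +
                     0.0047036 * (tk / 100)^2))

  if (formulation == "lueker00") {
    pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * lnt -
      0.011555 * s + 0.0001152 * s^2
    pk2 <- 471.78 / tk + 25.929 - 3.16967 * lnt -
      0.01781 * s + 0.0001122 * s^2
    k1 <- 10^(-pk1)
    k2 <- 10^(-pk2)
  } else {
    k1 <- exp(-2307.1266 / tk + 2.83655 - 1.5529413 * lnt +
                (-4.0484 / tk - 0.20760841) * ss + 0.08468345 * s -
                0.00654208 * s^1.5 + log(1 - 0.001005 * s))
    k2 <- exp(-3351.6106 / tk - 9.226508 - 0.2005743 * lnt +
                (-23.9722 / tk - 0.106901773) * ss + 0.1130822 * s -
                0.00846934 * s^1.5 + log(1 - 0.001005 * s))
  }

  # Dickson (1990), total scale
  kb <- exp((-8966.90 - 2890.53 * ss - 77.942 * s +
               1.728 * s^1.5 - 0.0996 * s^2) / tk +
              148.0248 + 137.1942 * ss + 1.62142 * s +
              (-24.4344 - 25.085 * ss - 0.2474 * s) * lnt +
              0.053105 * ss * tk)

  # DOE handbook (Millero 1995), total scale
  kw <- exp(148.9652 - 13847.26 / tk - 23.6521 * lnt +
              (118.67 / tk - 5.977 + 1.0495 * lnt) * ss - 0.01615 * s)

  # Mucci (1983), (mol/kg)^2
  log10t <- log10(tk)
  ksp_cal <- 10^(-171.9065 - 0.077993 * tk + 2839.319 / tk +
                   71.595 * log10t +
                   (-0.77712 + 0.0028426 * tk + 178.34 / tk) * ss -
                   0.07711 * s + 0.0041249 * s^1.5)
  ksp_arg <- 10^(-171.945 - 0.077993 * tk + 2903.293 / tk +
                   71.595 * log10t +
                   (-0.068393 + 0.0017276 * tk + 88.135 / tk) * ss -
                   0.10018 * s + 0.0059415 * s^1.5)

  # Millero (1995) pressure corrections, R = 83.131 cm3 bar mol-1 K-1
  if (any(p > 0)) {
    rt <- 83.131 * tk
    pc <- function(k, dv, dk) k * exp((-dv + 0.5 * dk * p) * p / rt)
    k1 <- pc(k1, -25.50 + 0.1271 * tc, (-3.08 + 0.0877 * tc) / 1000)
    k2 <- pc(k2, -15.82 - 0.0219 * tc, (1.13 - 0.1475 * tc) / 1000)
    kb <- pc(kb, -29.48 + 0.1622 * tc + 0.002608 * tc^2, -2.84 / 1000)
    kw <- pc(kw, -20.02 + 0.1119 * tc - 0.001409 * tc^2,
             (-5.13 + 0.0794 * tc) / 1000)
    dk_sp <- (-11.76 + 0.3692 * tc) / 1000
    ksp_cal <- pc(ksp_cal, -48.76 + 0.5304 * tc, dk_sp)
    ksp_arg <- pc(ksp_arg, -46.00 + 0.5304 * tc, dk_sp)
  }

  list(k0 = k0, k1 = k1, k2 = k2, kb = kb, kw = kw,
       ksp_cal = ksp_cal, ksp_arg = ksp_arg,
       boron_total = 0.000416 * s / 35,
       calcium = 0.01028 * s / 35)
}

# Total alkalinity implied by (dic, h) at constants k: carbonate + borate +
# water contributions minus free protons (total scale).
alk_from_h <- function(dic, h, k) {
  d <- h * h + k$k1 * h + k$k1 * k$k2
  dic * k$k1 * (h + 2 * k$k2) / d +
    k$boron_total * k$kb / (k$kb + h) +
    k$kw / h - h
}

# d(alk)/d(h) at fixed dic — analytic, for Newton polishing.
dalk_dh <- function(dic, h, k) {
  d <- h * h + k$k1 * h + k$k1 * k$k2
  num <- h + 2 * k$k2
  dic * k$k1 * (d - num * (2 * h + k$k1)) / (d * d) -
    k$boron_total * k$kb / (k$kb + h)^2 -
    k$kw / (h * h) - 1
}

# Vectorized hybrid root solve for [H+]: bracketed bisection on pH in ph_range
# followed by Newton polishing.  Returns h (mol/kg).  Errors if the residual
# does not change sign across the bracket.
solve_h <- function(dic, alk, k, ph_range = c(2, 12), tol = 1e-8) {
  lo <- rep_len(10^(-ph_range[2]), length(dic))
  hi <- rep_len(10^(-ph_range[1]), length(dic))
  f_lo <- alk_from_h(dic, lo, k) - alk
  f_hi <- alk_from_h(dic, hi, k) - alk
  bad <- sign(f_lo) == sign(f_hi)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("carbonate solver: no pH root in [%g, %g] for ",
                        "dic = %.6g mol/kg, alk = %.6g mol/kg (state %d)"),
                 ph_range[1], ph_range[2], dic[i], alk[i], which(bad)[1]))
  }
  # alk is monotone decreasing in h, so f(lo) > 0 > f(hi); 40 bisections
  # bound pH to ~1e-11, beyond the requested tolerance.
  n_iter <- max(30L, ceiling(log2(diff(ph_range) / tol)))
  for (it in seq_len(min(n_iter, 60L))) {
    mid <- sqrt(lo * hi)   # bisect in pH (log h)
    f_mid <- alk_from_h(dic, mid, k) - alk
    pos <- f_mid > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  h <- sqrt(lo * hi)
  for (it in 1:3) {
    f <- alk_from_h(dic, h, k) - alk
    h_new <- h - f / dalk_dh(dic, h, k)
    ok <- is.finite(h_new) & h_new > 0
    h[ok] <- h_new[ok]
  }
  h
}

# Fast warm-started Newton for the model inner loop; falls back to the
# bracketed solve for any state that fails to converge.
solve_h_fast <- function(dic, alk, k, h_guess) {
  h <- h_guess
  for (it in 1:6) {
    f <- alk_from_h(dic, h, k) - alk
    h_new <- h - f / dalk_dh(dic, h, k)
    bad <- !is.finite(h_new) | h_new <= 0
    h_new[bad] <- h[bad]
    if (all(abs(h_new - h) <= 1e-13 * h)) {
      return(h_new)
    }
    h <- h_new
  }
  resid <- abs(alk_from_h(dic, h, k) - alk)
  if (any(resid > 1e-12)) {
    redo <- resid > 1e-12
    k_sub <- lapply(k, function(x) if (length(x) > 1) x[redo] else x)
    h[redo] <- solve_h(dic[redo], alk[redo], k_sub)
  }
  h
}

speciate_at_h <- function(dic, h, k) {
  d <- h * h + k$k1 * h + k$k1 * k$k2
  co2aq <- dic * h * h / d
  list(co2aq = co2aq,
       hco3 = dic * k$k1 * h / d,
       co3 = dic * k$k1 * k$k2 / d,
       pco2 = co2aq / k$k0 * 1e6)
}

#' Solve the seawater inorganic carbon system from DIC and alkalinity
#'
#' Given dissolved inorganic carbon and total alkalinity (plus temperature,
#' salinity and pressure), finds the total-scale pH that closes the
#' alkalinity balance (carbonate + borate + water contributions) and returns
#' the full speciation: aqueous CO2, bicarbonate, carbonate ion, pCO2, and the
#' calcite/aragonite saturation states.
#'
#' The root solve brackets pH in `ph_range` and bisects to `tol` pH units,
#' then polishes with Newton steps, so the returned state satisfies the DIC
#' mass balance and reproduces the input alkalinity to near machine
#' precision.  The solver is deterministic and vectorized over states.
#'
#' The limiting case `dic = 0` is handled exactly: no carbon species exist
#' (`pco2 = co3 = 0`) and pH is set by borate and water alone.
#'
#' @param dic Dissolved inorganic carbon, mol per kg seawater (>= 0).
#' @param alk Total alkalinity, mol-equivalent per kg seawater.
#' @inheritParams co2_constants
#' @param ph_range Bracket for the total-scale pH root (default `c(2, 12)`).
#' @param tol Bisection tolerance in pH units.
#' @return A `carbonate_state` data.frame with columns `dic`, `alk`,
#'   `temperature`, `salinity`, `pressure`, `ph`, `h`, `co2aq`, `hco3`,
#'   `co3` (mol/kg), `pco2` (uatm), `omega_cal`, `omega_arg`.
#' @examples
#' solve_speciation(2050e-6, 2350e-6, temperature = 15, salinity = 35)
#' @export
solve_speciation <- function(dic, alk, temperature = 15, salinity = 35,
                             pressure = 0,
                             formulation = c("lueker00", "roy93"),
                             ph_range = c(2, 12), tol = 1e-8) {
  n <- max(length(dic), length(alk), length(temperature), length(salinity),
           length(pressure))
  dic <- rep_len(as.numeric(dic), n)
  alk <- rep_len(as.numeric(alk), n)
  if (any(!is.finite(dic)) || any(!is.finite(alk)))
    stop("non-finite dic/alk")
  if (any(dic < 0)) stop("dic must be >= 0")
  k <- co2_constants(rep_len(temperature, n), rep_len(salinity, n),
                     rep_len(pressure, n), formulation)
  h <- solve_h(dic, alk, k, ph_range = ph_range, tol = tol)
  sp <- speciate_at_h(dic, h, k)
  out <- data.frame(
    dic = dic, alk = alk,
    temperature = rep_len(as.numeric(temperature), n),
    salinity = rep_len(as.numeric(salinity), n),
    pressure = rep_len(as.numeric(pressure), n),
    ph = -log10(h), h = h,
    co2aq = sp$co2aq, hco3 = sp$hco3, co3 = sp$co3, pco2 = sp$pco2,
    omega_cal = k$calcium * sp$co3 / k$ksp_cal,
    omega_arg = k$calcium * sp$co3 / k$ksp_arg)
  class(out) <- c("carbonate_state", "data.frame")
  out
}

#' Carbonate mineral saturation state
#'
#' Omega = \[Ca2+\]\[CO3 2-\] / Ksp(mineral, T, S, P).  Omega > 1 favors
#' precipitation (and calcification); Omega = 0 iff the carbonate ion
#' concentration is zero.
#'
#' @param co3 Carbonate ion concentration, mol/kg (>= 0).
#' @param calcium Calcium concentration, mol/kg (> 0).  Defaults to the
#'   salinity-conservative value `0.01028 * S / 35`.
#' @inheritParams co2_constants
#' @param mineral `"aragonite"` or `"calcite"`.
#' @return Numeric vector of saturation states (dimensionless).
#' @export
saturation_state <- function(co3, calcium = NULL, temperature = 15,
                             salinity = 35, pressure = 0,
                             mineral = c("aragonite", "calcite")) {
  mineral <- match.arg(mineral)
  if (any(co3 < 0)) stop("co3 must be >= 0")
  k <- co2_constants(temperature, salinity, pressure)
  if (is.null(calcium)) calcium <- k$calcium
  if (any(calcium <= 0)) stop("calcium must be > 0")
  ksp <- if (mineral == "aragonite") k$ksp_arg else k$ksp_cal
  calcium * co3 / ksp
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf("<carbonate_state: %d state%s>\n", nrow(x),
              if (nrow(x) == 1) "" else "s"))
  print.data.frame(utils::head(as.data.frame(x)[
    , c("dic", "alk", "temperature", "ph", "pco2", "co3", "omega_arg")]),
    digits = 5, ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}
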