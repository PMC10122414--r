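#' Default climate-response parameters
#'
#' Two-layer global energy-balance parameters: radiative forcing per CO2
#' doubling `f2x` (W m-2), climate feedback `lambda` (W m-2 K-1, so the
#' equilibrium climate sensitivity is `f2x/lambda`), deep-ocean heat exchange
#' coefficient `gamma`, mixed-layer and deep heat capacities `c_ml`, `c_deep`
#' (W yr m-2 K-1), and the land warming amplification factor applied to the
#' global anomaly to drive the terrestrial biosphere.
#'
#' @return Named list of parameters.
#' @export
climate_params <- function() {
  list(f2x = 3.71, lambda = 3.71 / 3.0, gamma = 0.7,
       c_ml = 7.3, c_deep = 106,
       land_amplification = 1.4)
}

#' Radiative forcing from greenhouse-gas abundances
#'
#' CO2 forcing is logarithmic in concentration; CH4 and N2O use simplified
#' square-root expressions (band overlap neglected — adequate at the <0.1
#' W m-2 level for these trajectories).  Forcing is zero at the preindustrial
#' reference abundances.
#'
#' @param co2_ppm,ch4_ppb,n2o_ppb Abundances (vectors recycle).
#' @param params Climate parameter list from [climate_params()].
#' @return Radiative forcing, W m-2.
#' @export
radiative_forcing <- function(co2_ppm, ch4_ppb = erw_constants$ch4_ppb_pi,
                              n2o_ppb = erw_constants$n2o_ppb_pi,
                              params = climate_params()) {
  if (any(co2_ppm <= 0)) stop("co2_ppm must be > 0")
  params$f2x / log(2) * log(co2_ppm / erw_constants$co2_ppm_pi) +
    0.036 * (sqrt(ch4_ppb) - sqrt(erw_constants$ch4_ppb_pi)) +
    0.12 * (sqrt(n2o_ppb) - sqrt(erw_constants$n2o_ppb_pi))
}

#' Advance the two-layer energy-balance climate model by one step
#'
#' Explicit Euler update of the mixed-layer temperature anomaly `t_surf` and
#' deep-ocean anomaly `t_deep` under radiative forcing `forcing`:
#' `c_ml dT/dt = F - lambda T - gamma (T - T_d)`,
#' `c_deep dT_d/dt = gamma (T - T_d)`.
#' The land anomaly is `land_amplification * t_surf`.
#'
#' @param state List with `t_surf`, `t_deep` (degrees C anomaly).
#' @param forcing Radiative forcing, W m-2.
#' @param dt Time step, years.
#' @param params Climate parameter list.
#' @return Updated state list with `t_surf`, `t_deep`, `t_land`.
#' @export
climate_step <- function(state, forcing, dt, params = climate_params()) {
  ts <- state$t_surf
  td <- state$t_deep
  ts_new <- ts + dt * (forcing - params$lambda * ts -
                         params$gamma * (ts - td)) / params$c_ml
  td_new <- td + dt * params$gamma * (ts - td) / params$c_deep
  list(t_surf = ts_new, t_deep = td_new,
       t_land = params$land_amplification * ts_new)
}

#' Global temperature anomaly series for prescribed concentrations
#'
#' Integrates the two-layer energy balance model over a concentration
#' pathway with CO2 (and CH4/N2O) prescribed, with no carbon-cycle feedback.
#' Used to build the offline temperature forcing that drives stand-alone slab
#' biosphere runs during ensemble filtering.
#'
#' @param pathway A `concentration_pathway` (see [synthesize_pathway()]).
#' @param dt Integration step, years.
#' @param params Climate parameter list.
#' @return data.frame with `year`, `t_surf`, `t_land` (anomalies, degrees C).
#' @export
climate_series <- function(pathway, dt = 0.1, params = climate_params()) {
  years <- pathway$year
  st <- list(t_surf = 0, t_deep = 0, t_land = 0)
  out_ts <- numeric(length(years))
  out_tl <- numeric(length(years))
  out_ts[1] <- 0; out_tl[1] <- 0
  n_sub <- max(1L, round(1 / dt))
  for (i in seq_along(years)[-1]) {
    f0 <- radiative_forcing(pathway$co2[i - 1], pathway$ch4[i - 1],
                            pathway$n2o[i - 1], params)
    f1 <- radiative_forcing(pathway$co2[i], pathway$ch4[i],
                            pathway$n2o[i], params)
    for (s in seq_len(n_sub)) {
      frac <- (s - 0.5) / n_sub
      st <- climate_step(st, f0 + frac * (f1 - f0), 1 / n_sub, params)
    }
    out_ts[i] <- st$t_surf
    out_tl[i] <- st$t_land
  }
  data.frame(year = years, t_surf = out_ts, t_land = out_tl)
}
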