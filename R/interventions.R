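#' Feedstock stoichiometry for enhanced rock weathering
#'
#' Dissolution of silicate feedstock (wollastonite-like,
#' `CaSiO3 + 2 CO2 + 3 H2O -> Ca2+ + 2 HCO3- + H4SiO4`) captures 2 mol CO2
#' and delivers 2 mol DIC + 2 eq ALK, i.e. 1 mol DIC and 1 eq ALK per mol
#' CO2 captured.  Carbonate feedstock
#' (`CaCO3 + CO2 + H2O -> Ca2+ + 2 HCO3-`) captures 1 mol CO2 and delivers
#' 2 mol DIC + 2 eq ALK per mol captured; the extra mol of carbon is
#' rock-derived and is tagged separately so conservation audits close.
#'
#' @param feedstock `"silicate"` or `"carbonate"`.
#' @return List with `dic_per_co2`, `alk_per_co2` (mol per mol CO2
#'   captured) and `rock_per_co2` (rock-derived mol C per mol captured).
#' @export
feedstock_stoichiometry <- function(feedstock = c("silicate", "carbonate")) {
  feedstock <- match.arg(feedstock)
  if (feedstock == "silicate")
    list(dic_per_co2 = 1, alk_per_co2 = 1, rock_per_co2 = 0)
  else
    list(dic_per_co2 = 2, alk_per_co2 = 2, rock_per_co2 = 1)
}

#' ERW deployment fluxes from a capture rate
#'
#' Translates a CDR deployment rate into the atmospheric removal and the
#' river-delivered DIC and alkalinity inputs implied by the feedstock
#' stoichiometry.
#'
#' @param rate CDR rate, GtCO2/yr (vectorized, >= 0).
#' @param feedstock `"silicate"` or `"carbonate"`.
#' @return List: `atm_removal` (GtCO2/yr), `dic_input`, `alk_input`
#'   (mol/yr and mol-eq/yr), `rock_carbon` (GtCO2/yr of rock-derived carbon
#'   delivered beyond the captured CO2).
#' @export
erw_fluxes <- function(rate, feedstock = c("silicate", "carbonate")) {
  if (any(rate < 0)) stop("rate must be >= 0")
  st <- feedstock_stoichiometry(feedstock)
  mol <- gtco2_to_mol(rate)
  list(atm_removal = rate,
       dic_input = st$dic_per_co2 * mol,
       alk_input = st$alk_per_co2 * mol,
       rock_carbon = st$rock_per_co2 * rate)
}

#' Describe a carbon cycle intervention
#'
#' Two end-member deployment modes: `"baseline"` (emissions reduced by the
#' rate — equivalently direct removal with permanent storage) and `"erw"`
#' (the rate is captured from the atmosphere and delivered to the surface
#' ocean as DIC + alkalinity per the feedstock stoichiometry).  Rates for
#' the standard experiments lie in 0.5-40 GtCO2/yr; a constant 10 GtCO2/yr
#' from 2030 is the default experiment.
#'
#' @param mode `"baseline"` or `"erw"`.
#' @param feedstock `"silicate"`, `"carbonate"`, or `"none"` (baseline).
#' @param rate Constant rate (GtCO2/yr) or data.frame `year`, `rate`.
#' @param start_year First year of deployment.
#' @param routing Per-surface-box delivery weights (sum to 1); default all
#'   to the low-latitude surface box, which holds the coastal margins in
#'   the reduced geometry.
#' @return An `intervention` list.
#' @export
intervention <- function(mode = c("baseline", "erw"),
                         feedstock = c("none", "silicate", "carbonate"),
                         rate = 10, start_year = 2030,
                         routing = c(1, 0)) {
  mode <- match.arg(mode)
  feedstock <- match.arg(feedstock)
  if (mode == "erw" && feedstock == "none")
    stop("erw mode requires a feedstock")
  rates <- if (is.data.frame(rate)) rate$rate else rate
  if (any(rates < 0)) stop("rate must be >= 0")
  if (any(routing < 0) || abs(sum(routing) - 1) > 1e-12)
    stop("routing weights must be >= 0 and sum to 1")
  iv <- list(mode = mode, feedstock = feedstock, rate = rate,
             start_year = start_year, routing = routing)
  class(iv) <- "intervention"
  iv
}

# Deployment rate per year (0 before start_year).
intervention_rate <- function(iv, years) {
  r <- if (is.data.frame(iv$rate)) {
    stats::approx(iv$rate$year, iv$rate$rate, xout = years, rule = 2)$y
  } else rep(iv$rate, length(years))
  r[years < iv$start_year] <- 0
  r
}

#' Apply a baseline intervention to a control emission trajectory
#'
#' `emissions(t) = control(t) - rate(t)` for `t >= start_year`.  Emissions
#' may go negative (net removal); this is allowed and flagged in the
#' result's `net_negative` attribute.
#'
#' @param control_emissions data.frame `year`, `emission` (GtCO2/yr).
#' @param iv An `intervention` with `mode = "baseline"`.
#' @return Perturbed emission data.frame.
#' @export
apply_baseline <- function(control_emissions, iv) {
  if (iv$mode != "baseline") stop("intervention mode must be 'baseline'")
  out <- control_emissions
  out$emission <- out$emission - intervention_rate(iv, out$year)
  attr(out, "net_negative") <- any(out$emission < 0)
  out
}

#' Run a control simulation for one scenario
#'
#' Prescribed-CO2 run from the spun-up 1765 state along a concentration
#' pathway, diagnosing the implied emission trajectory and recording the
#' state snapshot at the intervention branch year.  The diagnosed emissions
#' define the control for all intervention experiments (re-running the model
#' emission-driven with them reproduces the prescribed CO2 to below 1 ppm).
#'
#' @param world Spun-up `world_state` (from [spinup()]).
#' @param pathway A `concentration_pathway`.
#' @param slab_par A `slab_params`.
#' @param years Run years (default 1765-2100).
#' @param branch_year Year whose start-of-year state is snapshotted.
#' @param dt Time step, years.
#' @return List: `ledger` (control `run_ledger`), `emissions` (data.frame
#'   `year`, `emission`, GtCO2/yr, with provenance attribute), `branch`
#'   (the `world_state` at `branch_year`).
#' @export
run_control <- function(world, pathway, slab_par, years = 1765:2100,
                        branch_year = 2030, dt = world$config$dt) {
  res <- integrate_world(world, years, mode = "prescribed",
                         pathway = pathway, slab_par = slab_par, dt = dt,
                         snapshot_years = branch_year)
  emis <- data.frame(year = years, emission = res$ledger$emissions)
  attr(emis, "provenance") <- attr(pathway, "label")
  list(ledger = res$ledger, emissions = emis,
       branch = res$snapshots[[as.character(branch_year)]],
       pathway = pathway)
}

#' Run an intervention experiment against a control
#'
#' Branches from the control's saved state at the intervention start year
#' and integrates emission-driven with the control's diagnosed emissions,
#' applying the intervention (baseline emission modulation, or ERW
#' atmospheric removal plus routed DIC/alkalinity delivery) each step.  A
#' rate-zero intervention reproduces the control trajectory to machine
#' tolerance.  Any conservation audit failure aborts with diagnostics.
#'
#' @param control Result of [run_control()].
#' @param iv An `intervention` (or NULL for a control rerun).
#' @param slab_par The same `slab_params` used for the control.
#' @param end_year Last simulated year.
#' @param dt Time step, years.
#' @return The experiment `run_ledger` (years `start_year` to `end_year`).
#' @export
run_experiment <- function(control, iv, slab_par,
                           end_year = max(control$emissions$year),
                           dt = control$branch$config$dt) {
  years <- control$branch$year:end_year
  res <- integrate_world(control$branch, years, mode = "emission",
                         pathway = control$pathway,
                         emissions = control$emissions, intervention = iv,
                         slab_par = slab_par, dt = dt)
  res$ledger
}
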