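#' Default four-box ocean geometry
#'
#' The reduced ocean resolves the minimum structure needed to separate
#' mixed-layer air-sea re-equilibration from interior carbon storage: a warm
#' low-latitude surface box, a cold high-latitude surface box (the site of
#' deep-water formation), an intermediate box, and a deep box.  Volumes sum
#' to 1.33e18 m3 and surface areas to the global ocean area.
#'
#' `t_ref` are preindustrial box temperatures; surface boxes warm with the
#' global mixed-layer anomaly scaled by `t_anom_factor` (interior boxes are
#' held at their reference temperature — interior warming is slow relative
#' to the run lengths considered).  `depth_mean` sets the pressure used for
#' in-situ carbonate chemistry, `pressure ~ depth/10` bar.
#'
#' @param volume,area,depth_mean,t_ref,t_anom_factor,salinity Per-box values
#'   (four boxes: `surf_low`, `surf_high`, `intermediate`, `deep`).
#' @return A `box_geometry` list.
#' @export
box_geometry <- function(volume = c(3.08e16, 1.35e16, 2.49e17, 1.0375e18),
                         area = c(3.08e14, 0.54e14, 0, 0),
                         depth_mean = c(50, 125, 550, 2500),
                         t_ref = c(21.5, 2.5, 8, 2),
                         t_anom_factor = c(0.8, 0.8, 0, 0),
                         salinity = 34.7) {
  g <- list(names = c("surf_low", "surf_high", "intermediate", "deep"),
            volume = volume, area = area, depth_mean = depth_mean,
            t_ref = t_ref, t_anom_factor = t_anom_factor,
            salinity = salinity,
            pressure = depth_mean / 10)
  validate_box_geometry(g)
  class(g) <- "box_geometry"
  g
}

validate_box_geometry <- function(g, volume_tol = 0.10) {
  if (any(g$volume <= 0)) stop("box volumes must be > 0")
  if (any(g$area < 0)) stop("surface areas must be >= 0")
  vtot <- sum(g$volume)
  if (abs(vtot - erw_constants$ocean_volume) / erw_constants$ocean_volume >
        volume_tol)
    stop(sprintf("total ocean volume %.3g m3 outside %g%% of %.3g m3",
                 vtot, 100 * volume_tol, erw_constants$ocean_volume))
  atot <- sum(g$area)
  if (abs(atot - erw_constants$ocean_area) / erw_constants$ocean_area > 0.02)
    stop("surface areas must sum to the global ocean area")
  invisible(g)
}

#' Default circulation configuration
#'
#' A single overturning cell (high-latitude surface -> deep -> intermediate
#' -> low-latitude surface -> high-latitude surface) plus bidirectional
#' mixing between vertically adjacent boxes, all in Sverdrups.  These rates,
#' together with the piston velocity, were fixed once so that the control
#' run's cumulative historical ocean uptake is ~30% of diagnosed emissions.
#'
#' @param overturning_sv Overturning rate, Sv.
#' @param mix_low_int_sv,mix_int_deep_sv,mix_high_deep_sv Mixing rates, Sv.
#' @return A `circulation_config` list.
#' @export
circulation_config <- function(overturning_sv = 24, mix_low_int_sv = 45,
                               mix_int_deep_sv = 60, mix_high_deep_sv = 160) {
  c <- list(overturning_sv = overturning_sv,
            mix_low_int_sv = mix_low_int_sv,
            mix_int_deep_sv = mix_int_deep_sv,
            mix_high_deep_sv = mix_high_deep_sv)
  class(c) <- "circulation_config"
  c
}

# Volume flow matrix (m3/yr), flow[i, j] = transport from box i to box j.
# Boxes: 1 surf_low, 2 surf_high, 3 intermediate, 4 deep.
flow_matrix <- function(circ) {
  sv <- erw_constants$sv_m3yr
  f <- matrix(0, 4, 4)
  psi <- circ$overturning_sv * sv
  f[2, 4] <- f[2, 4] + psi   # high-lat sinking
  f[4, 3] <- f[4, 3] + psi   # deep upwelling into intermediate
  f[3, 1] <- f[3, 1] + psi   # intermediate to low-lat surface
  f[1, 2] <- f[1, 2] + psi   # surface return flow
  mix <- function(i, j, rate) {
    f[i, j] <<- f[i, j] + rate * sv
    f[j, i] <<- f[j, i] + rate * sv
  }
  mix(1, 3, circ$mix_low_int_sv)
  mix(3, 4, circ$mix_int_deep_sv)
  mix(2, 4, circ$mix_high_deep_sv)
  f
}

# Linear transport operator on concentrations: dc/dt = m %*% c.
transport_operator <- function(circ, geom) {
  f <- flow_matrix(circ)
  inflow <- abs(colSums(f) - rowSums(f))
  if (any(inflow > 1e-6 * max(f)))
    stop("circulation does not conserve volume per box")
  m <- t(f)
  diag(m) <- diag(m) - rowSums(f)
  m / geom$volume
}

#' Transport stability bound
#'
#' Largest explicit-Euler step for which concentrations remain non-negative:
#' `dt < min_j V_j / outflow_j`.
#'
#' @param circulation A `circulation_config`.
#' @param geometry A `box_geometry`.
#' @return Stability bound, years.
#' @export
transport_stability_dt <- function(circulation, geometry) {
  m <- transport_operator(circulation, geometry)
  1 / max(-diag(m))
}

#' Advance ocean tracers by one transport step
#'
#' Explicit conservative update `c <- c + dt * M c` of all tracer
#' concentrations under the overturning + mixing operator.  Total tracer
#' inventory is conserved to floating-point roundoff; `dt` above the
#' stability bound is an error (the bound is reported).
#'
#' @param ocean An `ocean_state` (see [ocean_state()]).
#' @param circulation A `circulation_config`.
#' @param dt Time step, years.
#' @return Updated `ocean_state`.
#' @export
transport_step <- function(ocean, circulation, dt) {
  bound <- transport_stability_dt(circulation, ocean$geometry)
  if (dt > bound)
    stop(sprintf("transport dt = %g y exceeds stability bound %g y",
                 dt, bound))
  m <- transport_operator(circulation, ocean$geometry)
  ocean$conc <- ocean$conc + dt * (m %*% ocean$conc)
  ocean
}

#' Construct an ocean state
#'
#' Holds per-box tracer concentrations (mol/m3) for DIC, alkalinity and the
#' nutrient, current box temperatures, and the geometry.
#'
#' @param dic,alk,po4 Per-box concentrations, mol/m3 (length 4).
#' @param temperature Per-box temperatures, degC.
#' @param geometry A `box_geometry`.
#' @return An `ocean_state` list with a 4 x 3 concentration matrix `conc`.
#' @export
ocean_state <- function(dic, alk, po4, temperature = NULL,
                        geometry = box_geometry()) {
  if (is.null(temperature)) temperature <- geometry$t_ref
  if (any(dic < 0) || any(alk < 0) || any(po4 < 0))
    stop("tracer concentrations must be >= 0")
  if (any(temperature < -2 | temperature > 40))
    stop("box temperatures outside [-2, 40] degC")
  st <- list(conc = cbind(dic = dic, alk = alk, po4 = po4),
             temperature = temperature, geometry = geometry)
  class(st) <- "ocean_state"
  st
}

#' Default biological pump configuration
#'
#' Surface nutrient uptake is first-order on the standing stock with a
#' per-box timescale (`tau_uptake`, years; slower at high latitudes to
#' emulate incomplete utilization).  Export production carries carbon at the
#' Redfield `c_to_p` ratio; CaCO3 is exported at `rain_ratio` times organic
#' carbon export and strips 1 DIC + 2 ALK per mol from the surface.  The
#' remineralization partitions give the destination-box fractions for
#' low-latitude export (intermediate/deep); high-latitude export
#' remineralizes in the deep box.
#'
#' @param tau_uptake Per-surface-box uptake timescale, years (length 2).
#' @param c_to_p Organic matter C:P stoichiometry.
#' @param rain_ratio CaCO3:organic-carbon export ratio (>= 0).
#' @param remin_org_low,remin_ca_low Fractions of low-latitude organic/CaCO3
#'   export remineralized in (intermediate, deep); each must sum to 1.
#' @return A `bio_config` list.
#' @export
bio_config <- function(tau_uptake = c(2, 10), c_to_p = 106,
                       rain_ratio = 0.08,
                       remin_org_low = c(0.6, 0.4),
                       remin_ca_low = c(0.3, 0.7)) {
  if (rain_ratio < 0) stop("rain_ratio must be >= 0")
  if (c_to_p <= 0) stop("c_to_p must be > 0")
  if (abs(sum(remin_org_low) - 1) > 1e-12 ||
      abs(sum(remin_ca_low) - 1) > 1e-12)
    stop("remineralization fractions must sum to 1")
  b <- list(tau_uptake = tau_uptake, c_to_p = c_to_p,
            rain_ratio = rain_ratio, remin_org_low = remin_org_low,
            remin_ca_low = remin_ca_low)
  class(b) <- "bio_config"
  b
}

# One biological pump update on a raw concentration matrix.  Returns the
# updated matrix plus export diagnostics (mol/yr).  Uptake is clipped to the
# available nutrient.
bio_apply <- function(conc, geom, bio, dt) {
  v <- geom$volume
  p_exp <- conc[1:2, "po4"] * v[1:2] / bio$tau_uptake          # mol P/yr
  p_exp <- pmin(p_exp, conc[1:2, "po4"] * v[1:2] / dt)         # clip
  corg <- bio$c_to_p * p_exp                                   # mol C/yr
  caco3 <- bio$rain_ratio * corg
  # surface removal
  conc[1:2, "po4"] <- conc[1:2, "po4"] - dt * p_exp / v[1:2]
  conc[1:2, "dic"] <- conc[1:2, "dic"] - dt * (corg + caco3) / v[1:2]
  conc[1:2, "alk"] <- conc[1:2, "alk"] - dt * 2 * caco3 / v[1:2]
  # interior return: low-lat split intermediate/deep, high-lat all deep
  org_to <- c(0, 0, bio$remin_org_low[1] * corg[1],
              bio$remin_org_low[2] * corg[1] + corg[2])
  ca_to <- c(0, 0, bio$remin_ca_low[1] * caco3[1],
             bio$remin_ca_low[2] * caco3[1] + caco3[2])
  p_to <- c(0, 0, bio$remin_org_low[1] * p_exp[1],
            bio$remin_org_low[2] * p_exp[1] + p_exp[2])
  conc[, "dic"] <- conc[, "dic"] + dt * (org_to + ca_to) / v
  conc[, "alk"] <- conc[, "alk"] + dt * 2 * ca_to / v
  conc[, "po4"] <- conc[, "po4"] + dt * p_to / v
  list(conc = conc, corg_export = sum(corg), caco3_export = sum(caco3))
}

#' Advance the biological pump by one step
#'
#' Surface nutrient drawdown drives organic-carbon and CaCO3 export which is
#' restored to the interior boxes by remineralization/dissolution; total
#' carbon, alkalinity and nutrient are conserved exactly (burial is a
#' separate step).
#'
#' @param ocean An `ocean_state`.
#' @param bio A `bio_config`.
#' @param dt Time step, years.
#' @return Updated `ocean_state` with attributes `corg_export` and
#'   `caco3_export` (mol/yr).
#' @export
biological_pump_step <- function(ocean, bio, dt) {
  r <- bio_apply(ocean$conc, ocean$geometry, bio, dt)
  ocean$conc <- r$conc
  attr(ocean, "corg_export") <- r$corg_export
  attr(ocean, "caco3_export") <- r$caco3_export
  ocean
}

#' Default sediment/burial configuration
#'
#' CaCO3 burial in deep-sea sediments is closed with a first-order response
#' to the deep-box calcite saturation state:
#' `burial = b0 * max(omega_cal - 1, 0)^n_exp` (mol CaCO3/yr), removing
#' 1 DIC + 2 ALK per mol from the deep box.  `b0` is set so the
#' preindustrial burial flux is of order 0.1 GtC/yr.
#'
#' @param b0 Burial coefficient, mol/yr per unit saturation excess.
#' @param n_exp Exponent on the saturation excess.
#' @return A `sediment_config` list.
#' @export
sediment_config <- function(b0 = 4e13, n_exp = 1) {
  s <- list(b0 = b0, n_exp = n_exp)
  class(s) <- "sediment_config"
  s
}

burial_rate <- function(omega_cal_deep, sed) {
  sed$b0 * max(omega_cal_deep - 1, 0)^sed$n_exp
}

#' Advance CaCO3 burial by one step
#'
#' Computes the deep-box calcite saturation state from the current deep DIC
#' and alkalinity, applies the first-order burial closure, and removes
#' 1 DIC + 2 ALK per mol buried from the deep box.
#'
#' @param ocean An `ocean_state`.
#' @param sediment A `sediment_config`.
#' @param dt Time step, years.
#' @return List with updated `ocean` and `burial_flux` (mol CaCO3/yr).
#' @export
burial_step <- function(ocean, sediment, dt) {
  g <- ocean$geometry
  rho <- erw_constants$rho_sw
  st <- solve_speciation(ocean$conc[4, "dic"] / rho,
                         ocean$conc[4, "alk"] / rho,
                         temperature = ocean$temperature[4],
                         salinity = g$salinity, pressure = g$pressure[4])
  b <- burial_rate(st$omega_cal, sediment)
  ocean$conc[4, "dic"] <- ocean$conc[4, "dic"] - dt * b / g$volume[4]
  ocean$conc[4, "alk"] <- ocean$conc[4, "alk"] - dt * 2 * b / g$volume[4]
  list(ocean = ocean, burial_flux = b)
}

#' Air-sea CO2 gas exchange flux
#'
#' Bulk flux law `F = kw * K0 * rho * (pCO2_ocean - pCO2_atm) * area`,
#' positive into the atmosphere when the ocean is supersaturated.  The flux
#' is linear in the disequilibrium; carbon is conserved exactly when the
#' same flux is debited from the box and credited to the atmosphere.
#'
#' @param pco2_ocean Surface-box seawater pCO2, uatm.
#' @param pco2_atm Atmospheric pCO2, uatm (= ppm at 1 atm total pressure).
#' @param k0 CO2 solubility at the box surface, mol kg-1 atm-1.
#' @param area Box surface area, m2.
#' @param piston_velocity Gas transfer (piston) velocity, m/yr.
#' @return Flux, mol CO2/yr, positive into the atmosphere.
#' @export
gas_exchange <- function(pco2_ocean, pco2_atm, k0, area,
                         piston_velocity = 1500) {
  if (any(piston_velocity <= 0)) stop("piston_velocity must be > 0")
  piston_velocity * k0 * erw_constants$rho_sw *
    (pco2_ocean - pco2_atm) * 1e-6 * area
}
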