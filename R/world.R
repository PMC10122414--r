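#' Assemble the full model configuration
#'
#' Bundles the box geometry, circulation, biological pump, sediment closure,
#' climate parameters, gas exchange, routing of natural weathering, and the
#' default time step into one configuration object.  All unit conversions
#' (GtC per ppm, GtC to GtCO2) come from [erw_constants] and are stated
#' there once.
#'
#' @param geometry,circulation,bio,sediment Component configurations.
#' @param climate Climate parameter list from [climate_params()].
#' @param piston_velocity Gas transfer velocity, m/yr.
#' @param dt Coupled-model time step, years.
#' @param t0_land Reference (preindustrial) global land temperature, degC.
#' @param routing_natural Per-surface-box routing weights for the natural
#'   weathering flux (sum to 1).
#' @return A `world_config` list.
#' @export
world_config <- function(geometry = box_geometry(),
                         circulation = circulation_config(),
                         bio = bio_config(),
                         sediment = sediment_config(),
                         climate = climate_params(),
                         piston_velocity = 1500,
                         dt = 0.1,
                         t0_land = 8.0,
                         routing_natural = c(1, 0)) {
  if (abs(sum(routing_natural) - 1) > 1e-12 || any(routing_natural < 0))
    stop("routing weights must be >= 0 and sum to 1")
  cfg <- list(geometry = geometry, circulation = circulation, bio = bio,
              sediment = sediment, climate = climate,
              piston_velocity = piston_velocity, dt = dt,
              t0_land = t0_land, routing_natural = routing_natural)
  class(cfg) <- "world_config"
  cfg
}

# Carbonate constants for the four boxes at given temperatures (cached by
# the integrator; pressure/salinity fixed by geometry).
box_constants <- function(temp, geom) {
  co2_constants(temp, geom$salinity, geom$pressure)
}

ocean_carbon_gtc <- function(conc, geom) {
  mol_to_gtc(sum(conc[, "dic"] * geom$volume))
}

#' Spin the ocean-climate system up to a preindustrial steady state
#'
#' Two-stage procedure.  Stage 1 integrates the ocean as a closed system
#' (no burial, no weathering) under fixed preindustrial atmospheric CO2
#' until the tracer fields are steady, then diagnoses the CaCO3 burial flux
#' the sediment closure would produce in that state.  Stage 2 switches on
#' burial together with a constant weathering input of equal magnitude
#' (delivering 1 DIC + 2 ALK per mol CaCO3, routed to the surface), and
#' integrates further until the drift in every reservoir is below
#' `drift_tol` (relative change per century).  The returned state is the
#' year-1765 restart used by every subsequent run.
#'
#' The integration replaces a literal multi-10-ky spinup with the same
#' fixed point reached by long accelerated stepping at `dt_spin`; the drift
#' test guarantees the result is steady to the stated tolerance.
#'
#' @param config A `world_config`.
#' @param years_stage1,years_stage2 Integration lengths, years.
#' @param dt_spin Spinup time step, years.
#' @param drift_tol Maximum relative reservoir drift per century.
#' @param dic0,alk0,po40 Initial mean concentrations, mol/kg.
#' @return A `world_state` list: atmosphere (`atm_gtc`, anomalies), ocean
#'   concentration matrix `conc`, warm-start protons `h`, diagnosed
#'   `weathering_mol_yr`, slab pools unset (`NA`), `year = 1765`, and the
#'   configuration.
#' @export
spinup <- function(config = world_config(), years_stage1 = 8000,
                   years_stage2 = 500, dt_spin = 0.5, drift_tol = 1e-4,
                   dic0 = 2.10e-3, alk0 = 2.36e-3, po40 = 2.15e-6) {
  g <- config$geometry
  rho <- erw_constants$rho_sw
  conc <- cbind(dic = rep(dic0 * rho, 4), alk = rep(alk0 * rho, 4),
                po4 = rep(po40 * rho, 4))
  temp <- g$t_ref
  k <- box_constants(temp, g)
  h <- rep(10^-8.1, 4)
  pco2_atm <- erw_constants$co2_ppm_pi

  run_stage <- function(conc, h, n_years, weathering, dt_stage = dt_spin) {
    m_op <- transport_operator(config$circulation, g)
    a_op <- diag(4) + dt_stage * m_op
    burial_sum <- 0
    n_steps <- round(n_years / dt_stage)
    for (i in seq_len(n_steps)) {
      conc <- a_op %*% conc
      colnames(conc) <- c("dic", "alk", "po4")
      b <- bio_apply(conc, g, config$bio, dt_stage)
      conc <- b$conc
      h <- solve_h_fast(conc[, "dic"] / rho, conc[, "alk"] / rho, k, h)
      sp <- speciate_at_h(conc[, "dic"] / rho, h, k)
      if (!is.null(weathering)) {
        omega_cal_deep <- k$calcium[4] * sp$co3[4] / k$ksp_cal[4]
        bur <- burial_rate(omega_cal_deep, config$sediment)
        conc[4, "dic"] <- conc[4, "dic"] - dt_stage * bur / g$volume[4]
        conc[4, "alk"] <- conc[4, "alk"] - dt_stage * 2 * bur / g$volume[4]
        w_in <- weathering * config$routing_natural
        conc[1:2, "dic"] <- conc[1:2, "dic"] + dt_stage * w_in / g$volume[1:2]
        conc[1:2, "alk"] <- conc[1:2, "alk"] +
          dt_stage * 2 * w_in / g$volume[1:2]
        burial_sum <- burial_sum + bur * dt_stage
      }
      flux <- gas_exchange(sp$pco2[1:2], pco2_atm, k$k0[1:2], g$area[1:2],
                           config$piston_velocity)
      conc[1:2, "dic"] <- conc[1:2, "dic"] - dt_stage * flux / g$volume[1:2]
    }
    list(conc = conc, h = h, mean_burial = burial_sum / n_years)
  }

  s1 <- run_stage(conc, h, years_stage1, weathering = NULL)
  # diagnose the burial flux the closure would give in the stage-1 state
  k4 <- lapply(box_constants(temp, g), `[`, 4)
  h4 <- solve_h_fast(s1$conc[4, "dic"] / rho, s1$conc[4, "alk"] / rho, k4,
                     s1$h[4])
  sp4 <- speciate_at_h(s1$conc[4, "dic"] / rho, h4, k4)
  weathering <- burial_rate(k4$calcium * sp4$co3 / k4$ksp_cal,
                            config$sediment)
  s2 <- run_stage(s1$conc, s1$h, years_stage2, weathering = weathering)

  # Newton polish of the open-system fixed point: solve map(x) = x where
  # map is the century propagator, accelerating past the slow
  # burial-alkalinity adjustment that plain integration resolves only on
  # multi-millennial timescales.
  century <- function(x) {
    r <- run_stage(matrix(x, 4, 3, dimnames = list(NULL,
                                                   c("dic", "alk", "po4"))),
                   s2$h, 100, weathering = weathering,
                   dt_stage = config$dt)
    as.numeric(r$conc)
  }
  x <- as.numeric(s2$conc)
  for (newton_it in 1:6) {
    fx <- century(x) - x
    if (max(abs(fx / x)) < 1e-11) break
    jac <- matrix(0, 12, 12)
    for (j in 1:12) {
      dx <- x
      eps <- 1e-6 * x[j]
      dx[j] <- dx[j] + eps
      jac[, j] <- (century(dx) - dx - fx) / eps
    }
    step <- tryCatch(solve(jac, -fx), error = function(e) NULL)
    if (is.null(step)) break
    x_new <- x + step
    if (any(x_new <= 0)) break
    x <- x_new
  }
  s2$conc <- matrix(x, 4, 3, dimnames = list(NULL, c("dic", "alk", "po4")))

  # drift audit over one century
  s3 <- run_stage(s2$conc, s2$h, 100, weathering = weathering,
                  dt_stage = config$dt)
  inv2 <- colSums(s2$conc * g$volume)
  inv3 <- colSums(s3$conc * g$volume)
  drift <- abs(inv3 - inv2) / inv2
  if (any(drift > drift_tol))
    stop(sprintf(
      "spinup failed to converge: reservoir drift per century = %s",
      paste(signif(drift, 3), collapse = ", ")))

  world <- list(year = 1765,
                atm_gtc = erw_constants$co2_ppm_pi * erw_constants$gtc_per_ppm,
                t_surf = 0, t_deep = 0,
                conc = s3$conc, h = s3$h,
                temperature = temp,
                v = NA_real_, s = NA_real_,
                weathering_mol_yr = weathering,
                config = config)
  class(world) <- "world_state"
  world
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf("<world_state year %s>\n", format(x$year)))
  cat(sprintf("  atmosphere: %.1f ppm (%.0f GtC), anomaly %.2f degC\n",
              x$atm_gtc / erw_constants$gtc_per_ppm, x$atm_gtc, x$t_surf))
  cat(sprintf("  ocean DIC %.0f GtC; slab V %.0f, S %.0f GtC\n",
              ocean_carbon_gtc(x$conc, x$config$geometry), x$v, x$s))
  invisible(x)
}

# --- coupled integrator -----------------------------------------------------

# Integrate the coupled world over consecutive integer `years`.
# mode "prescribed": atmospheric CO2 follows `pathway`; the implied emission
#   is diagnosed each step.  mode "emission": atmospheric CO2 is prognostic,
#   driven by `emissions` (data.frame year, emission in GtCO2/yr).
# `intervention` (or NULL) is applied from its start year.  Returns the
# annual run ledger, optional state snapshots (taken at the start of the
# requested years), and the final state.  Aborts if the whole-system carbon
# audit fails.
integrate_world <- function(world, years, mode = c("emission", "prescribed"),
                            pathway, emissions = NULL, intervention = NULL,
                            slab_par, dt = world$config$dt,
                            snapshot_years = integer(0)) {
  mode <- match.arg(mode)
  cfg <- world$config
  g <- cfg$geometry
  rho <- erw_constants$rho_sw
  gtc_per_ppm <- erw_constants$gtc_per_ppm
  co2_gt <- erw_constants$gtco2_per_gtc
  n_yr <- length(years)
  if (any(diff(years) != 1)) stop("years must be consecutive")

  idx <- match(c(years, years[n_yr] + 1), pathway$year)
  if (any(is.na(idx)))
    stop("pathway must cover the run years plus one trailing year")
  co2_p <- pathway$co2[idx]; ch4_p <- pathway$ch4[idx]
  n2o_p <- pathway$n2o[idx]

  if (mode == "emission") {
    if (is.null(emissions)) stop("emission mode needs an emissions series")
    e_idx <- match(years, emissions$year)
    if (any(is.na(e_idx))) stop("emissions must cover the run years")
    emis_yr <- emissions$emission[e_idx]   # GtCO2/yr
  } else {
    emis_yr <- rep(NA_real_, n_yr)
  }

  # intervention series (all zero when NULL)
  cdr_yr <- numeric(n_yr); erw_dic_yr <- numeric(n_yr)
  erw_alk_yr <- numeric(n_yr); erw_rock_yr <- numeric(n_yr)
  route <- c(1, 0)
  if (!is.null(intervention)) {
    route <- intervention$routing
    act <- years >= intervention$start_year
    r <- intervention_rate(intervention, years)   # GtCO2/yr
    cdr_yr[act] <- r[act]
    if (intervention$mode == "baseline") {
      if (mode != "emission")
        stop("baseline interventions require emission-driven mode")
      emis_yr <- emis_yr - cdr_yr
    } else {
      fx <- erw_fluxes(r, intervention$feedstock)
      erw_dic_yr[act] <- fx$dic_input[act]
      erw_alk_yr[act] <- fx$alk_input[act]
      erw_rock_yr[act] <- fx$rock_carbon[act]    # GtCO2/yr of rock-derived C
    }
  }

  n_sub <- max(1L, round(1 / dt))
  dt <- 1 / n_sub
  m_op <- transport_operator(cfg$circulation, g)
  if (dt > 1 / max(-diag(m_op)))
    stop("dt exceeds the transport stability bound")
  a_op <- diag(4) + dt * m_op

  conc <- world$conc
  h <- world$h
  atm_gtc <- if (mode == "prescribed") co2_p[1] * gtc_per_ppm else
    world$atm_gtc
  t_surf <- world$t_surf; t_deep <- world$t_deep
  v <- world$v; s <- world$s
  if (is.na(v) || is.na(s)) {
    ss <- slab_steady_state(slab_par)
    v <- ss$v_star; s <- ss$s_star
  }
  weathering <- world$weathering_mol_yr
  w_in <- weathering * cfg$routing_natural

  # ledger accumulators
  led <- list(emissions = numeric(n_yr), j_cdr = cdr_yr,
              j_sea_air = numeric(n_yr), j_lnd_air = numeric(n_yr),
              burial = numeric(n_yr),
              erw_dic = erw_dic_yr, erw_alk = erw_alk_yr,
              erw_rock = erw_rock_yr,
              co2_ppm = numeric(n_yr), t_anom = numeric(n_yr),
              veg = numeric(n_yr), soil = numeric(n_yr),
              ocean_dic_gtc = numeric(n_yr), ocean_alk_mol = numeric(n_yr),
              surf_omega_arg = numeric(n_yr), surf_pco2 = numeric(n_yr),
              deep_omega_cal = numeric(n_yr))
  snapshots <- list()

  # carbon audit
  cum_burial <- 0; cum_input <- 0
  total0 <- atm_gtc + mol_to_gtc(sum(conc[, "dic"] * g$volume)) + v + s

  k <- box_constants(g$t_ref, g)
  t_cached <- g$t_ref
  area_w <- g$area[1:2] / sum(g$area[1:2])
  clim <- cfg$climate

  for (iy in seq_len(n_yr)) {
    yr <- years[iy]
    if (yr %in% snapshot_years) {
      snapshots[[as.character(yr)]] <- list(
        year = yr, atm_gtc = atm_gtc, t_surf = t_surf, t_deep = t_deep,
        conc = conc, h = h, temperature = t_cached, v = v, s = s,
        weathering_mol_yr = weathering, config = cfg)
    }
    j_sea_sum <- 0; j_lnd_sum <- 0; e_sum <- 0; bur_sum <- 0
    for (sub in seq_len(n_sub)) {
      f0 <- (sub - 1) / n_sub
      f1 <- sub / n_sub
      co2_now <- if (mode == "prescribed")
        co2_p[iy] + f0 * (co2_p[iy + 1] - co2_p[iy]) else
          atm_gtc / gtc_per_ppm
      ch4_now <- ch4_p[iy] + f0 * (ch4_p[iy + 1] - ch4_p[iy])
      n2o_now <- n2o_p[iy] + f0 * (n2o_p[iy + 1] - n2o_p[iy])

      # climate
      forc <- clim$f2x / log(2) * log(co2_now / erw_constants$co2_ppm_pi) +
        0.036 * (sqrt(ch4_now) - sqrt(erw_constants$ch4_ppb_pi)) +
        0.12 * (sqrt(n2o_now) - sqrt(erw_constants$n2o_ppb_pi))
      t_surf_new <- t_surf + dt * (forc - clim$lambda * t_surf -
                                     clim$gamma * (t_surf - t_deep)) / clim$c_ml
      t_deep <- t_deep + dt * clim$gamma * (t_surf - t_deep) / clim$c_deep
      t_surf <- t_surf_new
      t_land <- cfg$t0_land + clim$land_amplification * t_surf

      # box temperatures and constants (recomputed when drift > 0.005 K)
      t_box <- g$t_ref + g$t_anom_factor * t_surf
      if (max(abs(t_box - t_cached)) > 0.005) {
        k <- box_constants(t_box, g)
        t_cached <- t_box
      }

      # transport
      conc <- a_op %*% conc

      # biological pump
      b <- bio_apply(`colnames<-`(conc, c("dic", "alk", "po4")), g,
                     cfg$bio, dt)
      conc <- b$conc

      # speciation
      h <- solve_h_fast(conc[, "dic"] / rho, conc[, "alk"] / rho, k, h)
      sp <- speciate_at_h(conc[, "dic"] / rho, h, k)

      # burial + natural weathering
      omega_cal_deep <- k$calcium[4] * sp$co3[4] / k$ksp_cal[4]
      bur <- burial_rate(omega_cal_deep, cfg$sediment)
      conc[4, "dic"] <- conc[4, "dic"] - dt * bur / g$volume[4]
      conc[4, "alk"] <- conc[4, "alk"] - dt * 2 * bur / g$volume[4]
      conc[1:2, "dic"] <- conc[1:2, "dic"] + dt * w_in / g$volume[1:2]
      conc[1:2, "alk"] <- conc[1:2, "alk"] + dt * 2 * w_in / g$volume[1:2]

      # ERW delivery + atmospheric removal
      cdr_gtc <- 0
      if (erw_dic_yr[iy] > 0 || erw_alk_yr[iy] > 0) {
        conc[1:2, "dic"] <- conc[1:2, "dic"] +
          dt * erw_dic_yr[iy] * route / g$volume[1:2]
        conc[1:2, "alk"] <- conc[1:2, "alk"] +
          dt * erw_alk_yr[iy] * route / g$volume[1:2]
      }
      if (!is.null(intervention) && intervention$mode == "erw")
        cdr_gtc <- gtco2_to_gtc(cdr_yr[iy])

      # gas exchange
      flux <- cfg$piston_velocity * k$k0[1:2] * rho *
        (sp$pco2[1:2] - co2_now) * 1e-6 * g$area[1:2]
      conc[1:2, "dic"] <- conc[1:2, "dic"] - dt * flux / g$volume[1:2]
      j_sea_gtc <- mol_to_gtc(sum(flux))

      # slab biosphere
      sl <- slab_step(list(v = v, s = s), co2_now, t_land, slab_par, dt)
      v <- sl$v; s <- sl$s
      j_lnd_gtc <- gtco2_to_gtc(sl$j_lnd_air)

      # atmosphere budget
      if (mode == "emission") {
        e_gtc <- gtco2_to_gtc(emis_yr[iy])
        atm_gtc <- atm_gtc + dt * (e_gtc + j_sea_gtc + j_lnd_gtc - cdr_gtc)
      } else {
        atm_target <- (co2_p[iy] + f1 * (co2_p[iy + 1] - co2_p[iy])) *
          gtc_per_ppm
        e_gtc <- (atm_target - atm_gtc) / dt -
          (j_sea_gtc + j_lnd_gtc - cdr_gtc)
        atm_gtc <- atm_target
      }

      cum_burial <- cum_burial + dt * mol_to_gtc(bur)
      cum_input <- cum_input + dt *
        (e_gtc + mol_to_gtc(weathering) + gtco2_to_gtc(erw_rock_yr[iy]))
      j_sea_sum <- j_sea_sum + flux[1] + flux[2]
      j_lnd_sum <- j_lnd_sum + sl$j_lnd_air
      e_sum <- e_sum + e_gtc
      bur_sum <- bur_sum + bur
    }
    led$emissions[iy] <- gtc_to_gtco2(e_sum * dt)
    led$j_sea_air[iy] <- gtc_to_gtco2(mol_to_gtc(j_sea_sum * dt))
    led$j_lnd_air[iy] <- j_lnd_sum * dt
    led$burial[iy] <- mol_to_gtc(bur_sum * dt)
    led$co2_ppm[iy] <- atm_gtc / gtc_per_ppm
    led$t_anom[iy] <- t_surf
    led$veg[iy] <- v; led$soil[iy] <- s
    led$ocean_dic_gtc[iy] <- mol_to_gtc(sum(conc[, "dic"] * g$volume))
    led$ocean_alk_mol[iy] <- sum(conc[, "alk"] * g$volume)
    led$surf_omega_arg[iy] <-
      sum(area_w * k$calcium[1:2] * sp$co3[1:2] / k$ksp_arg[1:2])
    led$surf_pco2[iy] <- sum(area_w * sp$pco2[1:2])
    led$deep_omega_cal[iy] <- k$calcium[4] * sp$co3[4] / k$ksp_cal[4]
  }

  total1 <- atm_gtc + mol_to_gtc(sum(conc[, "dic"] * g$volume)) + v + s +
    cum_burial
  audit <- abs((total1 - total0) - cum_input) / total0
  if (audit > 1e-6)
    stop(sprintf("carbon conservation audit failed: residual %.3g relative",
                 audit))

  ledger <- data.frame(year = years, led)
  attr(ledger, "mode") <- mode
  attr(ledger, "label") <- attr(pathway, "label")
  attr(ledger, "intervention") <- intervention
  attr(ledger, "carbon_audit") <- audit
  class(ledger) <- c("run_ledger", "data.frame")

  final <- list(year = years[n_yr] + 1, atm_gtc = atm_gtc, t_surf = t_surf,
                t_deep = t_deep, conc = conc, h = h,
                temperature = t_cached, v = v, s = s,
                weathering_mol_yr = weathering, config = cfg)
  class(final) <- "world_state"
  list(ledger = ledger, snapshots = snapshots, final = final)
}

#' @export
print.run_ledger <- function(x, ...) {
  cat(sprintf("<run_ledger: %d-%d, mode %s, scenario %s>\n",
              min(x$year), max(x$year),
              attr(x, "mode") %||% "?", attr(x, "label") %||% "?"))
  print.data.frame(utils::tail(as.data.frame(x)[
    , c("year", "emissions", "j_cdr", "j_sea_air", "j_lnd_air", "co2_ppm",
        "t_anom", "surf_omega_arg")], 5), digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
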