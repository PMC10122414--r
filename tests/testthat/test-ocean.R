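make_test_ocean <- function(dic = rep(2.15, 4), alk = rep(2.42, 4),
                            po4 = rep(2.2e-3, 4)) {
  ocean_state(dic, alk, po4)
}

test_that("transport conserves tracers and leaves homogeneous fields alone", {
  circ <- circulation_config()
  oc <- make_test_ocean()
  g <- oc$geometry
  stepped <- transport_step(oc, circ, 0.1)
  # uniform concentration: unchanged
  expect_equal(stepped$conc, oc$conc, tolerance = 1e-13)
  # gradient: total inventory conserved to roundoff
  oc2 <- make_test_ocean(dic = c(2.0, 2.1, 2.2, 2.3))
  stepped2 <- transport_step(oc2, circ, 0.1)
  expect_equal(sum(stepped2$conc[, "dic"] * g$volume),
               sum(oc2$conc[, "dic"] * g$volume), tolerance = 1e-12)
  # above the stability bound: error reporting the bound
  bound <- transport_stability_dt(circ, g)
  expect_error(transport_step(oc2, circ, bound * 1.01), "stability bound")
})

test_that("two-box exchange follows the analytic exponential", {
  # restrict exchange to surf_low <-> intermediate only
  circ <- circulation_config(overturning_sv = 0, mix_low_int_sv = 30,
                             mix_int_deep_sv = 0, mix_high_deep_sv = 0)
  oc <- make_test_ocean(dic = c(2.4, 2.0, 2.0, 2.0))
  g <- oc$geometry
  q <- 30 * erw_constants$sv_m3yr
  rate <- q * (1 / g$volume[1] + 1 / g$volume[3])
  dt <- 0.02
  n <- 500
  for (i in seq_len(n)) oc <- transport_step(oc, circ, dt)
  # difference decays as exp(-rate t) (Euler-discretized rate)
  d0 <- 2.4 - 2.0
  rate_discrete <- -log(1 - dt * rate) / dt
  expect_equal(unname(oc$conc[1, "dic"] - oc$conc[3, "dic"]),
               d0 * exp(-rate_discrete * n * dt), tolerance = 1e-6)
  # untouched boxes unchanged
  expect_equal(unname(oc$conc[c(2, 4), "dic"]), c(2.0, 2.0))
})

test_that("gas exchange is zero at equilibrium and linear in disequilibrium", {
  k0 <- co2_constants(15, 35)$k0
  area <- 3.08e14
  expect_identical(gas_exchange(350, 350, k0, area), 0)
  f1 <- gas_exchange(400, 350, k0, area)
  f2 <- gas_exchange(450, 350, k0, area)
  expect_gt(f1, 0)  # supersaturated ocean outgasses
  expect_equal(f2, 2 * f1)
  expect_error(gas_exchange(400, 350, k0, area, piston_velocity = -1))
})

test_that("a DIC-perturbed surface box relaxes monotonically to equilibrium", {
  # single box against a fixed atmosphere, no transport/bio
  g <- box_geometry()
  rho <- erw_constants$rho_sw
  k <- lapply(co2_constants(g$t_ref[1], g$salinity, 0), `[`, 1)
  dic <- (2002e-6 + 100e-6) * rho   # +100 umol/kg perturbation
  alk <- 2310e-6 * rho
  atm <- 280
  dt <- 0.05
  h <- 10^-8.05
  pco2_prev <- Inf
  pco2_path <- numeric(400)
  for (i in seq_len(400)) {
    h <- erwcycle:::solve_h_fast(dic / rho, alk / rho, k, h)
    sp <- erwcycle:::speciate_at_h(dic / rho, h, k)
    pco2_path[i] <- sp$pco2
    flux <- gas_exchange(sp$pco2, atm, k$k0, g$area[1])
    dic <- dic - dt * flux / g$volume[1]
  }
  expect_true(all(diff(pco2_path) < 0))          # monotone relaxation
  expect_gt(pco2_path[400], atm)                  # from above
  # linearized e-folding: within a factor ~2 of the observed decay
  decay_obs <- log((pco2_path[1] - atm) / (pco2_path[400] - atm)) / (399 * dt)
  expect_gt(decay_obs, 0.1); expect_lt(decay_obs, 2)
})

test_that("biological pump conserves totals and builds a DIC gradient", {
  bio <- bio_config()
  g <- box_geometry()
  oc <- make_test_ocean()
  # rain ratio 0: alkalinity untouched by the pump
  oc_nr <- biological_pump_step(oc, bio_config(rain_ratio = 0), 0.1)
  expect_equal(oc_nr$conc[, "alk"], oc$conc[, "alk"])
  # zero surface nutrient: zero export
  oc0 <- make_test_ocean(po4 = c(0, 0, 2e-3, 2e-3))
  oc0s <- biological_pump_step(oc0, bio, 0.1)
  expect_identical(attr(oc0s, "corg_export"), 0)
  # conservation of C, ALK, P
  ocs <- biological_pump_step(oc, bio, 0.1)
  for (tr in c("dic", "alk", "po4"))
    expect_equal(sum(ocs$conc[, tr] * g$volume),
                 sum(oc$conc[, tr] * g$volume), tolerance = 1e-12)
  # pump + circulation at steady state: surface DIC below deep DIC
  w <- test_world()
  expect_lt(w$conc[1, "dic"], w$conc[4, "dic"])
  expect_lt(w$conc[2, "dic"], w$conc[4, "dic"])
})

test_that("burial responds to deep saturation and vanishes below it", {
  sed <- sediment_config(b0 = 4e13, n_exp = 1)
  # undersaturated deep box: zero burial
  oc_lo <- make_test_ocean(dic = rep(2.35, 4), alk = rep(2.36, 4))
  r_lo <- burial_step(oc_lo, sed, 0.1)
  expect_identical(r_lo$burial_flux, 0)
  expect_equal(r_lo$ocean$conc, oc_lo$conc)
  # supersaturated: positive burial removing 1 DIC + 2 ALK per mol
  oc_hi <- make_test_ocean(dic = rep(2.05, 4), alk = rep(2.45, 4))
  r_hi <- burial_step(oc_hi, sed, 0.1)
  expect_gt(r_hi$burial_flux, 0)
  g <- oc_hi$geometry
  d_dic <- (oc_hi$conc[4, "dic"] - r_hi$ocean$conc[4, "dic"]) * g$volume[4]
  d_alk <- (oc_hi$conc[4, "alk"] - r_hi$ocean$conc[4, "alk"]) * g$volume[4]
  expect_equal(unname(d_alk), unname(2 * d_dic), tolerance = 1e-12)
})

test_that("spun-up state balances weathering, burial and gas exchange", {
  w <- test_world()
  g <- w$config$geometry
  rho <- erw_constants$rho_sw
  st <- solve_speciation(w$conc[, "dic"] / rho, w$conc[, "alk"] / rho,
                         g$t_ref, g$salinity, g$pressure)
  # burial at the restart state equals the imposed weathering closely
  bur <- erwcycle:::burial_rate(st$omega_cal[4], w$config$sediment)
  expect_lt(abs(bur - w$weathering_mol_yr) / w$weathering_mol_yr, 1e-3)
  # area-weighted surface pCO2 within 5 uatm of the atmosphere
  aw <- g$area[1:2] / sum(g$area[1:2])
  expect_lt(abs(sum(aw * st$pco2[1:2]) - erw_constants$co2_ppm_pi), 5)
})

test_that("unforced restart holds atmospheric CO2 constant for centuries", {
  w <- test_world()
  sp <- slab_params()
  pi_pw <- synthesize_pathway(data.frame(year = c(1765, 2300),
                                         value = c(278, 278)), label = "pi")
  em <- diagnose_emissions(pi_pw, w, sp, years = 1765:2299)
  expect_lt(max(abs(em$emission)), 0.05)   # steady state: no implied source
  fwd <- integrate_world(w, 1765:2299, mode = "emission", pathway = pi_pw,
                         emissions = em, slab_par = sp)
  expect_lt(max(abs(fwd$ledger$co2_ppm - 278)), 1)   # < 1 ppm over 535 y
})

test_that("two-layer climate reproduces its limiting behaviour", {
  cp <- climate_params()
  # zero forcing at the preindustrial reference
  expect_equal(radiative_forcing(erw_constants$co2_ppm_pi), 0)
  # constant 2xCO2 forcing converges to the equilibrium sensitivity
  st <- list(t_surf = 0, t_deep = 0)
  for (i in seq_len(60000)) st <- climate_step(st, cp$f2x, 0.1, cp)
  expect_equal(st$t_surf, cp$f2x / cp$lambda, tolerance = 1e-3)
  expect_equal(st$t_land, cp$land_amplification * st$t_surf)
  # linear ramp: response matches the two-layer convolution integral
  dt <- 0.01
  n <- 5000
  st <- list(t_surf = 0, t_deep = 0)
  for (i in seq_len(n)) st <- climate_step(st, 0.05 * i * dt, dt, cp)
  two_layer_analytic <- function(t_end, slope) {
    # x(t) = V diag((exp(l t) - 1 - l t) / l^2) V^-1 f' for a ramp with
    # d(forcing)/dt = slope, from the eigen-decomposition of the 2x2 system
    a <- matrix(c(-(cp$lambda + cp$gamma) / cp$c_ml, cp$gamma / cp$c_ml,
                  cp$gamma / cp$c_deep, -cp$gamma / cp$c_deep), 2, 2,
                byrow = TRUE)
    ev <- eigen(a)
    b <- solve(ev$vectors, c(slope / cp$c_ml, 0))
    x <- ev$vectors %*% ((exp(ev$values * t_end) - 1 - ev$values * t_end) /
                           ev$values^2 * b)
    x[1]
  }
  expect_equal(st$t_surf, two_layer_analytic(n * dt, 0.05),
               tolerance = 5e-3)
  # response lags the equilibrium implied by instantaneous forcing
  expect_lt(st$t_surf, 0.05 * n * dt / cp$lambda)
})
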