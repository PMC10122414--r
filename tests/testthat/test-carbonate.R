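test_that("speciation matches the independent bisection oracle", {
  # frozen from the oracle: DIC 2050, ALK 2350 umol/kg, 15 degC, S 35
  s <- solve_speciation(2050e-6, 2350e-6, temperature = 15, salinity = 35)
  expect_equal(s$pco2, 273.81, tolerance = 1e-3)
  o <- oracle_speciate(2050e-6, 2350e-6, 15, 35)
  expect_lt(abs(s$pco2 - o$pco2) / o$pco2, 1e-3)
  expect_lt(abs(s$ph - o$ph), 1e-6)

  # grid of states spanning surface-to-deep conditions
  grid <- expand.grid(dic = seq(1800e-6, 2400e-6, length.out = 5),
                      alk = seq(2100e-6, 2500e-6, length.out = 5),
                      t = c(2, 15, 28), s = c(33, 35), p = c(0, 250))
  grid <- grid[grid$alk - grid$dic > -100e-6, ]
  sol <- solve_speciation(grid$dic, grid$alk, grid$t, grid$s, grid$p)
  for (i in seq_len(nrow(grid))) {
    o <- oracle_speciate(grid$dic[i], grid$alk[i], grid$t[i], grid$s[i],
                         grid$p[i])
    expect_lt(abs(sol$pco2[i] - o$pco2) / o$pco2, 1e-3)
  }
})

test_that("zero-carbon limit gives no carbon species", {
  s <- solve_speciation(0, 2350e-6)
  expect_identical(s$pco2, 0)
  expect_identical(s$co3, 0)
  expect_gt(s$ph, 7)  # alkaline borate/water solution
})

test_that("DIC mass balance and alkalinity round-trip close at solution", {
  s <- solve_speciation(c(1900e-6, 2100e-6, 2300e-6), 2350e-6,
                        temperature = c(4, 16, 28))
  expect_equal(s$co2aq + s$hco3 + s$co3, s$dic, tolerance = 1e-10)
  k <- co2_constants(s$temperature, s$salinity, s$pressure)
  alk_back <- s$hco3 + 2 * s$co3 +
    k$boron_total * k$kb / (k$kb + s$h) + k$kw / s$h - s$h
  expect_equal(alk_back, s$alk, tolerance = 1e-8)
})

test_that("pCO2 responds with the carbonate-system signs", {
  alk <- 2350e-6
  dics <- seq(1900e-6, 2250e-6, length.out = 12)
  p_dic <- solve_speciation(dics, alk)$pco2
  expect_true(all(diff(p_dic) > 0))      # dpCO2/dDIC > 0 at fixed ALK
  alks <- seq(2250e-6, 2500e-6, length.out = 12)
  p_alk <- solve_speciation(2100e-6, alks)$pco2
  expect_true(all(diff(p_alk) < 0))      # dpCO2/dALK < 0 at fixed DIC
  # carbonate-dissolution stoichiometry (2 ALK + 1 DIC) lowers pCO2
  base <- solve_speciation(2100e-6, 2350e-6)$pco2
  dis <- solve_speciation(2100e-6 + 50e-6, 2350e-6 + 100e-6)$pco2
  expect_lt(dis, base)
})

test_that("solver reports non-convergence outside the physical range", {
  expect_error(solve_speciation(2100e-6, -0.02), "no pH root")
  expect_error(solve_speciation(-1e-6, 2300e-6), "dic")
  expect_error(solve_speciation(2100e-6, 2300e-6, temperature = 80),
               "temperature")
})

test_that("saturation state follows its definition", {
  expect_identical(saturation_state(0), 0)
  # omega = 1 exactly when the ion product equals Ksp
  k <- co2_constants(25, 35, 0)
  co3_crit <- k$ksp_arg / 0.01028
  expect_equal(saturation_state(co3_crit, calcium = 0.01028,
                                temperature = 25, salinity = 35), 1)
  # derived check against an independently coded Ksp
  om <- saturation_state(200e-6, calcium = 10.28e-3, temperature = 25,
                         salinity = 35, mineral = "aragonite")
  om_oracle <- 10.28e-3 * 200e-6 / oracle_ksp_arg_surface(25, 35)
  expect_lt(abs(om - om_oracle) / om_oracle, 5e-3)
  expect_error(saturation_state(200e-6, mineral = "dolomite"))
})

test_that("omega_cal / omega_arg equals Ksp_arg / Ksp_cal exactly", {
  s <- solve_speciation(c(2000e-6, 2300e-6), 2350e-6,
                        temperature = c(2, 25), pressure = c(250, 0))
  k <- co2_constants(s$temperature, s$salinity, s$pressure)
  expect_equal(s$omega_cal / s$omega_arg, k$ksp_arg / k$ksp_cal,
               tolerance = 1e-12)
})

test_that("alternative constant formulation is selectable and consistent", {
  a <- solve_speciation(2050e-6, 2350e-6, formulation = "lueker00")
  b <- solve_speciation(2050e-6, 2350e-6, formulation = "roy93")
  expect_false(isTRUE(all.equal(a$pco2, b$pco2)))
  expect_lt(abs(a$pco2 - b$pco2) / a$pco2, 0.10)  # same physics, small shift
})
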