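test_that("slab flux laws evaluate to their closed forms", {
  p <- slab_params(n0 = 50, b = 0.6, lambda_veg = 0.002, lambda_0 = 10,
                   gamma = 0.03, q10 = 2)
  # NPP: reference point, doubling, and b = 0
  expect_equal(npp(p$c0, p), 50)
  expect_equal(npp(2 * p$c0, p), 50 * (1 + 0.6 * log(2)))
  expect_equal(npp(600, slab_params(n0 = 50, b = 0)), 50)
  expect_error(npp(-10, p))
  # litterfall: limits and turnover diagnostic
  expect_identical(litterfall(0, p), 0)
  p_fix <- slab_params(lambda_veg = 0, lambda_0 = 10)
  expect_equal(litterfall(400, p_fix), 40)
  expect_equal(vegetation_turnover(500, p), 0.002 * 500 + 10)
  # respiration: reference temperature and +10 degC
  expect_equal(soil_respiration(1500, p$t0, p), 0.03 * 1500)
  p_r <- slab_params(gamma = 0.03, q10 = 2)
  expect_equal(soil_respiration(1500, p_r$t0 + 10, p_r), 90)
})

test_that("closed-form steady states are recovered by integration", {
  p <- slab_params(n0 = 50, b = 0.6, lambda_veg = 0.002, lambda_0 = 10,
                   gamma = 0.033)
  ss <- slab_steady_state(p)
  expect_equal(ss$v_star, 50 * 10 / (1 - 50 * 0.002))  # 500 / 0.9
  expect_equal(ss$s_star, 50 / 0.033)
  # long integration from arbitrary positive initial conditions
  st <- list(v = 120, s = 3000)
  for (i in seq_len(40000))
    st <- slab_step(st, p$c0, p$t0, p, 0.1)[c("v", "s")]
  expect_equal(st$v, ss$v_star, tolerance = 1e-6)
  expect_equal(st$s, ss$s_star, tolerance = 1e-6)
})

test_that("land carbon is conserved against the returned land-air flux", {
  p <- slab_params()
  st <- list(v = 400, s = 1200)
  cum_flux_gtc <- 0
  dt <- 0.1
  for (i in seq_len(500)) {
    out <- slab_step(st, 450, p$t0 + 1.2, p, dt)
    cum_flux_gtc <- cum_flux_gtc + out$j_lnd_air / erw_constants$gtco2_per_gtc * dt
    st <- out[c("v", "s")]
  }
  expect_equal((st$v + st$s) - (400 + 1200), -cum_flux_gtc,
               tolerance = 1e-10)
})

test_that("step responses have the expected initial signs", {
  p <- slab_params()
  ss <- slab_steady_state(p)
  st0 <- list(v = ss$v_star, s = ss$s_star)
  # at the reference state the net land-air flux vanishes
  out0 <- slab_step(st0, p$c0, p$t0, p, 0.05)
  expect_equal(out0$j_lnd_air, 0, tolerance = 1e-8)
  # CO2 step up at fixed T: immediate land uptake (negative flux)
  expect_lt(slab_step(st0, 1.3 * p$c0, p$t0, p, 0.05)$j_lnd_air, 0)
  # warming at fixed CO2: immediate soil release (positive flux)
  expect_gt(slab_step(st0, p$c0, p$t0 + 2, p, 0.05)$j_lnd_air, 0)
})

test_that("parameter validation enforces the admissible region", {
  expect_error(slab_params(n0 = -5), "must be > 0")
  expect_error(slab_params(n0 = 200, lambda_veg = 0.01), "positive vegetation")
  expect_error(slab_params(lambda_veg = -0.1), "lambda_veg")
})
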