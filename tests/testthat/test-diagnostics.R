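toy_pair <- function(frac_sea = 0.2, frac_lnd = 0.1, rate = 10,
                     years = 2030:2100) {
  ctrl <- data.frame(year = years, j_cdr = 0, j_sea_air = 2, j_lnd_air = 1)
  exper <- data.frame(year = years, j_cdr = rate,
                      j_sea_air = 2 + frac_sea * rate,
                      j_lnd_air = 1 + frac_lnd * rate)
  attr(exper, "intervention") <- intervention("baseline", rate = rate,
                                              start_year = min(years))
  list(exp = exper, ctrl = ctrl)
}

test_that("eta and p recover closed-form values on proportional ledgers", {
  # no excess outgassing: eta = 1, p = 0
  tp0 <- toy_pair(0, 0)
  expect_equal(eta(tp0$exp, tp0$ctrl, 2100), 1)
  expect_equal(backflux(tp0$exp, tp0$ctrl, 2100), 0)
  # excess outgassing equal to deployment: eta = 0, p = 100
  tp1 <- toy_pair(0.7, 0.3)
  expect_equal(eta(tp1$exp, tp1$ctrl, 2100), 0)
  expect_equal(backflux(tp1$exp, tp1$ctrl, 2100), 100)
  # proportional backflux 0.3: eta = 0.7 (fixture value)
  fx <- make_fixtures(1)
  expect_equal(eta(fx$toy$exp, fx$toy$ctrl, 2100), fx$toy$eta)
  # Eq-identity p = (1 - eta) * 100 holds along the whole series
  bs <- backflux_series(tp1$exp, tp1$ctrl)
  expect_equal(bs$p, (1 - bs$eta) * 100, tolerance = 1e-14)
})

test_that("eta guards its preconditions", {
  tp <- toy_pair()
  short <- tp$ctrl[tp$ctrl$year <= 2050, ]
  expect_error(eta(tp$exp, short, 2100), "interval")
  zero <- tp$exp; zero$j_cdr <- 0
  expect_warning(out <- eta(zero, tp$ctrl, 2100), "undefined")
  expect_true(is.na(out))
})

test_that("p_leak is the ERW excess over baseline and zero at identity", {
  tp_base <- toy_pair(0.2, 0.1)
  tp_erw <- toy_pair(0.28, 0.1)
  expect_equal(p_leak(tp_erw$exp, tp_base$exp, tp_base$ctrl, 2100), 8)
  # identical ledgers: zero leakage
  expect_equal(p_leak(tp_base$exp, tp_base$exp, tp_base$ctrl, 2100), 0)
  # mismatched rate/start is an error
  other <- toy_pair(rate = 5)
  expect_error(p_leak(tp_erw$exp, other$exp, tp_base$ctrl, 2100),
               "share rate")
  # storage efficiency complements leakage
  tp_base$exp$ocean_dic_gtc <- 1000
  tp_erw$exp$ocean_dic_gtc <- 1400
  se <- storage_efficiency(tp_erw$exp, tp_base$exp, tp_base$ctrl, 2100)
  expect_equal(se$efficiency, 92)
  expect_equal(se$excess_ocean_dic_gtc, 400)
})

test_that("omega co-benefit compares runs at one year", {
  led <- function(om) data.frame(year = 2060:2080, surf_omega_arg = om)
  out <- omega_cobenefit(led(3.6), led(3.15), led(3.0), 2070)
  expect_equal(out$pct_change_erw, 20)
  expect_equal(out$pct_change_base, 5)
  expect_equal(out$ratio, 4)
  # identical runs: zero change
  same <- omega_cobenefit(led(3.0), led(3.0), led(3.0), 2070)
  expect_equal(same$pct_change_erw, 0)
})

test_that("rate independence holds exactly for linear-response ledgers", {
  mk <- function(rate) toy_pair(0.2, 0.1, rate = rate)
  exps <- lapply(c(r0.5 = 0.5, r5 = 5, r40 = 40), function(r) mk(r))
  audit <- rate_independence_audit(exps, 2100)
  expect_equal(unname(audit$spread), 0, tolerance = 1e-10)
  expect_true(audit$within_band)
  single <- rate_independence_audit(exps[1], 2100)
  expect_equal(single$spread, 0)
})

test_that("ensemble summaries are order-invariant with central intervals", {
  v <- c(5, 9, 7, 8, 6, 10, 11, 4, 7.5, 8.5)
  a <- ensemble_summary(v)
  b <- ensemble_summary(rev(v))
  expect_equal(a$median, b$median)
  expect_equal(a$lo, b$lo)
  expect_true(a$lo <= a$median && a$median <= a$hi)
})
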