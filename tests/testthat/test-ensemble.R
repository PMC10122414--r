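test_that("prior sampling is reproducible, in-range, and well-centred", {
  pr <- parameter_prior()
  # degenerate range collapses to the single point
  pr1 <- pr; pr1$min <- pr1$max <- c(50, 0.5, 0.002, 10, 0.03, 2)
  one <- sample_priors(pr1, 1, seed = 7)
  expect_equal(one$n0, 50); expect_equal(one$q10, 2)
  # same seed twice: identical draws
  a <- sample_priors(pr, 100, seed = 11)
  b <- sample_priors(pr, 100, seed = 11)
  expect_identical(a, b)
  # 1e4 uniform draws: inside range, mean within 3 SE of midpoint
  big <- sample_priors(pr, 10000, seed = 13)
  for (i in seq_len(nrow(pr))) {
    x <- big[[pr$param[i]]]
    expect_true(all(x >= pr$min[i] & x <= pr$max[i]))
    se <- (pr$max[i] - pr$min[i]) / sqrt(12) / sqrt(10000)
    expect_lt(abs(mean(x) - (pr$min[i] + pr$max[i]) / 2), 3.5 * se)
  }
  # every draw satisfies the slab invariants
  expect_silent(erwcycle:::slab_params_from_df(big))
  expect_error(sample_priors(data.frame(param = "n0", min = 5, max = 2,
                                        dist = "uniform"), 10, 1))
})

test_that("static filter verdicts follow the windows", {
  crit <- filter_criteria()
  forcing <- offline_forcing(builtin_pathway("mid"))
  # a hand-built member near the window centres passes
  good <- data.frame(member = 1L, n0 = 45, b = 0.3, lambda_veg = 0.002,
                     lambda_0 = 12, gamma = 0.033, q10 = 1.6,
                     c0 = 278, t0 = 8)
  v <- filter_static(good, forcing, crit)
  expect_true(v$pass)
  expect_true(v$pass_soil && v$pass_npp && v$pass_turnover)
  # gamma driving the soil stock to ~10x the window fails on soil only
  bad <- good; bad$gamma <- 0.0023
  vb <- filter_static(bad, forcing, crit)
  expect_false(vb$pass)
  expect_false(vb$pass_soil)
  expect_true(vb$pass_npp)
  # acceptance fraction over a broad prior is strictly between 0 and 1
  draws <- sample_priors(parameter_prior(), 4000, seed = 3)
  vs <- filter_static(draws, forcing, crit, dt = 0.25)
  frac <- mean(vs$pass)
  expect_gt(frac, 0); expect_lt(frac, 1)
})

test_that("dynamic filtering is monotone in the envelope width", {
  forcing <- offline_forcing(builtin_pathway("high"))
  draws <- sample_priors(parameter_prior(), 400, seed = 5)
  wide <- filter_criteria(delta_v = c(-1e6, 1e6), delta_s = c(-1e6, 1e6))
  mid <- filter_criteria(delta_v = c(-60, 240), delta_s = c(-150, 120))
  tight <- filter_criteria(delta_v = c(-10, 40), delta_s = c(-20, 20))
  v_wide <- filter_dynamic(draws, forcing, wide, dt = 0.25)
  v_mid <- filter_dynamic(draws, forcing, mid, dt = 0.25)
  v_tight <- filter_dynamic(draws, forcing, tight, dt = 0.25)
  # unbounded envelopes pass everything
  expect_true(all(v_wide$pass))
  # tightening shrinks the accepted set (subset property)
  expect_true(all(which(v_tight$pass) %in% which(v_mid$pass)))
  expect_true(all(which(v_mid$pass) %in% which(v_wide$pass)))
  # filtering is a pure function: identical verdicts on re-evaluation
  expect_identical(v_mid, filter_dynamic(draws, forcing, mid, dt = 0.25))
  expect_error(filter_criteria(soil = c(2000, 1200)), "lower < upper")
})

test_that("two-stage ensemble construction is seeded and audited", {
  # offline-only pipeline at reduced size
  ens <- build_ensemble(n_initial = 20000, seed = 21, world = NULL)
  expect_gt(ens$counts$n_offline, 0)
  expect_lt(ens$counts$n_offline, 20000)
  frac <- ens$counts$n_offline / ens$counts$n_initial
  # acceptance fraction of order 1e-3 to 1e-2 over the broad prior
  expect_gt(frac, 1e-4); expect_lt(frac, 5e-2)
  # reproducibility: same seed gives identical membership
  ens2 <- build_ensemble(n_initial = 20000, seed = 21, world = NULL)
  expect_identical(ens$members, ens2$members)
  # rejection histogram accounts for every rejected member
  expect_identical(ens$rejections$dynamic + ens$counts$n_offline,
                   ens$counts$n_static)
  # impossible windows fail loudly with the rejection tally
  crit0 <- filter_criteria(soil = c(1, 2))
  expect_error(build_ensemble(criteria = crit0, n_initial = 2000, seed = 1,
                              world = NULL), "rejections")
})

test_that("coupled-stage filtering retains members and their controls", {
  w <- test_world()
  ens <- build_ensemble(n_initial = 30000, n_coupled = 2, seed = 31,
                        world = w, pathway = builtin_pathway("mid"),
                        years = 1765:2100)
  expect_gte(ens$counts$n_final, 1)
  expect_identical(length(ens$controls), nrow(ens$members))
  led <- ens$controls[[1]]$ledger
  expect_s3_class(led, "run_ledger")
  expect_true(all(c("veg", "soil", "j_sea_air") %in% names(led)))
})
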