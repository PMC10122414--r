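# Shared, lazily built objects reused across test files.  The spun-up world
# is deterministic, so one instance serves every test.
.cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.cache$world)) .cache$world <- spinup()
  .cache$world
}

# A small set of observationally filtered slab members (fixed seed).
test_members <- function(n = 6) {
  if (is.null(.cache$members)) {
    draws <- sample_priors(parameter_prior(), 60000, seed = 2024)
    fmid <- offline_forcing(builtin_pathway("mid"))
    fhigh <- offline_forcing(builtin_pathway("high"))
    st <- filter_static(draws, fmid, dt = 0.25)
    dyn <- filter_dynamic(draws[st$pass, , drop = FALSE],
                          list(fmid, fhigh), dt = 0.25)
    .cache$members <- draws[st$pass, , drop = FALSE][dyn$pass, , drop = FALSE]
  }
  utils::head(.cache$members, n)
}

# Control + branch runs for one scenario/member, reused by diagnostics tests.
run_branch_set <- function(world, scenario, slab_par, ivs,
                           years = 1765:2100) {
  ctrl <- run_control(world, builtin_pathway(scenario), slab_par,
                      years = years)
  out <- list(ctrl = run_experiment(ctrl, NULL, slab_par))
  for (nm in names(ivs))
    out[[nm]] <- run_experiment(ctrl, ivs[[nm]], slab_par)
  out$control <- ctrl
  out
}
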