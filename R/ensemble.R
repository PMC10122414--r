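#' Default sampling prior for the slab-biosphere parameters
#'
#' Per-parameter (min, max) ranges and distribution tags used for the
#' stochastic ensemble.  The ranges span the literature uncertainty on each
#' quantity generously — the observational filters, not the prior edges, are
#' meant to carry the constraint: global NPP well outside the observed
#' 45-65 GtC/y, soil stocks outside 1200-2000 GtC, or vegetation turnover
#' outside 8-25 y are rejected downstream.  The product `n0 * lambda_veg`
#' stays below 1 over the whole box, so every draw admits a positive
#' vegetation steady state.
#'
#' @return A `parameter_prior` data.frame: `param`, `min`, `max`, `dist`.
#' @export
parameter_prior <- function() {
  p <- data.frame(
    param = c("n0", "b", "lambda_veg", "lambda_0", "gamma", "q10"),
    min   = c(20,  0.1, 0,      2,  0.01, 1.2),
    max   = c(100, 1.2, 0.009, 40,  0.10, 4.0),
    dist  = c("uniform", "uniform", "uniform", "uniform", "uniform",
              "uniform"),
    stringsAsFactors = FALSE)
  class(p) <- c("parameter_prior", "data.frame")
  p
}

validate_prior <- function(prior) {
  if (any(prior$min > prior$max))
    stop("prior ranges must have min < max")
  pos <- prior$param %in% c("n0", "lambda_0", "gamma", "q10")
  if (any(prior$min[pos] <= 0))
    stop("positive-constrained parameters need strictly positive ranges")
  if (any(prior$dist == "loguniform" & prior$min <= 0))
    stop("log-uniform ranges must be strictly positive")
  invisible(prior)
}

#' Draw slab parameter sets from a prior
#'
#' Reproducible (seeded) sampling; each draw lies inside its range.
#'
#' @param prior A `parameter_prior`.
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed, recorded on the result.
#' @param c0,t0 Reference pCO2 (ppm) and land temperature (degC) attached
#'   to every member.
#' @return data.frame with one row per member, columns `member`, the six
#'   parameters, `c0`, `t0`; attribute `seed`.
#' @export
sample_priors <- function(prior = parameter_prior(), n, seed,
                          c0 = erw_constants$co2_ppm_pi, t0 = 8.0) {
  if (n < 1) stop("n must be >= 1")
  validate_prior(prior)
  set.seed(seed)
  draws <- lapply(seq_len(nrow(prior)), function(i) {
    r <- prior[i, ]
    if (r$dist == "loguniform")
      exp(stats::runif(n, log(r$min), log(r$max)))
    else
      stats::runif(n, r$min, r$max)
  })
  names(draws) <- prior$param
  out <- data.frame(member = seq_len(n), draws, c0 = c0, t0 = t0)
  attr(out, "seed") <- seed
  out
}

# Member data.frame -> vectorized slab_params
slab_params_from_df <- function(df) {
  p <- list(n0 = df$n0, b = df$b, lambda_veg = df$lambda_veg,
            lambda_0 = df$lambda_0, gamma = df$gamma, q10 = df$q10,
            c0 = df$c0, t0 = df$t0)
  validate_slab_params(p)
  class(p) <- "slab_params"
  p
}

#' Default observational filter criteria
#'
#' Acceptance windows for the stand-alone slab runs: modern (year
#' `modern_year`) soil carbon stock, NPP, and vegetation turnover time, and
#' envelopes for the dynamic response — the change in vegetation and soil
#' carbon over `century` — chosen to bracket the spread of CMIP5-class
#' projections.  All windows are configurable; the defaults are recorded in
#' every ensemble manifest.
#'
#' @param soil,npp,turnover Modern windows: GtC, GtC/y, years.
#' @param delta_v,delta_s Century-change envelopes, GtC.
#' @param modern_year Year at which the modern windows apply.
#' @param century `c(from, to)` for the dynamic-response envelopes.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(soil = c(1200, 2000), npp = c(45, 65),
                            turnover = c(8, 25),
                            delta_v = c(-60, 240), delta_s = c(-150, 120),
                            modern_year = 2015, century = c(2015, 2100)) {
  cr <- list(soil = soil, npp = npp, turnover = turnover,
             delta_v = delta_v, delta_s = delta_s,
             modern_year = modern_year, century = century)
  for (w in cr[c("soil", "npp", "turnover", "delta_v", "delta_s")])
    if (w[1] >= w[2]) stop("filter windows must have lower < upper")
  class(cr) <- "filter_criteria"
  cr
}

#' Offline forcing for stand-alone slab runs
#'
#' Annual atmospheric pCO2 and land temperature along a concentration
#' pathway, with temperature from the two-layer energy balance model under
#' prescribed concentrations (no carbon-cycle feedback) and land
#' amplification applied.
#'
#' @param pathway A `concentration_pathway`.
#' @param t0_land Reference land temperature added to the anomaly, degC.
#' @param params Climate parameters.
#' @return data.frame `year`, `co2`, `t_land`.
#' @export
offline_forcing <- function(pathway, t0_land = 8.0,
                            params = climate_params()) {
  cs <- climate_series(pathway, params = params)
  data.frame(year = pathway$year, co2 = pathway$co2,
             t_land = t0_land + cs$t_land)
}

#' Static observational filter for slab parameter sets
#'
#' Integrates the stand-alone slab model for every member under historical
#' forcing and tests the modern soil stock, NPP, and vegetation turnover
#' against the acceptance windows.
#'
#' @param members Parameter data.frame from [sample_priors()].
#' @param forcing Offline forcing from [offline_forcing()] covering
#'   `criteria$modern_year`.
#' @param criteria A `filter_criteria`.
#' @param dt Slab integration step, years.
#' @return data.frame: `member`, `pass`, per-criterion verdicts, and the
#'   modern diagnostics `soil_modern`, `npp_modern`, `turnover_modern`.
#' @export
filter_static <- function(members, forcing, criteria = filter_criteria(),
                          dt = 0.1) {
  my <- criteria$modern_year
  if (!my %in% forcing$year) stop("forcing must cover the modern year")
  par <- slab_params_from_df(members)
  run <- slab_run(par, forcing$year, forcing$co2, forcing$t_land, dt = dt,
                  out_years = my)
  s_mod <- run$s[1, ]; n_mod <- run$n[1, ]; tau_mod <- run$turnover[1, ]
  ok_s <- s_mod >= criteria$soil[1] & s_mod <= criteria$soil[2]
  ok_n <- n_mod >= criteria$npp[1] & n_mod <= criteria$npp[2]
  ok_t <- tau_mod >= criteria$turnover[1] & tau_mod <= criteria$turnover[2]
  data.frame(member = members$member, pass = ok_s & ok_n & ok_t,
             pass_soil = ok_s, pass_npp = ok_n, pass_turnover = ok_t,
             soil_modern = s_mod, npp_modern = n_mod,
             turnover_modern = tau_mod)
}

#' Dynamic-response filter for slab parameter sets
#'
#' Integrates each member along one or more scenario forcings and requires
#' the century changes in vegetation and soil carbon to fall inside the
#' configured envelopes for every scenario.
#'
#' @param members Parameter data.frame.
#' @param scenario_forcings A single offline forcing data.frame or a list
#'   of them.
#' @param criteria A `filter_criteria`.
#' @param dt Slab integration step, years.
#' @return data.frame `member`, `pass`, and per-scenario `delta_v`,
#'   `delta_s`.
#' @export
filter_dynamic <- function(members, scenario_forcings,
                           criteria = filter_criteria(), dt = 0.1) {
  if (is.data.frame(scenario_forcings))
    scenario_forcings <- list(scenario_forcings)
  par <- slab_params_from_df(members)
  out <- data.frame(member = members$member,
                    pass = rep(TRUE, nrow(members)))
  for (i in seq_along(scenario_forcings)) {
    f <- scenario_forcings[[i]]
    yrs <- criteria$century
    run <- slab_run(par, f$year, f$co2, f$t_land, dt = dt, out_years = yrs)
    dv <- run$v[2, ] - run$v[1, ]
    ds <- run$s[2, ] - run$s[1, ]
    ok <- dv >= criteria$delta_v[1] & dv <= criteria$delta_v[2] &
      ds >= criteria$delta_s[1] & ds <= criteria$delta_s[2]
    out$pass <- out$pass & ok
    out[[paste0("delta_v_", i)]] <- dv
    out[[paste0("delta_s_", i)]] <- ds
  }
  out
}

#' Build the filtered slab-biosphere ensemble
#'
#' Two-stage pipeline mirroring the ensemble construction logic:
#' stage 1 draws `n_initial` parameter sets from the prior and filters them
#' offline (static modern windows + dynamic century envelopes under the
#' supplied scenario forcings); stage 2 takes the first `n_coupled`
#' survivors, runs each fully coupled to the box model along `pathway`, and
#' re-applies the modern windows and century envelopes to the coupled run.
#' All counts, seeds and per-criterion rejection tallies are recorded.
#'
#' @param prior A `parameter_prior`.
#' @param criteria A `filter_criteria`.
#' @param n_initial Stage-1 sample size.
#' @param n_coupled Number of offline survivors promoted to coupled runs
#'   (capped at the survivor count).
#' @param seed Integer seed.
#' @param world Spun-up `world_state` (required for the coupled stage;
#'   `NULL` skips stage 2 and returns the offline ensemble).
#' @param pathway Scenario pathway for the coupled filtering runs.
#' @param offline_scenarios Pathways for the offline dynamic filter
#'   (default: the mid and high built-in scenarios).
#' @param years Coupled run years.
#' @param dt Coupled time step (default from the world config).
#' @return An `erw_ensemble` list: `members` (accepted parameter sets),
#'   `counts`, `rejections`, `criteria`, `seed`, and (with a coupled stage)
#'   `controls` — the per-member coupled control outputs.
#' @export
build_ensemble <- function(prior = parameter_prior(),
                           criteria = filter_criteria(),
                           n_initial = 1e5, n_coupled = 300, seed = 1,
                           world = NULL, pathway = NULL,
                           offline_scenarios = NULL,
                           years = 1765:2100, dt = NULL) {
  members <- sample_priors(prior, n_initial, seed)
  if (is.null(offline_scenarios))
    offline_scenarios <- list(builtin_pathway("mid"),
                              builtin_pathway("high"))
  t0_land <- if (!is.null(world)) world$config$t0_land else 8.0
  forcings <- lapply(offline_scenarios, offline_forcing, t0_land = t0_land)
  # truncate to the years the filters actually evaluate
  hist_forcing <- forcings[[1]][forcings[[1]]$year <= criteria$modern_year, ]
  dyn_forcings <- lapply(forcings, function(f)
    f[f$year <= criteria$century[2], ])

  st <- filter_static(members, hist_forcing, criteria)
  dyn <- filter_dynamic(members[st$pass, , drop = FALSE], dyn_forcings,
                        criteria)
  offline_pass <- members[st$pass, , drop = FALSE][dyn$pass, , drop = FALSE]
  counts <- list(n_initial = n_initial,
                 n_static = sum(st$pass),
                 n_offline = nrow(offline_pass))
  rejections <- list(soil = sum(!st$pass_soil), npp = sum(!st$pass_npp),
                     turnover = sum(!st$pass_turnover),
                     dynamic = sum(st$pass) - nrow(offline_pass))
  if (nrow(offline_pass) == 0)
    stop(paste0("no ensemble members survived offline filtering; ",
                "rejections: ", paste(names(rejections), unlist(rejections),
                                      sep = "=", collapse = ", ")))

  if (is.null(world)) {
    out <- list(members = offline_pass, counts = counts,
                rejections = rejections, criteria = criteria, seed = seed)
    class(out) <- "erw_ensemble"
    return(out)
  }

  if (is.null(pathway)) pathway <- builtin_pathway("mid")
  if (is.null(dt)) dt <- world$config$dt
  n_coupled <- min(n_coupled, nrow(offline_pass))
  cand <- offline_pass[seq_len(n_coupled), , drop = FALSE]
  keep <- logical(n_coupled)
  controls <- vector("list", n_coupled)
  my <- criteria$modern_year
  for (i in seq_len(n_coupled)) {
    sp <- slab_params_from_df(cand[i, ])
    ctrl <- run_control(world, pathway, sp, years = years, dt = dt)
    led <- ctrl$ledger
    i_my <- match(my, led$year)
    i_c0 <- match(criteria$century[1], led$year)
    i_c1 <- match(criteria$century[2], led$year)
    n_mod <- sp$n0 * (1 + sp$b * log(led$co2_ppm[i_my] / sp$c0))
    tau_mod <- sp$lambda_veg * led$veg[i_my] + sp$lambda_0
    ok <- led$soil[i_my] >= criteria$soil[1] &
      led$soil[i_my] <= criteria$soil[2] &
      n_mod >= criteria$npp[1] & n_mod <= criteria$npp[2] &
      tau_mod >= criteria$turnover[1] & tau_mod <= criteria$turnover[2] &
      (led$veg[i_c1] - led$veg[i_c0]) >= criteria$delta_v[1] &
      (led$veg[i_c1] - led$veg[i_c0]) <= criteria$delta_v[2] &
      (led$soil[i_c1] - led$soil[i_c0]) >= criteria$delta_s[1] &
      (led$soil[i_c1] - led$soil[i_c0]) <= criteria$delta_s[2]
    keep[i] <- isTRUE(ok)
    controls[[i]] <- ctrl
  }
  counts$n_coupled_tried <- n_coupled
  counts$n_final <- sum(keep)
  if (counts$n_final == 0)
    stop("no ensemble members survived coupled filtering")
  out <- list(members = cand[keep, , drop = FALSE],
              controls = controls[keep],
              counts = counts, rejections = rejections,
              criteria = criteria, seed = seed)
  class(out) <- "erw_ensemble"
  out
}

#' @export
print.erw_ensemble <- function(x, ...) {
  cat("<erw_ensemble>\n  counts:",
      paste(names(x$counts), unlist(x$counts), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Median and central-interval summary of ensemble values
#'
#' @param values Numeric vector (one value per member).
#' @param level Central interval probability (default 0.68, mirroring
#'   one-sigma-style reporting).
#' @return List: `median`, `lo`, `hi`, `sd`.
#' @export
ensemble_summary <- function(values, level = 0.68) {
  qs <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  list(median = stats::median(values, na.rm = TRUE), lo = qs[1], hi = qs[2],
       sd = stats::sd(values))
}
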