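#' Run the full backflux/leakage study
#'
#' End-to-end reproduction pipeline: spin up the box model, build the
#' observationally filtered slab ensemble (two-stage: offline filtering of
#' `n_initial` prior draws, then coupled filtering of `n_coupled`
#' candidates), and for every retained member run the paired
#' control/intervention experiments needed for the headline diagnostics:
#'
#' * baseline (modulated emissions) backflux `p_base` through `eval_year`
#'   on the low- and high-emission scenarios,
#' * ERW leakage `p_leak` for silicate and carbonate feedstock on the
#'   mid-range scenario, with the silicate storage efficiency,
#' * the surface aragonite-saturation co-benefit at `omega_year` on the
#'   mid-range scenario.
#'
#' All randomness derives from `seed`; given the same seed and sizes the
#' study is exactly reproducible.
#'
#' @param seed Integer seed.
#' @param n_members Ensemble members carried through the experiments
#'   (capped at the number surviving the coupled filter).
#' @param n_initial Stage-1 prior sample size.
#' @param n_coupled Offline survivors promoted to coupled filtering.
#' @param rate CDR deployment rate, GtCO2/yr.
#' @param start_year Deployment start.
#' @param end_year Last simulated year.
#' @param eval_year Year at which p is evaluated ("end of the century" =
#'   integrated through this year inclusive).
#' @param omega_year Year for the saturation co-benefit.
#' @param dt Time step, years.
#' @param progress Print per-member progress.
#' @return A list: `summary` (named medians: `p_base_low`, `p_base_high`,
#'   `p_leak_silicate`, `p_leak_carbonate`, `storage_efficiency_silicate`,
#'   `omega_increase_erw_pct`, `omega_ratio_erw_over_base`), `per_member`
#'   (data.frame of per-member metrics), `envelopes` (central-68% intervals),
#'   `counts` (ensemble bookkeeping), and `n_members`.
#' @export
run_erw_study <- function(seed = 1, n_members = 100, n_initial = 250000,
                          n_coupled = 120, rate = 10, start_year = 2030,
                          end_year = 2100, eval_year = 2100,
                          omega_year = 2070, dt = 0.1, progress = FALSE) {
  cfg <- world_config(dt = dt)
  world <- spinup(cfg)
  pw_mid <- builtin_pathway("mid")
  ens <- build_ensemble(parameter_prior(), filter_criteria(),
                        n_initial = n_initial, n_coupled = n_coupled,
                        seed = seed, world = world, pathway = pw_mid,
                        years = 1765:end_year, dt = dt)
  n_use <- min(n_members, nrow(ens$members))
  members <- ens$members[seq_len(n_use), , drop = FALSE]

  iv_base <- intervention("baseline", rate = rate, start_year = start_year)
  iv_sil <- intervention("erw", "silicate", rate = rate,
                         start_year = start_year)
  iv_carb <- intervention("erw", "carbonate", rate = rate,
                          start_year = start_year)

  res <- data.frame(member = members$member,
                    p_base_low = NA_real_, p_base_high = NA_real_,
                    p_base_mid = NA_real_,
                    p_leak_sil = NA_real_, p_leak_carb = NA_real_,
                    omega_erw = NA_real_, omega_base = NA_real_)
  for (i in seq_len(n_use)) {
    sp <- slab_params_from_df(members[i, ])
    # mid-range scenario: reuse the coupled-stage control
    ctrl_mid <- ens$controls[[i]]
    ctrlb <- run_experiment(ctrl_mid, NULL, sp, end_year = end_year)
    base <- run_experiment(ctrl_mid, iv_base, sp, end_year = end_year)
    sil <- run_experiment(ctrl_mid, iv_sil, sp, end_year = end_year)
    carb <- run_experiment(ctrl_mid, iv_carb, sp, end_year = end_year)
    res$p_base_mid[i] <- backflux(base, ctrlb, eval_year)
    res$p_leak_sil[i] <- p_leak(sil, base, ctrlb, eval_year)
    res$p_leak_carb[i] <- p_leak(carb, base, ctrlb, eval_year)
    ob <- omega_cobenefit(sil, base, ctrlb, omega_year)
    res$omega_erw[i] <- ob$pct_change_erw
    res$omega_base[i] <- ob$pct_change_base
    # low- and high-emission scenarios: baseline backflux
    for (scen in c("low", "high")) {
      ctrl <- run_control(world, builtin_pathway(scen), sp,
                          years = 1765:end_year, dt = dt)
      cb <- run_experiment(ctrl, NULL, sp, end_year = end_year)
      bb <- run_experiment(ctrl, iv_base, sp, end_year = end_year)
      res[[paste0("p_base_", scen)]][i] <- backflux(bb, cb, eval_year)
    }
    if (progress && i %% 10 == 0)
      message(sprintf("member %d / %d done", i, n_use))
  }

  med <- function(x) stats::median(x)
  summary <- list(
    p_base_low = med(res$p_base_low),
    p_base_high = med(res$p_base_high),
    p_base_mid = med(res$p_base_mid),
    p_leak_silicate = med(res$p_leak_sil),
    p_leak_carbonate = med(res$p_leak_carb),
    storage_efficiency_silicate = 100 - med(res$p_leak_sil),
    omega_increase_erw_pct = med(res$omega_erw),
    omega_increase_base_pct = med(res$omega_base),
    omega_ratio_erw_over_base = med(res$omega_erw / res$omega_base),
    leak_ratio_carb_over_sil = med(res$p_leak_carb / res$p_leak_sil))
  envelopes <- lapply(res[-1], ensemble_summary)
  list(summary = summary, per_member = res, envelopes = envelopes,
       counts = ens$counts, n_members = n_use, seed = seed,
       world = world, ensemble = ens)
}
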