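#' Trapezoidal integral of an annual series
#' @param x Time axis (years).
#' @param y Values.
#' @return Integral over the full axis.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

check_paired <- function(exp_ledger, ctrl_ledger, from, to) {
  yrs <- exp_ledger$year
  if (!all(c(from, to) %in% yrs) || !all(c(from, to) %in% ctrl_ledger$year))
    stop("ledgers do not cover the requested interval")
  e <- exp_ledger[exp_ledger$year >= from & exp_ledger$year <= to, ]
  c <- ctrl_ledger[ctrl_ledger$year >= from & ctrl_ledger$year <= to, ]
  if (!identical(e$year, c$year))
    stop("experiment and control ledgers have mismatched time axes")
  list(e = e, c = c)
}

#' Net CDR impact ratio eta
#'
#' Time-integrated net impact of an intervention on atmospheric CO2: the
#' deployed removal (or additional mitigation) minus the excess release of
#' carbon from ocean and land relative to the control, normalized by the
#' cumulative deployment:
#' `eta(t) = Int[J_CDR - dJ_sea-air - dJ_lnd-air] / Int[J_CDR]`,
#' integrated (trapezoid on the annual-mean series) from the intervention
#' start.  Dimensionless; 1 means no backflux.
#'
#' @param exp_ledger,ctrl_ledger Paired `run_ledger`s sharing a time axis.
#' @param t Evaluation year (integration upper bound, inclusive).
#' @param from Integration start (default the experiment's intervention
#'   start year, else the first ledger year).
#' @return `eta` at `t` (scalar).
#' @export
eta <- function(exp_ledger, ctrl_ledger, t, from = NULL) {
  iv <- attr(exp_ledger, "intervention")
  if (is.null(from))
    from <- if (!is.null(iv)) iv$start_year else min(exp_ledger$year)
  p <- check_paired(exp_ledger, ctrl_ledger, from, t)
  denom <- trapz(p$e$year, p$e$j_cdr)
  if (denom <= 0) {
    warning("cumulative J_CDR is zero; eta undefined")
    return(NA_real_)
  }
  integrand <- p$e$j_cdr - (p$e$j_sea_air - p$c$j_sea_air) -
    (p$e$j_lnd_air - p$c$j_lnd_air)
  trapz(p$e$year, integrand) / denom
}

#' Carbon backflux percentage p
#'
#' `p = (1 - eta) * 100`: the percentage of deployed CDR (or additional
#' mitigation) counteracted by carbon release from the ocean and
#' terrestrial reservoirs up to year `t`.
#'
#' @inheritParams eta
#' @return Backflux percentage at `t`.
#' @export
backflux <- function(exp_ledger, ctrl_ledger, t, from = NULL) {
  (1 - eta(exp_ledger, ctrl_ledger, t, from = from)) * 100
}

check_matched_interventions <- function(a, b) {
  ia <- attr(a, "intervention"); ib <- attr(b, "intervention")
  if (is.null(ia) || is.null(ib))
    stop("both ledgers must carry an intervention")
  ra <- if (is.data.frame(ia$rate)) ia$rate$rate else ia$rate
  rb <- if (is.data.frame(ib$rate)) ib$rate$rate else ib$rate
  if (!isTRUE(all.equal(ra, rb)) || ia$start_year != ib$start_year)
    stop("ERW and baseline ledgers must share rate and start year")
  la <- attr(a, "label"); lb <- attr(b, "label")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("ERW and baseline ledgers come from different scenarios")
  invisible(TRUE)
}

#' ERW carbon leakage p_leak
#'
#' The additional backflux of an ERW deployment beyond the equivalent
#' baseline (modulated-emissions) intervention at the same rate, start year
#' and scenario: `p_leak(t) = p_ERW(t) - p_base(t)`.  This isolates the
#' re-release of carbon that was initially captured through ERW.
#'
#' @param erw_ledger,base_ledger,ctrl_ledger `run_ledger`s on one time axis;
#'   ERW and baseline must use the same rate, start year and scenario.
#' @param t Evaluation year.
#' @return `p_leak` at `t`, percentage points.
#' @export
p_leak <- function(erw_ledger, base_ledger, ctrl_ledger, t) {
  check_matched_interventions(erw_ledger, base_ledger)
  backflux(erw_ledger, ctrl_ledger, t) -
    backflux(base_ledger, ctrl_ledger, t)
}

#' Long-term ocean storage efficiency of ERW
#'
#' `100 - p_leak(t)`: the percentage of carbon initially captured through
#' ERW that remains stored (predominantly as DIC in the ocean interior)
#' after correcting for the baseline Earth-system backflux.  Also reports
#' the excess sub-surface ocean DIC inventory of the ERW run relative to
#' the baseline run at `t` (the box-model analogue of a depth-integrated
#' DIC anomaly).
#'
#' @inheritParams p_leak
#' @return List: `efficiency` (percent) and `excess_ocean_dic_gtc`.
#' @export
storage_efficiency <- function(erw_ledger, base_ledger, ctrl_ledger, t) {
  pl <- p_leak(erw_ledger, base_ledger, ctrl_ledger, t)
  ie <- match(t, erw_ledger$year); ib <- match(t, base_ledger$year)
  list(efficiency = 100 - pl,
       excess_ocean_dic_gtc =
         erw_ledger$ocean_dic_gtc[ie] - base_ledger$ocean_dic_gtc[ib])
}

#' Surface aragonite saturation co-benefit
#'
#' Percent change of the area-weighted global-mean surface aragonite
#' saturation state in the ERW and baseline runs relative to the control at
#' year `t`, and their ratio — the leverage of alkalinity delivery on
#' surface carbonate chemistry beyond direct CO2 removal alone.
#'
#' @param erw_ledger,base_ledger,ctrl_ledger `run_ledger`s.
#' @param t Evaluation year.
#' @return List: `omega_erw`, `omega_base`, `omega_ctrl` (levels),
#'   `pct_change_erw`, `pct_change_base`, `ratio`.
#' @export
omega_cobenefit <- function(erw_ledger, base_ledger, ctrl_ledger, t) {
  oe <- erw_ledger$surf_omega_arg[match(t, erw_ledger$year)]
  ob <- base_ledger$surf_omega_arg[match(t, base_ledger$year)]
  oc <- ctrl_ledger$surf_omega_arg[match(t, ctrl_ledger$year)]
  if (any(is.na(c(oe, ob, oc)))) stop("year not covered by all ledgers")
  ce <- (oe / oc - 1) * 100
  cb <- (ob / oc - 1) * 100
  list(omega_erw = oe, omega_base = ob, omega_ctrl = oc,
       pct_change_erw = ce, pct_change_base = cb,
       ratio = if (cb != 0) ce / cb else NA_real_)
}

#' Rate-independence audit of the relative backflux
#'
#' The relative backflux p is expected to be nearly independent of the
#' deployment rate over roughly two orders of magnitude.  Given a list of
#' (experiment, control) ledger pairs across rates, computes p at `t` for
#' each and flags whether the max-min spread exceeds `band` percentage
#' points.
#'
#' @param experiments Named list; each element a list with `exp` and `ctrl`
#'   ledgers (optionally `base` for p_leak).
#' @param t Evaluation year.
#' @param band Allowed spread, percentage points.
#' @return List: `p` (per rate), `spread`, `within_band`.
#' @export
rate_independence_audit <- function(experiments, t, band = 5) {
  p <- vapply(experiments, function(e) {
    if (!is.null(e$base)) p_leak(e$exp, e$base, e$ctrl, t)
    else backflux(e$exp, e$ctrl, t)
  }, numeric(1))
  spread <- if (length(p) > 1) max(p) - min(p) else 0
  list(p = p, spread = spread, within_band = spread <= band)
}

#' Backflux time series for one experiment/control pair
#'
#' Convenience wrapper returning `eta(t)` and `p(t)` for every ledger year
#' at or after the intervention start, plus the integrand components.
#'
#' @inheritParams eta
#' @return data.frame `year`, `eta`, `p`.
#' @export
backflux_series <- function(exp_ledger, ctrl_ledger, from = NULL) {
  iv <- attr(exp_ledger, "intervention")
  if (is.null(from))
    from <- if (!is.null(iv)) iv$start_year else min(exp_ledger$year)
  yrs <- exp_ledger$year[exp_ledger$year > from]
  et <- vapply(yrs, function(t) eta(exp_ledger, ctrl_ledger, t, from = from),
               numeric(1))
  data.frame(year = yrs, eta = et, p = (1 - et) * 100)
}
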