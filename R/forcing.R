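#' Built-in concentration-pathway anchor sets
#'
#' Idealized anchor points (year, concentration) for three greenhouse-gas
#' trajectories spanning 1765-2300, standing in for the published
#' concentration-pathway tables so the package runs self-contained:
#' \describe{
#'   \item{"low"}{CO2 peaks near 450 ppm mid-century and declines toward
#'     ~420 ppm by 2100 (strong-mitigation-like).}
#'   \item{"mid"}{CO2 stabilizes near 540 ppm after 2100
#'     (moderate-mitigation-like, RCP4.5-like).}
#'   \item{"high"}{CO2 reaches ~940 ppm by 2100 and stabilizes near 1960
#'     ppm by 2250 (high-emission-like, RCP8.5-like).}
#' }
#' The anchor values are approximations chosen to emulate the canonical
#' pathway shapes; user-supplied tables can be used instead via
#' [read_pathway_csv()].
#'
#' @param scenario One of `"low"`, `"mid"`, `"high"`.
#' @return A list of three data.frames (`co2`, `ch4`, `n2o`) with columns
#'   `year`, `value`.
#' @export
scenario_anchors <- function(scenario = c("low", "mid", "high")) {
  scenario <- match.arg(scenario)
  hist_co2 <- data.frame(
    year  = c(1765, 1800, 1850, 1900, 1950, 1980, 2000, 2010, 2020),
    value = c(278, 283, 285, 296, 311, 339, 369, 390, 412))
  hist_ch4 <- data.frame(
    year  = c(1765, 1850, 1900, 1950, 2000, 2020),
    value = c(722, 800, 925, 1147, 1751, 1870))
  hist_n2o <- data.frame(
    year  = c(1765, 1900, 1950, 2000, 2020),
    value = c(270, 280, 290, 316, 333))
  fut <- switch(scenario,
    low = list(
      co2 = data.frame(year  = c(2030, 2050, 2070, 2100, 2150, 2200, 2300),
                       value = c(435, 450, 442, 420, 405, 395, 385)),
      ch4 = data.frame(year  = c(2050, 2100, 2300),
                       value = c(1452, 1254, 1250)),
      n2o = data.frame(year  = c(2100, 2300),
                       value = c(344, 342))),
    mid = list(
      co2 = data.frame(year  = c(2030, 2050, 2070, 2100, 2150, 2300),
                       value = c(435, 487, 524, 538, 543, 543)),
      ch4 = data.frame(year  = c(2050, 2100, 2300),
                       value = c(1833, 1576, 1576)),
      n2o = data.frame(year  = c(2100, 2300),
                       value = c(372, 372))),
    high = list(
      co2 = data.frame(year  = c(2030, 2050, 2070, 2100, 2150, 2200, 2250, 2300),
                       value = c(449, 541, 677, 936, 1430, 1760, 1960, 1962)),
      ch4 = data.frame(year  = c(2050, 2100, 2250, 2300),
                       value = c(2740, 3751, 3900, 3900)),
      n2o = data.frame(year  = c(2100, 2250, 2300),
                       value = c(435, 525, 525))))
  list(co2 = rbind(hist_co2, fut$co2),
       ch4 = rbind(hist_ch4, fut$ch4),
       n2o = rbind(hist_n2o, fut$n2o))
}

interp_anchors <- function(anchors, years) {
  if (any(!is.finite(anchors$value)) || any(anchors$value <= 0))
    stop("anchors must be finite and > 0")
  if (is.unsorted(anchors$year, strictly = TRUE))
    stop("anchor years must be strictly increasing")
  if (nrow(anchors) == 1)
    return(rep(anchors$value, length(years)))
  f <- stats::splinefun(anchors$year, anchors$value, method = "monoH.FC")
  out <- f(pmin(pmax(years, min(anchors$year)), max(anchors$year)))
  out
}

#' Synthesize an idealized concentration pathway
#'
#' Builds an annual concentration trajectory for CO2, CH4, and N2O over
#' `years` by piecewise-monotone cubic interpolation (Fritsch-Carlson)
#' through anchor control points.  The interpolant passes through the
#' anchors exactly and preserves monotonicity between monotone anchors
#' (non-monotone anchor sequences may overshoot slightly near a peak).
#'
#' @param anchors Anchor list as returned by [scenario_anchors()], or a
#'   single data.frame of CO2 anchors (`year`, `value`) in which case CH4 and
#'   N2O are held preindustrial.
#' @param label Scenario label stored on the result.
#' @param years Annual time axis (default 1765-2300).
#' @return A `concentration_pathway` data.frame with columns `year`, `co2`
#'   (ppm), `ch4`, `n2o` (ppb), and attribute `label`.
#' @export
synthesize_pathway <- function(anchors, label = "custom",
                               years = 1765:2300) {
  if (is.data.frame(anchors))
    anchors <- list(co2 = anchors,
                    ch4 = data.frame(year = range(anchors$year),
                                     value = erw_constants$ch4_ppb_pi),
                    n2o = data.frame(year = range(anchors$year),
                                     value = erw_constants$n2o_ppb_pi))
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  out <- data.frame(year = years,
                    co2 = interp_anchors(anchors$co2, years),
                    ch4 = interp_anchors(anchors$ch4, years),
                    n2o = interp_anchors(anchors$n2o, years))
  if (any(out$co2 <= 0) || any(out$ch4 <= 0) || any(out$n2o <= 0))
    stop("synthesized pathway has non-positive concentrations")
  attr(out, "label") <- label
  class(out) <- c("concentration_pathway", "data.frame")
  out
}

#' Shorthand for the built-in scenarios
#' @param scenario `"low"`, `"mid"`, or `"high"`.
#' @param years Annual time axis.
#' @return A `concentration_pathway`.
#' @export
builtin_pathway <- function(scenario = c("low", "mid", "high"),
                            years = 1765:2300) {
  scenario <- match.arg(scenario)
  synthesize_pathway(scenario_anchors(scenario), label = scenario,
                     years = years)
}

#' Read a concentration pathway from CSV
#'
#' Accepts a table with columns `year`, `co2`, and optionally `ch4`, `n2o`
#' (held preindustrial when absent), e.g. a real concentration-pathway table
#' supplied by the user.
#'
#' @param path CSV file path.
#' @param label Scenario label.
#' @return A `concentration_pathway`.
#' @export
read_pathway_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("year", "co2") %in% names(d)))
    stop("pathway CSV needs at least 'year' and 'co2' columns")
  if (is.null(d$ch4)) d$ch4 <- erw_constants$ch4_ppb_pi
  if (is.null(d$n2o)) d$n2o <- erw_constants$n2o_ppb_pi
  out <- d[, c("year", "co2", "ch4", "n2o")]
  if (is.unsorted(out$year, strictly = TRUE))
    stop("pathway years must be strictly increasing")
  if (any(out$co2 <= 0 | out$ch4 <= 0 | out$n2o <= 0))
    stop("pathway concentrations must be > 0")
  attr(out, "label") <- label
  class(out) <- c("concentration_pathway", "data.frame")
  out
}

#' Write a pathway or emission trajectory to CSV
#' @param x data.frame to write.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Diagnose the emission trajectory implied by a prescribed CO2 pathway
#'
#' Runs the full coupled model from the spun-up state with atmospheric CO2
#' prescribed to the pathway; the emission each year is the atmospheric
#' carbon increment plus the net uptake by ocean and land.  Re-running the
#' model emission-driven with the diagnosed trajectory reproduces the
#' prescribed CO2 to below `tol_ppm` everywhere (checked when
#' `check_roundtrip = TRUE`; failure is an error reporting the residual).
#'
#' @param pathway A `concentration_pathway`.
#' @param world Spun-up `world_state`.
#' @param slab_par A `slab_params`.
#' @param years Run years.
#' @param dt Time step, years.
#' @param check_roundtrip Verify the inversion by an emission-driven rerun.
#' @param tol_ppm Round-trip tolerance, ppm.
#' @return data.frame `year`, `emission` (GtCO2/yr) with attribute
#'   `provenance` naming the pathway.
#' @export
diagnose_emissions <- function(pathway, world, slab_par,
                               years = 1765:2100, dt = world$config$dt,
                               check_roundtrip = FALSE, tol_ppm = 1) {
  ctrl <- run_control(world, pathway, slab_par, years = years, dt = dt)
  if (check_roundtrip) {
    fwd <- integrate_world(world, years, mode = "emission",
                           pathway = pathway, emissions = ctrl$emissions,
                           slab_par = slab_par, dt = dt)
    idx <- match(years, pathway$year)
    resid <- max(abs(fwd$ledger$co2_ppm - pathway$co2[idx + 1]))
    if (resid > tol_ppm)
      stop(sprintf("emission inversion round-trip residual %.3g ppm", resid))
  }
  ctrl$emissions
}
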