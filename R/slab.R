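#' Construct a slab-biosphere parameter set
#'
#' The globally aggregated two-pool terrestrial carbon model has six free
#' parameters plus two reference values:
#' \describe{
#'   \item{n0}{Net primary production at the reference pCO2, GtC/y.}
#'   \item{b}{CO2-fertilization growth parameter (dimensionless).}
#'   \item{lambda_veg}{Vegetation-dependent turnover coefficient, y/GtC.}
#'   \item{lambda_0}{Baseline vegetation turnover time, y.}
#'   \item{gamma}{Soil carbon turnover rate at the reference temperature, 1/y.}
#'   \item{q10}{Factor change in soil respiration per 10 degC warming.}
#'   \item{c0}{Reference atmospheric pCO2, ppm (preindustrial by default).}
#'   \item{t0}{Reference land temperature, degC.}
#' }
#' A positive vegetation steady state requires `n0 * lambda_veg < 1`.
#'
#' @param n0,b,lambda_veg,lambda_0,gamma,q10,c0,t0 Parameter values.
#' @return A `slab_params` list.
#' @export
slab_params <- function(n0 = 50, b = 0.6, lambda_veg = 0.002, lambda_0 = 10,
                        gamma = 0.033, q10 = 2, c0 = erw_constants$co2_ppm_pi,
                        t0 = 8.0) {
  p <- list(n0 = n0, b = b, lambda_veg = lambda_veg, lambda_0 = lambda_0,
            gamma = gamma, q10 = q10, c0 = c0, t0 = t0)
  validate_slab_params(p)
  class(p) <- "slab_params"
  p
}

validate_slab_params <- function(p) {
  with(p, {
    if (any(n0 <= 0) || any(lambda_0 <= 0) || any(gamma <= 0) ||
        any(q10 <= 0))
      stop("n0, lambda_0, gamma, q10 must be > 0")
    if (any(lambda_veg < 0)) stop("lambda_veg must be >= 0")
    if (any(n0 * lambda_veg >= 1))
      stop("n0 * lambda_veg must be < 1 for a positive vegetation steady state")
  })
  invisible(p)
}

#' Net primary production as a function of atmospheric pCO2
#'
#' `N = n0 * (1 + b * log(C / c0))`, clipped at zero (with a warning) if a
#' very low pCO2 drives the logarithm negative enough to exceed `1/b`.
#'
#' @param c_ppm Atmospheric pCO2, ppm (> 0).
#' @param params A `slab_params` object (vector fields allowed).
#' @return NPP, GtC/y.
#' @export
npp <- function(c_ppm, params) {
  if (any(c_ppm <= 0)) stop("atmospheric pCO2 must be > 0")
  n <- params$n0 * (1 + params$b * log(c_ppm / params$c0))
  if (any(n < 0)) {
    warning("NPP clipped at zero for some states")
    n <- pmax(n, 0)
  }
  n
}

#' Litterfall production
#'
#' `L = V / (lambda_veg * V + lambda_0)`: vegetation is lost on an intrinsic
#' turnover time `lambda_veg * V + lambda_0` (years) that grows with standing
#' biomass.
#'
#' @param v Vegetation carbon, GtC (>= 0).
#' @param params A `slab_params` object.
#' @return Litterfall, GtC/y.
#' @export
litterfall <- function(v, params) {
  if (any(v < 0)) stop("vegetation carbon must be >= 0")
  v / (params$lambda_veg * v + params$lambda_0)
}

#' Vegetation turnover time diagnostic
#' @param v Vegetation carbon, GtC.
#' @param params A `slab_params` object.
#' @return Turnover time `lambda_veg * V + lambda_0`, years.
#' @export
vegetation_turnover <- function(v, params) {
  params$lambda_veg * v + params$lambda_0
}

#' Soil respiration with Q10 temperature dependence
#'
#' `R = gamma * S * q10^((T - t0) / 10)`.
#'
#' @param s Soil carbon, GtC (>= 0).
#' @param t_land Land temperature, degC.
#' @param params A `slab_params` object.
#' @return Soil respiration, GtC/y.
#' @export
soil_respiration <- function(s, t_land, params) {
  if (any(s < 0)) stop("soil carbon must be >= 0")
  params$gamma * s * params$q10^((t_land - params$t0) / 10)
}

#' Closed-form slab steady state at the reference climate
#'
#' At `(c0, t0)`, `dV/dt = dS/dt = 0` gives
#' `V* = n0 * lambda_0 / (1 - n0 * lambda_veg)` and `S* = n0 / gamma`.
#'
#' @param params A `slab_params` object.
#' @return List with `v_star`, `s_star` (GtC).
#' @export
slab_steady_state <- function(params) {
  list(v_star = params$n0 * params$lambda_0 / (1 - params$n0 * params$lambda_veg),
       s_star = params$n0 / params$gamma)
}

slab_derivs <- function(v, s, c_ppm, t_land, params) {
  n <- params$n0 * pmax(0, 1 + params$b * log(c_ppm / params$c0))
  l <- v / (params$lambda_veg * v + params$lambda_0)
  r <- params$gamma * s * params$q10^((t_land - params$t0) / 10)
  list(dv = n - l, ds = l - r, n = n, l = l, r = r)
}

#' Integrate the slab biosphere over one step
#'
#' RK4 update of the vegetation and soil pools under fixed atmospheric pCO2
#' and land temperature over the step.  Pools are clipped at zero if a step
#' would drive them negative (logged via warning); carbon accounting remains
#' exact because the returned land-air flux is computed from the actual pool
#' change, `J_lnd_air = -(dV + dS)/dt`, converted to GtCO2/y (positive into
#' the atmosphere).
#'
#' Stability: RK4 is stable here for `dt` well below the fastest pool
#' timescale, `min(lambda_0, 1/gamma)` years; the package default `dt = 0.1`
#' y is far inside that bound for all admissible priors.
#'
#' @param state List with `v`, `s` (GtC; scalars or member vectors).
#' @param c_ppm Atmospheric pCO2, ppm.
#' @param t_land Land temperature, degC.
#' @param params A `slab_params` object (fields may be member vectors).
#' @param dt Time step, years.
#' @return List with updated `v`, `s`, diagnostic fluxes `n`, `l`, `r`
#'   (GtC/y), and `j_lnd_air` (GtCO2/y, positive = into atmosphere).
#' @export
slab_step <- function(state, c_ppm, t_land, params, dt) {
  if (dt <= 0) stop("dt must be > 0")
  v0 <- state$v; s0 <- state$s
  k1 <- slab_derivs(v0, s0, c_ppm, t_land, params)
  k2 <- slab_derivs(v0 + 0.5 * dt * k1$dv, s0 + 0.5 * dt * k1$ds,
                    c_ppm, t_land, params)
  k3 <- slab_derivs(v0 + 0.5 * dt * k2$dv, s0 + 0.5 * dt * k2$ds,
                    c_ppm, t_land, params)
  k4 <- slab_derivs(v0 + dt * k3$dv, s0 + dt * k3$ds, c_ppm, t_land, params)
  v1 <- v0 + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
  s1 <- s0 + dt / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
  if (any(v1 < 0) || any(s1 < 0)) {
    warning("slab pool clipped at zero")
    v1 <- pmax(v1, 0); s1 <- pmax(s1, 0)
  }
  j_lnd_gtc <- -((v1 - v0) + (s1 - s0)) / dt
  list(v = v1, s = s1, n = k1$n, l = k1$l, r = k1$r,
       j_lnd_air = gtc_to_gtco2(j_lnd_gtc))
}

#' Offline slab-biosphere run under prescribed forcing
#'
#' Integrates the slab model (vectorized over ensemble members) from the
#' reference steady state along annual pCO2 and land-temperature series.
#' This is the stand-alone configuration used for ensemble filtering.
#'
#' @param params A `slab_params` whose fields may be equal-length vectors
#'   (one element per member).
#' @param years Annual time axis.
#' @param co2_ppm Atmospheric pCO2 per year, ppm.
#' @param t_land Land temperature per year, degC.
#' @param dt Integration step, years.
#' @param out_years Years at which to record pools/fluxes (default all).
#' @return List of matrices (`length(out_years)` x members): `v`, `s`, `n`,
#'   `turnover`, plus `out_years`.
#' @export
slab_run <- function(params, years, co2_ppm, t_land, dt = 0.1,
                     out_years = years) {
  stopifnot(length(years) == length(co2_ppm),
            length(years) == length(t_land))
  ss <- slab_steady_state(params)
  v <- ss$v_star; s <- ss$s_star
  n_mem <- length(v)
  out_idx <- match(out_years, years)
  if (any(is.na(out_idx))) stop("out_years must be a subset of years")
  res_v <- matrix(NA_real_, length(out_years), n_mem)
  res_s <- res_v; res_n <- res_v
  rec <- function(i_out, n_now) {
    res_v[i_out, ] <<- v; res_s[i_out, ] <<- s; res_n[i_out, ] <<- n_now
  }
  d0 <- slab_derivs(v, s, co2_ppm[1], t_land[1], params)
  if (!is.na(io <- match(1L, out_idx))) rec(io, d0$n)
  n_sub <- max(1L, round(1 / dt))
  for (i in seq_along(years)[-1]) {
    for (sub in seq_len(n_sub)) {
      frac <- (sub - 0.5) / n_sub
      cc <- co2_ppm[i - 1] + frac * (co2_ppm[i] - co2_ppm[i - 1])
      tt <- t_land[i - 1] + frac * (t_land[i] - t_land[i - 1])
      st <- slab_step(list(v = v, s = s), cc, tt, params, 1 / n_sub)
      v <- st$v; s <- st$s
    }
    if (!is.na(io <- match(i, out_idx))) {
      d <- slab_derivs(v, s, co2_ppm[i], t_land[i], params)
      rec(io, d$n)
    }
  }
  list(out_years = out_years, v = res_v, s = res_s, n = res_n,
       turnover = sweep(sweep(res_v, 2, params$lambda_veg, "*"), 2,
                        params$lambda_0, "+"))
}
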