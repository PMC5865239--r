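#' @useDynLib nitricline, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# flatten ecosystem params to the scalar list the compiled core expects
flatten_bio <- function(params) {
  ph <- params$phyto
  list(
    y_aoo = params$aoo$y, vmax_aoo = params$aoo$traits$vmax,
    k_aoo = params$aoo$traits$k,
    y_noo = params$noo$y, vmax_noo = params$noo$traits$vmax,
    k_noo = params$noo$traits$k,
    vmax_d = params$het$vmax_d, k_d = params$het$k_d, y_d = params$het$y_d,
    mu_max = ph$mu_max, k_nh4p = ph$k_nh4p, k_no2p = ph$k_no2p,
    k_no3p = ph$k_no3p,
    gamma_coef = ph$phi * ph$a_chl * 0.0864 * 12000,
    theta_max = ph$theta_max,
    chl_coef = ph$cn_ratio * C_G_PER_MOL * 1000,
    g_max = params$grazing$g_max, k_g = params$grazing$k_g,
    zeta = params$grazing$zeta, m_z = params$grazing$m_z, m_b = params$m_b
  )
}

o2_factor_profile <- function(params, n) {
  if (isTRUE(params$o2$enabled)) {
    o2 <- rep_len(params$o2$profile, n)
    o2 / (o2 + params$o2$k_o2)
  } else {
    rep(1, n)
  }
}

#' Integrate the column model to equilibrium
#'
#' Advances the nine-variable column with fixed-step classical RK4
#' over the combined biological, diffusive, and sinking tendencies
#' until the solution stops changing: the convergence metric is the
#' maximum over variables and depths of \eqn{|dC/dt| / (C + \epsilon)}
#' estimated from successive daily-averaged states over a trailing
#' window (\eqn{\epsilon} = 1e-6 umol/L). Negative concentrations
#' produced by a step are clipped to zero with the removed mass
#' logged, so the nitrogen budget remains auditable.
#'
#' @param params [ecosystem_params()].
#' @param grid [column_grid()].
#' @param physics [physics_params()].
#' @param state Initial state matrix (n x 9, mol N/m^3); default
#'   [column_init()].
#' @param dt Time step in days; default [auto_dt()] (half the stricter
#'   stability bound). Rounded so that a day holds an integer number
#'   of steps.
#' @param tolerance Convergence tolerance on the metric (per day).
#' @param max_time Maximum simulated time in days; if reached without
#'   convergence the result is flagged, not an error.
#' @param check_every Days between convergence checks (the trailing
#'   window).
#' @param clip Clip negative concentrations after each step (default
#'   `TRUE`). With clipping off the scheme conserves total nitrogen to
#'   round-off, at the price of admitting small negative excursions.
#' @return Object of class `column_solution`: the final `state`,
#'   elapsed `time` (days), `converged` flag, convergence history
#'   `conv`, per-variable clipped mass (mol N/m^2), depth-integrated
#'   nitrogen `inventory` time series, the equilibrium light/
#'   photoacclimation fields in `env`, and biological rate profiles in
#'   `rates`.
#' @examples
#' \donttest{
#' sol <- integrate_to_equilibrium(grid = column_grid(2000, 20),
#'                                 max_time = 500)
#' }
#' @export
integrate_to_equilibrium <- function(params = ecosystem_params(),
                                     grid = column_grid(),
                                     physics = physics_params(),
                                     state = NULL,
                                     dt = NULL,
                                     tolerance = 1e-4,
                                     max_time = 6000,
                                     check_every = 10,
                                     clip = TRUE) {
  stopifnot(inherits(params, "ecosystem_params"),
            inherits(grid, "column_grid"),
            inherits(physics, "physics_params"))
  if (is.null(state)) state <- column_init(grid)
  stopifnot(nrow(state) == grid$n, ncol(state) == length(state_vars),
            all(is.finite(state)), all(state >= 0))
  if (is.null(dt)) dt <- auto_dt(grid, physics)
  stopifnot(dt > 0)

  Tz <- temperature_profile(grid)
  res <- col_integrate_cpp(
    state0 = unname(state), bio = flatten_bio(params),
    kz_faces_m2d = kz_profile(grid, physics) * 86400,
    gt = temperature_factor(Tz, params),
    gt_nit = temperature_factor(Tz, params, nitrifier = TRUE),
    o2f = o2_factor_profile(params, grid$n),
    dz = grid$dz, w_s = physics$w_s, k_w = physics$k_w,
    k_chl = physics$k_chl, i_max = physics$i_max, diel = physics$diel,
    dt = dt, max_time = max_time, tol = tolerance,
    check_every = check_every, eps_molm3 = 1e-9, clip = clip
  )

  final <- res$state
  colnames(final) <- state_vars
  sol <- structure(
    list(
      state = final, grid = grid, physics = physics, params = params,
      time = res$time, converged = res$converged, dt = res$dt,
      tolerance = tolerance,
      conv = data.frame(time = res$conv_time, metric = res$conv_metric),
      clipped = stats::setNames(res$clipped, state_vars),
      inventory = data.frame(time = res$inventory_time,
                             total_n = res$inventory_total)
    ),
    class = "column_solution"
  )
  sol$env <- solution_environment(sol)
  sol$rates <- solution_rates(sol)
  sol
}

# light, temperature, photoacclimation fields at the final state
solution_environment <- function(sol) {
  lf <- column_light_field(sol$state, sol$grid, sol$physics, sol$params)
  list(I = lf$I, T = temperature_profile(sol$grid), theta = lf$theta,
       chl = chlorophyll_from_state(sol$state[, "p"], lf$theta, sol$params,
                                    floor = TRUE))
}

# biological rate profiles at the final state
solution_rates <- function(sol) {
  lf <- column_light_field(sol$state, sol$grid, sol$physics, sol$params)
  Tz <- temperature_profile(sol$grid)
  d <- biological_tendencies(sol$state, lf$I, Tz, sol$params, fluxes = TRUE)
  attr(d, "rates")
}

#' @export
print.column_solution <- function(x, ...) {
  cat(sprintf("column solution: %d cells x %g m, t = %g d (%s, dt = %.3g d)\n",
              x$grid$n, x$grid$dz, x$time,
              if (x$converged) sprintf("converged, metric %.2e/d", utils::tail(x$conv$metric, 1))
              else "NOT converged", x$dt))
  peak <- function(v) {
    i <- which.max(x$state[, v])
    sprintf("%.1f nmol/L at %g m", mol_m3_to_nmol_l(x$state[i, v]),
            x$grid$z_center[i])
  }
  cat("  peak NH4+:", peak("nh4"), "\n")
  cat("  peak NO2-:", peak("no2"), "\n")
  cat(sprintf("  clipped mass: %.3g mol N/m^2\n", sum(x$clipped)))
  invisible(x)
}

#' Long-format data frame of a column solution
#'
#' One row per depth and variable; concentrations reported in umol/L
#' alongside the model's mol/m^3. Includes the derived chlorophyll,
#' irradiance, and temperature profiles.
#'
#' @param x A `column_solution`.
#' @param ... Unused.
#' @return A data frame with columns `depth_m`, `variable`, `mol_m3`,
#'   `umol_l`.
#' @export
as.data.frame.column_solution <- function(x, ...) {
  n <- x$grid$n
  long <- do.call(rbind, lapply(state_vars, function(v) {
    data.frame(depth_m = x$grid$z_center, variable = v,
               mol_m3 = x$state[, v],
               umol_l = mol_m3_to_umol_l(x$state[, v]))
  }))
  extra <- data.frame(
    depth_m = rep(x$grid$z_center, 3),
    variable = rep(c("chl_mg_m3", "irradiance_uein", "temperature_c"),
                   each = n),
    mol_m3 = NA_real_,
    umol_l = c(x$env$chl, x$env$I, x$env$T)
  )
  rbind(long, extra)
}
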