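#' Depth-resolved microbial loss rate
#'
#' The specific loss rate shared by all four microbial prey
#' populations: maintenance mortality plus grazing pressure,
#' \eqn{L(z) = m_B + g(z) Z(z)}, with the grazing coefficient from
#' [grazing_rate()] evaluated at the (equilibrium) state.
#'
#' @param sol A `column_solution`.
#' @return Loss rate per day at cell centers.
#' @export
loss_rate <- function(sol) {
  S <- mol_m3_to_umol_l(sol$state)
  gt <- temperature_factor(sol$env$T, sol$params)
  g <- grazing_rate(S[, "p"], S[, "b_het"], S[, "b_aoo"], S[, "b_noo"],
                    sol$params, gt)
  sol$params$m_b + g * S[, "z"]
}

#' Subsistence concentration of a chemoautotroph
#'
#' Resource-ratio theory: the concentration at which Monod growth
#' exactly balances loss,
#' \deqn{R^* = \frac{K L}{y V_{max} - L}.}
#' Where the maximum growth rate \eqn{y V_{max}} does not exceed the
#' loss rate the population is unsustainable at any concentration and
#' R* is undefined: those depths are returned as `NA` (masked), never
#' as negative values.
#'
#' @param traits [kinetic_traits()] of the population.
#' @param y Yield on the limiting resource.
#' @param L Loss rate, per day (vectorized).
#' @param gamma_t Optional temperature factor on the maximum growth
#'   rate (default 1; nitrifiers are temperature-exempt by default).
#' @return R* in umol/L, `NA` where undefined.
#' @export
rstar_nitrifier <- function(traits, y, L, gamma_t = 1) {
  stopifnot(inherits(traits, "kinetic_traits"), all(L >= 0))
  mu_max <- y * traits$vmax * gamma_t
  denom <- mu_max - L
  ifelse(denom > 0, traits$k * L / denom, NA_real_)
}

#' Subsistence DIN concentrations of the phytoplankton
#'
#' Uses the maximum light-limited growth rate (the light-saturation
#' curve without nutrient limitation),
#' \deqn{\mu_{light} = \mu_{max}\gamma_T(1 - \exp(-\Gamma\theta /
#'   (\mu_{max}\gamma_T))),}
#' evaluated with the equilibrium photoacclimation state, and returns
#' \eqn{R^* = K L/(\mu_{light} - L)} for each DIN species. Depths where
#' light cannot sustain growth against losses (\eqn{\mu_{light} \le L})
#' are masked `NA`.
#'
#' @param sol A `column_solution`.
#' @param L Loss rate per day; default [loss_rate()] of the solution.
#' @return List of vectors `mu_light`, `nh4`, `no2`, `no3` (umol/L).
#' @export
rstar_phyto <- function(sol, L = loss_rate(sol)) {
  p <- sol$params
  gt <- temperature_factor(sol$env$T, p)
  mu0 <- p$phyto$mu_max * gt
  gamma <- photosynthesis_gamma(sol$env$I, p)
  mu_light <- ifelse(gamma > 0, mu0 * (1 - exp(-gamma * sol$env$theta / mu0)), 0)
  rs <- function(K) ifelse(mu_light > L, K * L / (mu_light - L), NA_real_)
  list(mu_light = mu_light, nh4 = rs(p$phyto$k_nh4p),
       no2 = rs(p$phyto$k_no2p), no3 = rs(p$phyto$k_no3p))
}

#' Depth-resolved subsistence concentrations of all competitors
#'
#' @param sol A `column_solution`.
#' @return Object of class `rstar_profile`: data frame with depth,
#'   loss rate, and R* columns (umol/L) for the ammonia oxidizer
#'   (NH4+), nitrite oxidizer (NO2-), and phytoplankton (each DIN
#'   species); `NA` marks depths where the type cannot subsist.
#' @export
rstar_profile <- function(sol) {
  L <- loss_rate(sol)
  ph <- rstar_phyto(sol, L)
  out <- data.frame(
    depth_m = sol$grid$z_center,
    loss = L,
    aoo_nh4 = rstar_nitrifier(sol$params$aoo$traits, sol$params$aoo$y, L),
    noo_no2 = rstar_nitrifier(sol$params$noo$traits, sol$params$noo$y, L),
    p_nh4 = ph$nh4, p_no2 = ph$no2, p_no3 = ph$no3,
    p_mu_light = ph$mu_light
  )
  class(out) <- c("rstar_profile", "data.frame")
  out
}

# discrete maximum with parabolic sub-cell refinement; ties go shallow
refine_peak <- function(z, y) {
  i <- which.max(y)                      # which.max takes the first (shallowest) tie
  n <- length(y)
  interior <- i > 1 && i < n
  if (interior) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom < 0) {
      off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
      dz <- z[2] - z[1]
      return(list(value = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * off,
                  depth = z[i] + off * dz, interior = TRUE))
    }
  }
  list(value = y[i], depth = z[i], interior = interior)
}

#' Primary-nitrite-maximum metrics of a solution
#'
#' Locates the NO2-, NH4+, chlorophyll (deep chlorophyll maximum), and
#' oxidation-rate maxima by scanning the equilibrium profiles, with
#' parabolic sub-cell refinement of each discrete maximum (ties broken
#' toward the shallower depth). A profile whose maximum sits on the
#' boundary, or that is flat, yields `pnm_present = FALSE`.
#'
#' @param sol A `column_solution`.
#' @param exclude_bottom Depth band above the seafloor excluded from
#'   the peak scans (m, default 100): the bottom boundary layer where
#'   sinking detritus accumulates stands in for the sediment, and its
#'   remineralization maximum is not a water-column feature.
#' @return Object of class `pnm_metrics`: peak concentrations
#'   (nmol/L) and depths (m) for NO2- and NH4+, their ratio
#'   `no2_to_nh4` at the respective peaks, the DCM depth, peak
#'   oxidation rates (nmol/L/d) and depths, and the `pnm_present`
#'   flag (interior, non-flat NO2- maximum).
#' @export
pnm_metrics <- function(sol, exclude_bottom = 100) {
  keep <- sol$grid$z_center <= sol$grid$H - exclude_bottom
  z <- sol$grid$z_center[keep]
  no2 <- mol_m3_to_nmol_l(sol$state[keep, "no2"])
  nh4 <- mol_m3_to_nmol_l(sol$state[keep, "nh4"])
  ox <- oxidation_rate_profiles(sol)[keep, ]
  p_no2 <- refine_peak(z, no2)
  p_nh4 <- refine_peak(z, nh4)
  p_chl <- refine_peak(z, sol$env$chl[keep])
  p_ao <- refine_peak(z, ox$nh4_oxidation)
  p_no <- refine_peak(z, ox$no2_oxidation)
  flat <- diff(range(no2)) <= 1e-12 * max(no2, 1e-12)
  structure(
    list(
      peak_no2 = p_no2$value, no2_depth = p_no2$depth,
      peak_nh4 = p_nh4$value, nh4_depth = p_nh4$depth,
      no2_to_nh4 = p_no2$value / p_nh4$value,
      dcm_depth = p_chl$depth,
      peak_nh4_oxidation = p_ao$value, nh4_oxidation_depth = p_ao$depth,
      peak_no2_oxidation = p_no$value, no2_oxidation_depth = p_no$depth,
      pnm_present = p_no2$interior && !flat
    ),
    class = "pnm_metrics"
  )
}

#' @export
print.pnm_metrics <- function(x, ...) {
  cat(sprintf("PNM %s: peak [NO2-] %.1f nM at %.0f m; peak [NH4+] %.1f nM at %.0f m (NO2:NH4 = %.2f)\n",
              if (x$pnm_present) "present" else "ABSENT",
              x$peak_no2, x$no2_depth, x$peak_nh4, x$nh4_depth, x$no2_to_nh4))
  cat(sprintf("  DCM at %.0f m; peak NH4 oxidation %.2f nM/d at %.0f m\n",
              x$dcm_depth, x$peak_nh4_oxidation, x$nh4_oxidation_depth))
  invisible(x)
}

#' One-row data frame of PNM metrics
#'
#' @param x A `pnm_metrics` object.
#' @param ... Unused.
#' @return One-row data frame, convenient for CSV export.
#' @export
as.data.frame.pnm_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Ammonia- and nitrite-oxidation rate profiles
#'
#' The bulk rates of the two nitrification steps,
#' \eqn{\mu_{AOO} B_{AOO}/y_{NH4}} and \eqn{\mu_{NOO} B_{NOO}/y_{NO2}},
#' reported in nmol N per liter per day.
#'
#' @param sol A `column_solution`.
#' @return Data frame with `depth_m`, `nh4_oxidation`, `no2_oxidation`
#'   (nmol/L/d).
#' @export
oxidation_rate_profiles <- function(sol) {
  r <- sol$rates
  nh4_ox <- r$mu_aoo * sol$state[, "b_aoo"] / sol$params$aoo$y
  no2_ox <- r$mu_noo * sol$state[, "b_noo"] / sol$params$noo$y
  data.frame(depth_m = sol$grid$z_center,
             nh4_oxidation = mol_m3_to_nmol_l(nh4_ox),
             no2_oxidation = mol_m3_to_nmol_l(no2_ox))
}

#' Convert biomass concentration to cell abundance
#'
#' @param biomass Biomass in mol N per m^3.
#' @param quota Nitrogen cell quota, fmol N per cell (> 0).
#' @return Cells per mL.
#' @examples
#' biomass_to_cells(umol_l_to_mol_m3(0.01), quota = 0.12)
#' @export
biomass_to_cells <- function(biomass, quota) {
  stopifnot(quota > 0, all(biomass >= 0))
  biomass / (quota * 1e-9)   # (mol/m^3) / (1e-15 mol/cell) / (1e6 mL/m^3)
}

#' Nitrogen budget audit of a column run
#'
#' Depth-integrated total nitrogen through time, its relative drift,
#' and the reconciliation against the clipped-mass ledger (clipping
#' negative concentrations to zero adds mass; a closed run should
#' show drift equal to the logged clipped mass, and zero when no
#' clipping occurred).
#'
#' @param sol A `column_solution`.
#' @return List with the `inventory` time series (mol N/m^2),
#'   `drift` (absolute, mol N/m^2), `relative_drift_per_year`,
#'   `clipped_total` (mol N/m^2), and `residual` (drift minus clipped
#'   mass — numerical error only).
#' @export
nitrogen_budget <- function(sol) {
  inv <- sol$inventory
  stopifnot(nrow(inv) >= 2)
  drift <- inv$total_n[nrow(inv)] - inv$total_n[1]
  span_years <- (inv$time[nrow(inv)] - inv$time[1]) / 365
  clipped_total <- sum(sol$clipped)
  list(
    inventory = inv,
    drift = drift,
    relative_drift_per_year = drift / inv$total_n[1] / span_years,
    clipped_total = clipped_total,
    residual = drift - clipped_total
  )
}

#' Ammonia oxidation rate from a 15N tracer incubation
#'
#' Isotope-tracer rate computation: the fraction of the nitrite pool
#' that became labelled over the incubation, scaled by the labelling of
#' the spiked ammonium pool and the final nitrite concentration,
#' \deqn{AOR = \frac{a^{NO_2}_f - a^{NO_2}_i}{a^{NH_4}}
#'   [NO_2^-]_f (V \Delta t)^{-1}.}
#' The sample-volume term is part of the published formula and is kept
#' verbatim by default even though it makes the nominal units nM per
#' (L day); set `include_volume = FALSE` for the volume-free variant
#' (nM per day).
#'
#' @param a_no2_i,a_no2_f Atom percent 15N of nitrite at the start and
#'   end of the incubation (0-100).
#' @param a_nh4 Atom percent 15N of the spiked ammonium pool (> 0).
#' @param no2_f Final nitrite concentration, nM.
#' @param v Sample volume, L.
#' @param dt Incubation duration, days (> 0).
#' @param include_volume Keep the `1/V` factor? Default `TRUE`.
#' @return Rate in nM per day (per liter when `include_volume`). A
#'   decrease in labelling returns a negative rate with a warning.
#' @examples
#' tracer_aor(0.37, 0.40, a_nh4 = 50, no2_f = 100)   # 0.06 nM/d
#' @export
tracer_aor <- function(a_no2_i, a_no2_f, a_nh4, no2_f, v = 1, dt = 1,
                       include_volume = TRUE) {
  stopifnot(a_nh4 > 0, dt > 0, v > 0, no2_f >= 0,
            a_no2_i >= 0, a_no2_i <= 100, a_no2_f >= 0, a_no2_f <= 100)
  denom <- if (include_volume) v * dt else dt
  rate <- (a_no2_f - a_no2_i) / a_nh4 * no2_f / denom
  if (rate < 0) warning("final nitrite labelling below initial: negative rate")
  rate
}

#' Zero-dimensional chemostat equilibrium
#'
#' Single population growing on one resource under a fixed specific
#' loss rate and constant resource supply, integrated with RK4 until
#' steady. At steady state growth balances loss, so the ambient
#' resource concentration equals the subsistence concentration
#' \eqn{R^* = K L/(y V_{max} - L)} — an independent dynamical check on
#' the closed-form R*.
#'
#' @param traits [kinetic_traits()].
#' @param y Yield.
#' @param loss Specific loss rate, per day; must be below `y * vmax`.
#' @param supply Resource supply, umol/L per day.
#' @param r0,b0 Initial resource and biomass, umol/L.
#' @param dt Time step (days).
#' @param max_time Maximum integration time (days).
#' @param tol Relative steady-state tolerance on dR/dt.
#' @return List with final `resource` and `biomass` (umol/L), `time`,
#'   and `converged`.
#' @export
chemostat_equilibrium <- function(traits, y, loss, supply = 0.01,
                                  r0 = 1, b0 = 0.01, dt = 0.05,
                                  max_time = 20000, tol = 1e-10) {
  stopifnot(loss > 0, y * traits$vmax > loss)
  f <- function(t, s) {
    mu <- monod_growth(s[1], traits, y)
    c(supply - mu / y * s[2], (mu - loss) * s[2])
  }
  s <- c(r0, b0)
  t <- 0
  converged <- FALSE
  while (t < max_time) {
    s <- rk4_step(f, s, t, dt)
    s <- pmax(s, 0)
    t <- t + dt
    d <- f(t, s)
    if (abs(d[1]) < tol * (s[1] + 1e-12) && abs(d[2]) < tol * (s[2] + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(resource = s[1], biomass = s[2], time = t, converged = converged)
}
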