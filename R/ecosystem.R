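#' Names and order of the nine nitrogen state variables
#'
#' Concentrations are carried internally in mol N per m^3 (1 umol/L =
#' 1e-3 mol/m^3): the three DIN species, organic detritus, and the
#' nitrogen-based biomass of the five microbial functional types
#' (heterotrophic bacteria, ammonia oxidizers, nitrite oxidizers,
#' picophytoplankton, microzooplankton grazer).
#' @export
state_vars <- c("nh4", "no2", "no3", "det", "b_het", "b_aoo", "b_noo", "p", "z")

#' Unit conversions between mol/m^3, umol/L and nmol/L
#'
#' @param x Numeric concentrations.
#' @return Converted concentrations.
#' @name units
NULL

#' @rdname units
#' @export
umol_l_to_mol_m3 <- function(x) x * 1e-3

#' @rdname units
#' @export
mol_m3_to_umol_l <- function(x) x * 1e3

#' @rdname units
#' @export
mol_m3_to_nmol_l <- function(x) x * 1e6

#' Biological parameters of the nine-variable ecosystem model
#'
#' Assembles every biological parameter of the water-column ecosystem.
#' Nitrifier yields come from the whole-organism stoichiometries
#' ([nitrifier_yield()]) and nitrifier kinetics from the culture-derived
#' ammonia-oxidizer traits with allometric scaling for the larger
#' nitrite oxidizer ([build_noo_traits()]). Values printed in primary
#' sources (nitrifier kinetics and yields, y_D = 0.14, g_max = K_g = 1,
#' zeta = 0.5) are used verbatim; the remaining rates are calibrated
#' defaults chosen to reproduce a realistic oligotrophic column (see
#' the package vignette) and are marked `"calibrated"` in
#' `attr(params, "provenance")`. An annotated parameter listing ships
#' at `system.file("extdata", "default_parameters.yaml", package =
#' "nitricline")`.
#'
#' Concentration-like parameters are given in umol N/L; rates per day.
#'
#' @param f Electron fraction to synthesis for both nitrifiers.
#' @param d Biomass electron equivalents.
#' @param aoo_traits [kinetic_traits()] of the ammonia oxidizer.
#' @param noo_volume_factor NOO:AOO cell volume ratio (default 10; a
#'   50-fold ratio has also been suggested for some communities).
#' @param het Heterotroph parameters: `vmax_d` (per day), `k_d`
#'   (umol/L), `y_d` (mol biomass N per mol detritus N).
#' @param phyto Phytoplankton parameters; by default derived from
#'   [phyto_traits_from_volume()] at the 0.6 um Prochlorococcus
#'   diameter, plus light-harvesting constants `phi` (mol C per mol
#'   photons), `a_chl` (m^2 per mg Chl), `theta_max` (g Chl per g C),
#'   and `cn_ratio` (mol C per mol N).
#' @param grazing Grazer parameters: `g_max` (per day), `k_g` (umol/L),
#'   growth efficiency `zeta`, quadratic mortality `m_z`
#'   (per (umol/L) per day).
#' @param m_b Linear mortality of the four microbial prey (per day).
#' @param temperature Arrhenius parameters `tau`, `a_e` (Kelvin; negative
#'   values give rates increasing with temperature), `t0` (Kelvin).
#' @param nitrifier_temperature_exempt If `TRUE` (default) nitrifier
#'   growth is not modified by temperature.
#' @param o2 Optional oxygen limitation hook: list with `enabled`
#'   (default `FALSE`), `k_o2` (umol/L) and `profile` (fixed O2 in
#'   umol/L, scalar or per-depth), applied as a Monod factor on
#'   nitrifier growth when enabled.
#' @return An object of class `ecosystem_params` (nested list).
#' @export
ecosystem_params <- function(
    f = 0.03,
    d = 20,
    aoo_traits = kinetic_traits(vmax = 50.8, k = 133, k_unit = "nmol_l"),
    noo_volume_factor = 10,
    het = list(vmax_d = 0.1 / 0.14, k_d = 0.03, y_d = 0.14),
    phyto = NULL,
    grazing = list(g_max = 1, k_g = 1, zeta = 0.5, m_z = 1),
    m_b = 0.01,
    temperature = list(tau = 0.8, a_e = -4000, t0 = 293.15),
    nitrifier_temperature_exempt = TRUE,
    o2 = list(enabled = FALSE, k_o2 = 1, profile = NULL)) {
  if (is.null(phyto)) {
    allo <- phyto_traits_from_volume(sphere_volume(0.6))
    phyto <- list(
      mu_max = allo$mu_max,
      k_nh4p = allo$k_nh4,
      k_no2p = allo$k_nox,
      k_no3p = allo$k_nox,
      phi = 0.03, a_chl = 0.02, theta_max = 0.25, cn_ratio = 6.6
    )
  }
  p <- structure(
    list(
      aoo = list(traits = aoo_traits,
                 y = nitrifier_yield("ammonia_oxidation", f, d)),
      noo = list(traits = build_noo_traits(aoo_traits, noo_volume_factor),
                 y = nitrifier_yield("nitrite_oxidation", f, d),
                 volume_factor = noo_volume_factor),
      het = het,
      phyto = phyto,
      grazing = grazing,
      m_b = m_b,
      temperature = temperature,
      nitrifier_temperature_exempt = nitrifier_temperature_exempt,
      o2 = o2,
      f = f,
      d = d
    ),
    class = "ecosystem_params"
  )
  attr(p, "provenance") <- c(
    aoo = "culture-derived", noo = "allometric from AOO",
    het = "calibrated (y_d printed)", phyto = "allometric defaults (calibrated)",
    grazing = "printed orders of magnitude", m_b = "calibrated",
    temperature = "calibrated"
  )
  validate_ecosystem_params(p)
}

validate_ecosystem_params <- function(p) {
  stopifnot(inherits(p, "ecosystem_params"))
  with(p, {
    if (aoo$y <= 0 || aoo$y >= 1 || noo$y <= 0 || noo$y >= 1 || het$y_d <= 0 || het$y_d >= 1)
      stop("yields must lie in (0, 1)")
    if (grazing$zeta <= 0 || grazing$zeta >= 1)
      stop("grazer growth efficiency zeta must lie in (0, 1)")
    rates <- c(het$vmax_d, het$k_d, phyto$mu_max, phyto$k_nh4p, phyto$k_no2p,
               phyto$k_no3p, grazing$g_max, grazing$k_g, grazing$m_z, m_b)
    if (any(rates < 0)) stop("rates and half-saturations must be non-negative")
  })
  p
}

#' @export
print.ecosystem_params <- function(x, ...) {
  cat("nine-variable ecosystem parameters\n")
  cat(sprintf("  AOO: Vmax %.3g /d, K %.3g uM, y %.4g (1/%.1f)\n",
              x$aoo$traits$vmax, x$aoo$traits$k, x$aoo$y, 1 / x$aoo$y))
  cat(sprintf("  NOO: Vmax %.3g /d, K %.3g uM, y %.4g (1/%.1f), volume factor %g\n",
              x$noo$traits$vmax, x$noo$traits$k, x$noo$y, 1 / x$noo$y,
              x$noo$volume_factor))
  cat(sprintf("  het: VmaxD %.3g /d, K_D %.3g uM, y_D %.3g\n",
              x$het$vmax_d, x$het$k_d, x$het$y_d))
  cat(sprintf("  phyto: mu_max %.3g /d, K_NH4 %.3g uM, K_NOx %.3g uM, theta_max %.3g\n",
              x$phyto$mu_max, x$phyto$k_nh4p, x$phyto$k_no2p, x$phyto$theta_max))
  cat(sprintf("  grazing: g_max %.3g, K_g %.3g uM, zeta %.3g, m_Z %.3g; m_B %.3g /d\n",
              x$grazing$g_max, x$grazing$k_g, x$grazing$zeta, x$grazing$m_z, x$m_b))
  invisible(x)
}

#' Nitrifier-difference experiments
#'
#' Maps an experiment tag to AOO/NOO parameter overrides used to
#' isolate the yield and affinity differences between the two
#' nitrifier types:
#' \describe{
#'  \item{both_differences}{defaults: NOO has the lower stoichiometric
#'    yield and the allometric affinity penalty.}
#'  \item{yield_only}{NOO gets the AOO uptake traits; yields differ.}
#'  \item{affinity_only}{NOO keeps the allometric traits; its yield is
#'    set to the AOO yield.}
#'  \item{no_difference}{NOO gets AOO traits and AOO yield (identical
#'    subsistence concentrations).}
#' }
#'
#' @param params An [ecosystem_params()] object.
#' @param experiment One of the four tags.
#' @return Modified parameter set, with the tag stored in
#'   `params$experiment`.
#' @export
apply_experiment <- function(params,
                             experiment = c("both_differences", "yield_only",
                                            "affinity_only", "no_difference")) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(params, "ecosystem_params"))
  if (experiment %in% c("yield_only", "no_difference")) {
    params$noo$traits <- params$aoo$traits
    params$noo$volume_factor <- 1
  }
  if (experiment %in% c("affinity_only", "no_difference")) {
    params$noo$y <- params$aoo$y
  }
  params$experiment <- experiment
  params
}

#' Arrhenius temperature modification of biological rates
#'
#' \deqn{\gamma_T = \tau \exp\left(A_E\left(\frac{1}{T + 273.15} -
#'   \frac{1}{T_0}\right)\right)}
#' with `T` in degrees Celsius and `T_0` in Kelvin. With the
#' conventional negative `A_E`, rates increase with temperature and
#' `tau` normalizes the warm-end maximum. Nitrifier rates are exempt
#' when `params$nitrifier_temperature_exempt` is set, in which case
#' `temperature_factor(T, params, nitrifier = TRUE)` returns 1.
#'
#' @param T Temperature in degrees C (vectorized).
#' @param params An [ecosystem_params()] object (or a list with a
#'   `temperature` block).
#' @param nitrifier Is the consumer one of the nitrifying types?
#' @return Dimensionless factor, same length as `T`.
#' @export
temperature_factor <- function(T, params, nitrifier = FALSE) {
  stopifnot(all(T > -273.15))
  if (nitrifier && isTRUE(params$nitrifier_temperature_exempt)) {
    return(rep(1, length(T)))
  }
  tp <- params$temperature
  tp$tau * exp(tp$a_e * (1 / (T + 273.15) - 1 / tp$t0))
}

#' Monod growth rate on a single limiting resource
#'
#' \eqn{\mu = y V_{max} R / (R + K)}. When several resources may limit,
#' pass each concentration and the minimum is taken (Liebig's law):
#' supply `R` as a list of concentration vectors with `traits`/`y` as
#' parallel lists.
#'
#' @param R Resource concentration(s); unit set by `r_unit`.
#' @param traits [kinetic_traits()] (half-saturation in umol/L).
#' @param y Yield, mol biomass N per mol resource.
#' @param r_unit Unit of `R`: `"umol_l"` (default), `"nmol_l"`, or
#'   `"mol_m3"`.
#' @return Growth rate in per day.
#' @examples
#' aoa <- kinetic_traits(50.8, 133, "nmol_l")
#' monod_growth(133, aoa, 1 / 112.1, r_unit = "nmol_l")  # half of y*Vmax
#' @export
monod_growth <- function(R, traits, y, r_unit = c("umol_l", "nmol_l", "mol_m3")) {
  r_unit <- match.arg(r_unit)
  if (is.list(R)) {
    mus <- mapply(function(r, tr, yy) monod_growth(r, tr, yy, r_unit = r_unit),
                  R, traits, y, SIMPLIFY = FALSE)
    return(Reduce(pmin, mus))
  }
  stopifnot(inherits(traits, "kinetic_traits"), all(R >= 0))
  R_um <- switch(r_unit, umol_l = R, nmol_l = R / 1000, mol_m3 = R * 1e3)
  y * traits$vmax * R_um / (R_um + traits$k)
}

#' Phytoplankton nutrient limitation term
#'
#' Sum of the three DIN Monod saturation terms. The sum is used exactly
#' as defined and can exceed 1 when all pools are replete; the uptake
#' partition divides by the same sum, so total uptake remains mu_P.
#'
#' @param nh4,no2,no3 Concentrations in umol/L (vectorized).
#' @param params [ecosystem_params()].
#' @return Dimensionless gamma_N >= 0.
#' @export
gamma_n <- function(nh4, no2, no3, params) {
  ph <- params$phyto
  nh4 / (nh4 + ph$k_nh4p) + no2 / (no2 + ph$k_no2p) + no3 / (no3 + ph$k_no3p)
}

# Photosynthetic rate scale: Gamma (per day, per unit theta) from
# irradiance in uEin m^-2 s^-1. phi [mol C / mol photons] * a_chl
# [m^2/mg Chl] * I [mol photons m^-2 d^-1] * 12000 [mg C / mol C]
# = mg C (mg Chl)^-1 d^-1; times theta [g Chl / g C] gives d^-1.
photosynthesis_gamma <- function(I, params) {
  ph <- params$phyto
  ph$phi * ph$a_chl * (I * 86400 / 1e6) * 12000
}

#' Light- and nutrient-limited phytoplankton growth
#'
#' Photoacclimation model: the chlorophyll-to-carbon ratio takes its
#' balanced-growth value
#' \deqn{\theta = \theta_{max} / (1 + \Gamma \theta_{max} /
#'   (2 \mu_{max}\gamma_N\gamma_T)),}
#' and growth saturates exponentially with the absorbed light
#' \deqn{\mu_P = \mu_{max}\gamma_N\gamma_T (1 -
#'   \exp(-\Gamma\theta/(\mu_{max}\gamma_N\gamma_T))),}
#' where \eqn{\Gamma = \phi a_{chl} I} is the photosynthetic rate
#' scale. \eqn{\mu_P = 0} when there is no light or no nutrient. The
#' returned `theta` is the dynamical (un-floored) value; the reporting
#' floor of `0.1 * theta_max` is applied in [chlorophyll_from_state()]
#' only.
#'
#' @param I Irradiance, uEin m^-2 s^-1 (vectorized).
#' @param T Temperature, degrees C.
#' @param nh4,no2,no3 DIN concentrations, umol/L.
#' @param params [ecosystem_params()].
#' @return List of vectors: `mu_p` (per day), `theta` (g Chl / g C),
#'   `gamma_n`, `gamma` (the light scale, per day per unit theta).
#' @export
phyto_growth <- function(I, T, nh4, no2, no3, params) {
  gn <- gamma_n(nh4, no2, no3, params)
  gt <- temperature_factor(T, params)
  gamma <- photosynthesis_gamma(I, params)
  mu_cap <- params$phyto$mu_max * gn * gt
  theta_max <- params$phyto$theta_max
  theta <- ifelse(mu_cap > 0,
                  theta_max / (1 + gamma * theta_max / (2 * mu_cap)),
                  theta_max)
  mu_p <- ifelse(mu_cap > 0 & gamma > 0,
                 mu_cap * (1 - exp(-gamma * theta / mu_cap)),
                 0)
  list(mu_p = mu_p, theta = theta, gamma_n = gn, gamma = gamma)
}

#' Partition phytoplankton growth among the three DIN species
#'
#' Total uptake mu_P is apportioned proportionally to each species'
#' Monod saturation term divided by their sum, so the three specific
#' uptake rates add up to mu_P exactly; all are zero when no DIN is
#' present.
#'
#' @param mu_p Phytoplankton growth rate (per day).
#' @param nh4,no2,no3 DIN concentrations, umol/L.
#' @param params [ecosystem_params()].
#' @return List of vectors `v_nh4`, `v_no2`, `v_no3` (per day).
#' @export
din_uptake_rates <- function(mu_p, nh4, no2, no3, params) {
  ph <- params$phyto
  t1 <- nh4 / (nh4 + ph$k_nh4p)
  t2 <- no2 / (no2 + ph$k_no2p)
  t3 <- no3 / (no3 + ph$k_no3p)
  s <- t1 + t2 + t3
  safe <- ifelse(s > 0, s, 1)
  list(v_nh4 = ifelse(s > 0, mu_p * t1 / safe, 0),
       v_no2 = ifelse(s > 0, mu_p * t2 / safe, 0),
       v_no3 = ifelse(s > 0, mu_p * t3 / safe, 0))
}

#' Heterotrophic bacterial growth on detritus
#'
#' \eqn{\mu_{het} = y_D V_{maxD} D/(D + K_D)\,\gamma_T}. The default
#' parameters give a saturated growth rate of about 0.1 per day, the
#' average bulk marine bacterial growth rate.
#'
#' @param det Detritus concentration, umol N/L.
#' @param params [ecosystem_params()].
#' @param gamma_t Temperature factor (default 1).
#' @return Growth rate per day.
#' @export
het_growth <- function(det, params, gamma_t = 1) {
  stopifnot(all(det >= 0))
  h <- params$het
  h$y_d * h$vmax_d * det / (det + h$k_d) * gamma_t
}

#' Grazing rate coefficient
#'
#' Saturating function of total microbial prey biomass,
#' \eqn{g = g_{max}\gamma_T / (P + B_{het} + B_{AOO} + B_{NOO} + K_g)}.
#' The grazing flux on prey i is `g * Z * B_i`, so `g` has units of
#' per (umol N/L) per day; the grazer's specific loss-rate contribution
#' is `g * Z` (per day, identical for all prey).
#'
#' @param p,b_het,b_aoo,b_noo Prey biomasses, umol N/L.
#' @param params [ecosystem_params()].
#' @param gamma_t Temperature factor (default 1).
#' @return Rate coefficient `g`, per (umol N/L) per day.
#' @export
grazing_rate <- function(p, b_het, b_aoo, b_noo, params, gamma_t = 1) {
  gr <- params$grazing
  gr$g_max * gamma_t / (p + b_het + b_aoo + b_noo + gr$k_g)
}

# ---- flux ledger ------------------------------------------------------------

# Every biological transfer appears once here, as from -> to. Tendencies
# are assembled from the signed incidence matrix, so local nitrogen
# conservation holds by construction.
flux_topology <- function() {
  data.frame(
    flux = c("aoo_growth", "aoo_no2_production", "noo_assimilation",
             "noo_oxidation", "p_uptake_nh4", "p_uptake_no2", "p_uptake_no3",
             "het_growth", "het_remineralization",
             "graze_assim_p", "graze_assim_het", "graze_assim_aoo", "graze_assim_noo",
             "graze_excrete_p", "graze_excrete_het", "graze_excrete_aoo", "graze_excrete_noo",
             "mortality_p", "mortality_het", "mortality_aoo", "mortality_noo",
             "z_mortality"),
    from = c("nh4", "nh4", "nh4",
             "no2", "nh4", "no2", "no3",
             "det", "det",
             "p", "b_het", "b_aoo", "b_noo",
             "p", "b_het", "b_aoo", "b_noo",
             "p", "b_het", "b_aoo", "b_noo",
             "z"),
    to = c("b_aoo", "no2", "b_noo",
           "no3", "p", "p", "p",
           "b_het", "nh4",
           "z", "z", "z", "z",
           "nh4", "nh4", "nh4", "nh4",
           "det", "det", "det", "det",
           "det"),
    stringsAsFactors = FALSE
  )
}

flux_incidence <- function() {
  topo <- flux_topology()
  M <- matrix(0, nrow(topo), length(state_vars),
              dimnames = list(topo$flux, state_vars))
  for (i in seq_len(nrow(topo))) {
    M[i, topo$from[i]] <- -1
    M[i, topo$to[i]] <- 1
  }
  M
}

# Flux magnitudes (umol N / L / d), rows = depths, columns = fluxes.
biological_fluxes <- function(S, I, T, params) {
  # S: matrix n x 9 in umol/L
  nh4 <- S[, "nh4"]; no2 <- S[, "no2"]; no3 <- S[, "no3"]; det <- S[, "det"]
  b_het <- S[, "b_het"]; b_aoo <- S[, "b_aoo"]; b_noo <- S[, "b_noo"]
  p <- S[, "p"]; z <- S[, "z"]

  gt <- temperature_factor(T, params)
  gt_nit <- temperature_factor(T, params, nitrifier = TRUE)

  o2f <- 1
  if (isTRUE(params$o2$enabled)) {
    o2 <- params$o2$profile
    if (is.null(o2)) stop("o2 limitation enabled but no profile supplied")
    o2f <- o2 / (o2 + params$o2$k_o2)
  }

  mu_aoo <- monod_growth(nh4, params$aoo$traits, params$aoo$y) * gt_nit * o2f
  mu_noo <- monod_growth(no2, params$noo$traits, params$noo$y) * gt_nit * o2f
  mu_het <- het_growth(det, params, gt)
  pg <- phyto_growth(I, T, nh4, no2, no3, params)
  up <- din_uptake_rates(pg$mu_p, nh4, no2, no3, params)
  g <- grazing_rate(p, b_het, b_aoo, b_noo, params, gt)
  zeta <- params$grazing$zeta
  m_b <- params$m_b
  m_z <- params$grazing$m_z * gt

  F <- cbind(
    aoo_growth = mu_aoo * b_aoo,
    aoo_no2_production = (1 / params$aoo$y - 1) * mu_aoo * b_aoo,
    noo_assimilation = mu_noo * b_noo,
    noo_oxidation = mu_noo * b_noo / params$noo$y,
    p_uptake_nh4 = up$v_nh4 * p,
    p_uptake_no2 = up$v_no2 * p,
    p_uptake_no3 = up$v_no3 * p,
    het_growth = mu_het * b_het,
    het_remineralization = (1 / params$het$y_d - 1) * mu_het * b_het,
    graze_assim_p = zeta * g * z * p,
    graze_assim_het = zeta * g * z * b_het,
    graze_assim_aoo = zeta * g * z * b_aoo,
    graze_assim_noo = zeta * g * z * b_noo,
    graze_excrete_p = (1 - zeta) * g * z * p,
    graze_excrete_het = (1 - zeta) * g * z * b_het,
    graze_excrete_aoo = (1 - zeta) * g * z * b_aoo,
    graze_excrete_noo = (1 - zeta) * g * z * b_noo,
    mortality_p = m_b * p,
    mortality_het = m_b * b_het,
    mortality_aoo = m_b * b_aoo,
    mortality_noo = m_b * b_noo,
    z_mortality = m_z * z^2
  )
  attr(F, "rates") <- list(mu_aoo = mu_aoo, mu_noo = mu_noo, mu_het = mu_het,
                           mu_p = pg$mu_p, theta = pg$theta,
                           gamma_n = pg$gamma_n, g = g, uptake = up)
  F
}

#' Local biological tendencies of the nine state variables
#'
#' Computes every biological source and sink term of the ecosystem
#' equations (transport and sinking are handled by the column
#' operators). Internally each nitrogen transfer is a single entry in
#' a flux ledger mapped to the state variables through a signed
#' incidence matrix, so the nine tendencies sum to zero at machine
#' precision for any state: total nitrogen is locally conserved.
#'
#' @param state Numeric vector of length 9 (named or in [state_vars]
#'   order) or a matrix with one row per depth and 9 columns, in
#'   mol N per m^3.
#' @param I Irradiance, uEin m^-2 s^-1 (scalar or per-depth).
#' @param T Temperature, degrees C (scalar or per-depth).
#' @param params [ecosystem_params()].
#' @param fluxes If `TRUE`, attach the flux ledger (matrix, umol/L/d)
#'   and growth-rate diagnostics as attributes `"fluxes"` and
#'   `"rates"`.
#' @return Tendencies d(state)/dt in mol N m^-3 per day, same shape as
#'   `state`.
#' @export
biological_tendencies <- function(state, I, T, params, fluxes = FALSE) {
  vec_in <- is.null(dim(state))
  S <- if (vec_in) matrix(state, nrow = 1, dimnames = list(NULL, state_vars)) else state
  if (is.null(colnames(S))) colnames(S) <- state_vars
  S <- S[, state_vars, drop = FALSE]
  if (any(S < 0)) stop("negative state component: integrator fault upstream")
  S_um <- mol_m3_to_umol_l(S)
  F <- biological_fluxes(S_um, I, T, params)
  dS_um <- F %*% flux_incidence()
  out <- umol_l_to_mol_m3(dS_um)
  if (vec_in) {
    res <- drop(out)
    names(res) <- state_vars
  } else {
    res <- out
  }
  if (fluxes) {
    attr(res, "fluxes") <- F
    attr(res, "rates") <- attr(F, "rates")
  }
  res
}
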