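pars <- ecosystem_params()

test_that("temperature factor follows the Arrhenius form with nitrifier exemption", {
  tp <- pars$temperature
  expect_equal(temperature_factor(tp$t0 - 273.15, pars), tp$tau)
  p0 <- pars; p0$temperature$a_e <- 0
  expect_equal(temperature_factor(c(-1, 10, 25), p0), rep(tp$tau, 3))
  # negative a_e (the conventional sign): rates increase with temperature
  Ts <- seq(0, 30, by = 2)
  expect_true(all(diff(temperature_factor(Ts, pars)) > 0))
  expect_equal(temperature_factor(Ts, pars, nitrifier = TRUE), rep(1, length(Ts)))
  pn <- pars; pn$nitrifier_temperature_exempt <- FALSE
  expect_equal(temperature_factor(Ts, pn, nitrifier = TRUE),
               temperature_factor(Ts, pn))
})

test_that("Monod growth saturates and respects Liebig's minimum", {
  aoa <- kinetic_traits(50.8, 133, "nmol_l")
  y <- 1 / 112.1
  expect_equal(monod_growth(133, aoa, y, r_unit = "nmol_l"), y * 50.8 / 2)
  expect_equal(round(monod_growth(133, aoa, y, r_unit = "nmol_l"), 3), 0.227)
  expect_equal(monod_growth(1e9, aoa, y), y * 50.8, tolerance = 1e-6)
  expect_equal(monod_growth(umol_l_to_mol_m3(0.133), aoa, y, r_unit = "mol_m3"),
               y * 50.8 / 2)
  # two potentially limiting resources: the scarcer one sets the rate
  o2_traits <- kinetic_traits(50.8, 1)
  mu <- monod_growth(list(0.133, 1e-4), list(aoa, o2_traits), list(y, y))
  expect_equal(mu, monod_growth(1e-4, o2_traits, y))
})

test_that("the DIN limitation sum behaves as a sum of saturations", {
  expect_equal(gamma_n(0, 0, 0, pars), 0)
  expect_equal(gamma_n(pars$phyto$k_nh4p, 0, 0, pars), 0.5)
  expect_equal(gamma_n(pars$phyto$k_nh4p, pars$phyto$k_no2p,
                       pars$phyto$k_no3p, pars), 1.5)
})

test_that("phytoplankton growth handles dark, saturated, and linear light", {
  g <- phyto_growth(I = 0, T = 20, nh4 = 1, no2 = 1, no3 = 1, pars)
  expect_equal(g$mu_p, 0)
  cap <- pars$phyto$mu_max * g$gamma_n * temperature_factor(20, pars)
  # photoacclimation pins absorbed light at twice the capacity under
  # saturating irradiance, so growth tends to cap*(1 - exp(-2))
  sat <- phyto_growth(I = 5000, T = 20, nh4 = 1, no2 = 1, no3 = 1, pars)
  expect_equal(sat$mu_p, cap * (1 - exp(-2)), tolerance = 5e-3)
  expect_lt(sat$mu_p, cap)
  # with theta held fixed, the growth law itself saturates at cap
  th <- sat$theta
  expect_equal(cap * (1 - exp(-1e6 * th / cap)), cap)
  dim_l <- phyto_growth(I = 0.05, T = 20, nh4 = 1, no2 = 1, no3 = 1, pars)
  expect_equal(dim_l$mu_p, dim_l$gamma * dim_l$theta, tolerance = 0.02)
  none <- phyto_growth(I = 100, T = 20, nh4 = 0, no2 = 0, no3 = 0, pars)
  expect_equal(none$mu_p, 0)
})

test_that("DIN uptake partition sums to the growth rate", {
  only_nh4 <- din_uptake_rates(0.4, nh4 = 0.5, no2 = 0, no3 = 0, pars)
  expect_equal(only_nh4$v_nh4, 0.4)
  expect_equal(only_nh4$v_no2 + only_nh4$v_no3, 0)
  sym <- din_uptake_rates(0.4, nh4 = pars$phyto$k_nh4p, no2 = 0,
                          no3 = pars$phyto$k_no3p, pars)
  expect_equal(sym$v_nh4, sym$v_no3)
  set.seed(1)
  for (i in 1:20) {
    x <- runif(3, 0, 2)
    up <- din_uptake_rates(0.7, x[1], x[2], x[3], pars)
    expect_equal(up$v_nh4 + up$v_no2 + up$v_no3, 0.7)
  }
  zero <- din_uptake_rates(0.7, 0, 0, 0, pars)
  expect_equal(unlist(zero), c(v_nh4 = 0, v_no2 = 0, v_no3 = 0))
})

test_that("heterotroph growth saturates near the bulk marine rate", {
  h <- pars$het
  expect_equal(het_growth(h$k_d, pars), h$y_d * h$vmax_d / 2)
  expect_equal(het_growth(0, pars), 0)
  expect_equal(h$y_d * h$vmax_d, 0.1, tolerance = 1e-8)
})

test_that("grazing saturates with total prey and fluxes scale with Z", {
  gr <- pars$grazing
  g <- grazing_rate(gr$k_g, 0, 0, 0, pars, gamma_t = 1)
  expect_equal(g, gr$g_max / (2 * gr$k_g))
  expect_equal(grazing_rate(0, 0, 0, 0, pars, 1), gr$g_max / gr$k_g)
  # flux is linear in Z at fixed prey
  expect_equal(2 * g * 0.05 * 0.1, g * (2 * 0.05) * 0.1)
})

test_that("biological tendencies conserve nitrogen for random states", {
  set.seed(99)
  S <- matrix(runif(1000 * 9, 0, 2e-3), ncol = 9,
              dimnames = list(NULL, state_vars))
  dS <- biological_tendencies(S, I = 100, T = 15, pars)
  expect_lt(max(abs(rowSums(dS))), 1e-16)
  expect_true(all(is.finite(dS)))
})

test_that("nutrients are inert without organisms", {
  s <- setNames(rep(0, 9), state_vars)
  s[c("nh4", "no2", "no3", "det")] <- umol_l_to_mol_m3(c(0.5, 0.3, 20, 1))
  dS <- biological_tendencies(s, I = 200, T = 25, pars)
  expect_equal(unname(dS), rep(0, 9))
})

test_that("negative states are rejected as integrator faults", {
  s <- setNames(rep(1e-4, 9), state_vars)
  s["no2"] <- -1e-6
  expect_error(biological_tendencies(s, 100, 15, pars), "negative state")
})

test_that("each ledger flux moves mass between exactly two pools", {
  M <- nitricline:::flux_incidence()
  expect_true(all(rowSums(M) == 0))
  expect_true(all(rowSums(abs(M)) == 2))
  # and the assembled tendencies equal the ledger-projected fluxes
  s <- setNames(umol_l_to_mol_m3(rep(0.1, 9)), state_vars)
  dS <- biological_tendencies(s, I = 50, T = 18, pars, fluxes = TRUE)
  F <- attr(dS, "fluxes")
  expect_true(all(F >= 0))
  expect_equal(unname(umol_l_to_mol_m3(drop(F %*% M))), as.vector(dS))
})

test_that("tendencies match an independent term-by-term tally", {
  s_um <- list(nh4 = 0.1, no2 = 0.1, no3 = 0.1, det = 0.1, b_het = 0.1,
               b_aoo = 0.1, b_noo = 0.1, p = 0.1, z = 0.1)
  want <- oracle_tendencies(s_um, I = 80, Tc = 18, pars)
  got <- biological_tendencies(umol_l_to_mol_m3(unlist(s_um)), 80, 18, pars)
  expect_equal(mol_m3_to_umol_l(unname(got)), unname(unlist(want)),
               tolerance = 1e-12)
  # a second, asymmetric state
  s2 <- list(nh4 = 0.01, no2 = 0.25, no3 = 15, det = 0.05, b_het = 0.02,
             b_aoo = 0.08, b_noo = 0.03, p = 0.2, z = 0.04)
  want2 <- oracle_tendencies(s2, I = 5, Tc = 8, pars)
  got2 <- biological_tendencies(umol_l_to_mol_m3(unlist(s2)), 5, 8, pars)
  expect_equal(mol_m3_to_umol_l(unname(got2)), unname(unlist(want2)),
               tolerance = 1e-12)
})

test_that("identical nitrifiers differ only by the NOO assimilation term", {
  twin <- apply_experiment(pars, "no_difference")
  s <- setNames(umol_l_to_mol_m3(c(0.1, 0.1, 1, 0.2, 0.05, 0.07, 0.07, 0.1, 0.03)),
                state_vars)
  dS <- biological_tendencies(s, I = 20, T = 12, twin, fluxes = TRUE)
  r <- attr(dS, "rates")
  # same traits, same yields, equal biomass and equal substrate: identical growth
  expect_equal(unname(r$mu_aoo), unname(r$mu_noo))
  expect_equal(unname(dS["b_aoo"]), unname(dS["b_noo"]))
})

test_that("experiments override the nitrite oxidizer as labelled", {
  y_only <- apply_experiment(pars, "yield_only")
  expect_equal(y_only$noo$traits, pars$aoo$traits)
  expect_equal(y_only$noo$y, pars$noo$y)
  a_only <- apply_experiment(pars, "affinity_only")
  expect_equal(a_only$noo$traits, pars$noo$traits)
  expect_equal(a_only$noo$y, pars$aoo$y)
  none <- apply_experiment(pars, "no_difference")
  expect_equal(none$noo$traits, pars$aoo$traits)
  expect_equal(none$noo$y, pars$aoo$y)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(ecosystem_params(het = list(vmax_d = 0.7, k_d = 0.1, y_d = 1.4)),
               "yields")
  expect_error(ecosystem_params(grazing = list(g_max = 1, k_g = 1, zeta = 0,
                                               m_z = 1)), "zeta")
  expect_error(ecosystem_params(m_b = -0.1))
})
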