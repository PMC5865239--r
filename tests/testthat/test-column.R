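grid <- column_grid(2000, 10)
phys <- physics_params()

test_that("the grid places faces and centers consistently", {
  expect_equal(grid$n, 200)
  expect_equal(grid$z_face[1], 0)
  expect_equal(grid$z_face[grid$n + 1], grid$H)
  expect_equal(grid$z_center, (grid$z_face[-1] + grid$z_face[-(grid$n + 1)]) / 2)
  expect_error(column_grid(2000, 3.3), "integer multiple")
})

test_that("the diffusivity profile has mixed layer, interior, and bottom layer", {
  kz <- kz_profile(grid, phys)
  expect_equal(kz[1], phys$k_max + phys$k_min, tolerance = 1e-6)
  expect_equal(kz[grid$n + 1], phys$k_max + phys$k_min, tolerance = 1e-6)
  mid <- kz[grid$z_face > 500 & grid$z_face < 900]
  expect_true(all(mid < phys$k_min * 1.05))
  expect_true(all(kz >= phys$k_min))
})

test_that("the temperature profile spans 26 to 2 degrees, decreasing", {
  expect_equal(temperature_profile(0), 26)
  expect_equal(temperature_profile(1e6), 2, tolerance = 1e-6)
  Tz <- temperature_profile(grid)
  expect_true(all(diff(Tz) < 0))
  expect_lt(temperature_profile(150), temperature_profile(0))
})

test_that("light attenuates with water and chlorophyll and averages the diel cycle", {
  I0 <- light_profile(grid, chl = 0, phys)
  expect_equal(I0, 0.5 * phys$i_max * exp(-phys$k_w * grid$z_center))
  set.seed(3)
  chl <- abs(rnorm(grid$n, 0.1, 0.1))
  I1 <- light_profile(grid, chl, phys)
  expect_true(all(diff(I1) <= 0))
  expect_true(all(I1 <= I0))
  diel <- phys; diel$diel <- TRUE
  ts <- seq(0, 1, length.out = 2001)[-2001]
  surface <- vapply(ts, function(t) light_profile(grid, 0, diel, t)[1], numeric(1))
  expect_equal(mean(surface), I0[1], tolerance = 1e-6)
})

test_that("chlorophyll conversion is linear with a reporting floor", {
  p <- ecosystem_params()
  expect_equal(chlorophyll_from_state(0, 0.2, p), 0)
  expect_equal(chlorophyll_from_state(2e-5, 0.2, p),
               2 * chlorophyll_from_state(1e-5, 0.2, p))
  th_floor <- 0.01 * p$phyto$theta_max
  expect_equal(chlorophyll_from_state(1e-5, th_floor, p),
               1e-5 * p$phyto$cn_ratio * 12 * 0.1 * p$phyto$theta_max * 1000)
  expect_gt(chlorophyll_from_state(1e-5, th_floor, p),
            chlorophyll_from_state(1e-5, th_floor, p, floor = FALSE))
})

test_that("diffusion conserves mass and vanishes on uniform profiles", {
  kz <- kz_profile(grid, phys) * 86400
  expect_equal(diffusion_tendency(rep(3, grid$n), kz, grid), rep(0, grid$n))
  set.seed(5)
  prof <- runif(grid$n)
  td <- diffusion_tendency(prof, kz, grid)
  expect_lt(abs(sum(td) * grid$dz), 1e-10 * sum(abs(td)) * grid$dz + 1e-14)
  # linear profile with constant K: interior tendency zero, boundary
  # cells feel the no-flux walls
  kz_const <- rep(10, grid$n + 1)
  lin <- 1 + 0.01 * grid$z_center
  tl <- diffusion_tendency(lin, kz_const, grid)
  expect_equal(tl[2:(grid$n - 1)], rep(0, grid$n - 2))
  # hand discretization of the two boundary cells: the downward
  # gradient mixes mass upward, so the top cell gains and the bottom loses
  expect_equal(tl[1], 10 * 0.01 / grid$dz)
  expect_equal(tl[grid$n], -10 * 0.01 / grid$dz)
})

test_that("QUICK sinking conserves mass and is divergence-free on uniform fields", {
  det <- rep(2, grid$n)
  ts <- sinking_tendency(det, 10, grid)
  expect_equal(ts[3:(grid$n - 1)], rep(0, grid$n - 3))
  expect_equal(sum(ts) * grid$dz, 0)
  set.seed(6)
  det2 <- runif(grid$n)
  expect_lt(abs(sum(sinking_tendency(det2, 10, grid)) * grid$dz), 1e-12)
})

test_that("QUICK diffuses a sinking pulse less than first-order upwind", {
  g <- column_grid(1000, 5)
  z <- g$z_center
  pulse <- exp(-((z - 200) / 30)^2)
  w <- 10
  dt <- 0.01
  advect <- function(scheme) {
    y <- pulse
    for (i in seq_len(2000)) {   # 20 days, 200 m of travel
      y <- rk4_step(function(t, x) scheme(x, w, g), y, 0, dt)
    }
    y
  }
  q <- advect(sinking_tendency)
  u <- advect(oracle_upwind_sinking)
  moments <- function(y) {
    m0 <- sum(y); mu <- sum(z * y) / m0
    c(mu = mu, var = sum((z - mu)^2 * y) / m0)
  }
  mq <- moments(q); mu_ <- moments(u); m0 <- moments(pulse)
  # both displace the pulse by ~w*t within discretization error
  expect_equal(unname(mq["mu"]), 400, tolerance = 0.02)
  expect_equal(unname(mu_["mu"]), 400, tolerance = 0.05)
  # upwind spreads the pulse far more than QUICK
  expect_lt(mq["var"] - m0["var"], 0.2 * (mu_["var"] - m0["var"]))
  # and the two solutions agree to within the upwind discretization error
  expect_lt(max(abs(q - u)), 0.5 * max(pulse))
})

test_that("the RK4 stepper is fourth-order on exponential decay", {
  f <- function(t, y) -y
  errs <- vapply(c(0.4, 0.2, 0.1, 0.05), function(dt) {
    y <- 1
    for (i in seq_len(round(2 / dt))) y <- rk4_step(f, y, 0, dt)
    abs(y - exp(-2))
  }, numeric(1))
  slopes <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(slopes > 3.7 & slopes < 4.3))
  # small-step limit reduces to forward Euler to O(dt^2)
  dt <- 1e-4
  expect_equal(rk4_step(f, 1, 0, dt), 1 - dt, tolerance = 1e-8)
})

test_that("the automatic step respects both stability bounds", {
  dt <- auto_dt(grid, phys)
  kz_m2d <- max(kz_profile(grid, phys)) * 86400
  expect_lte(dt, 0.5 * grid$dz^2 / (2 * kz_m2d) + 1e-12)
  expect_lte(dt, 0.5 * grid$dz / phys$w_s + 1e-12)
  expect_lte(dt, 0.01)
})

test_that("compiled and reference right-hand sides agree", {
  g <- column_grid(2000, 50)
  pars <- ecosystem_params()
  S <- random_state(g, seed = 11)
  want <- column_rhs(S, g, phys, pars)
  got <- nitricline:::col_rhs_cpp(
    unname(S), nitricline:::flatten_bio(pars),
    kz_profile(g, phys) * 86400,
    temperature_factor(temperature_profile(g), pars),
    temperature_factor(temperature_profile(g), pars, nitrifier = TRUE),
    rep(1, g$n), g$dz, phys$w_s, phys$k_w, phys$k_chl, phys$i_max,
    FALSE, 0)
  expect_equal(unname(want), got, tolerance = 1e-12)
})

test_that("an abiotic column with uniform nutrients stays put and converges", {
  g <- column_grid(2000, 50)
  S <- matrix(0, g$n, 9, dimnames = list(NULL, state_vars))
  S[, "no3"] <- umol_l_to_mol_m3(15)
  S[, "nh4"] <- umol_l_to_mol_m3(0.2)
  sol <- integrate_to_equilibrium(state = S, grid = g, max_time = 100,
                                  check_every = 5, tolerance = 1e-6)
  expect_true(sol$converged)
  expect_lt(sol$time, 100)
  expect_equal(sol$state, S, tolerance = 1e-12)
  expect_equal(sum(sol$clipped), 0)
})

test_that("diel forcing integrates stably with daily-average convergence", {
  g <- column_grid(2000, 100)
  phys <- physics_params(diel = TRUE)
  sol <- integrate_to_equilibrium(grid = g, physics = phys, max_time = 40,
                                  tolerance = 0, check_every = 10)
  expect_true(all(is.finite(sol$state)))
  expect_equal(sol$time, 40)
  expect_gte(nrow(sol$conv), 2)
  # daylight drives some phytoplankton growth despite the dark half-cycle
  expect_gt(max(sol$state[, "p"]), umol_l_to_mol_m3(1e-3))
})

test_that("the oxygen limitation hook throttles nitrifier growth when enabled", {
  pars <- ecosystem_params(o2 = list(enabled = TRUE, k_o2 = 1, profile = 0.5))
  s <- setNames(umol_l_to_mol_m3(rep(0.1, 9)), state_vars)
  d_on <- biological_tendencies(s, I = 0, T = 10, pars, fluxes = TRUE)
  d_off <- biological_tendencies(s, I = 0, T = 10, ecosystem_params(),
                                 fluxes = TRUE)
  r_on <- attr(d_on, "rates")
  r_off <- attr(d_off, "rates")
  # Monod factor 0.5/(0.5+1) = 1/3 on both oxidation steps
  expect_equal(unname(r_on$mu_aoo), unname(r_off$mu_aoo) / 3)
  expect_equal(unname(r_on$mu_noo), unname(r_off$mu_noo) / 3)
  # heterotrophs are untouched by the hook
  expect_equal(unname(r_on$mu_het), unname(r_off$mu_het))
  pars_bad <- ecosystem_params(o2 = list(enabled = TRUE, k_o2 = 1, profile = NULL))
  expect_error(biological_tendencies(s, 0, 10, pars_bad), "no profile")
})

test_that("the abiotic fixture converges with inert, mixing-only nutrients", {
  cfg <- fixture_config("abiotic_control")
  cfg$grid <- list(H = 2000, dz = 50)
  sol <- run_column(cfg, max_time = 2000, tolerance = 1e-3)
  expect_true(sol$converged)
  expect_equal(sum(sol$state[, c("b_het", "b_aoo", "b_noo", "p", "z")]), 0)
  expect_lt(max(sol$state[, "no2"]), 1e-15)
  ox <- oxidation_rate_profiles(sol)
  expect_equal(max(ox$nh4_oxidation), 0)
  # total N only redistributed
  b <- nitrogen_budget(sol)
  expect_lt(abs(b$drift), 1e-10)
})

test_that("the high-mixing fixture converges with nitrite reaching the surface", {
  cfg <- fixture_config("high_mixing")
  cfg$grid <- list(H = 2000, dz = 20)
  sol <- run_column(cfg, max_time = 6000, tolerance = 1e-3)
  expect_true(sol$converged)
  surf_no2 <- mol_m3_to_nmol_l(sol$state[1, "no2"])
  expect_gt(surf_no2, 1)            # nanomolar nitrite at the surface
})

test_that("without nitrifiers no nitrite or nitrate is produced", {
  g <- column_grid(2000, 50)
  S <- column_init(g)
  S[, "b_aoo"] <- 0
  S[, "b_noo"] <- 0
  no3_start <- sum(S[, "no3"])
  sol <- integrate_to_equilibrium(state = S, grid = g, max_time = 300,
                                  tolerance = 0)
  expect_lt(max(sol$state[, "no2"]), 1e-12)
  expect_lte(sum(sol$state[, "no3"]), no3_start * (1 + 1e-9))
})
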