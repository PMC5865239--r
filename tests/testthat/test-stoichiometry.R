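test_that("electron equivalents follow the oxidation-state formula", {
  expect_equal(biomass_composition()$d, 20)
  expect_equal(electron_equivalents(biomass_composition()), 20)
  # nitrogen-free molecules: formaldehyde-unit CH2O and glucose
  expect_equal(electron_equivalents(list(c = 1, h = 2, o = 1, n = 0)), 4)
  expect_equal(electron_equivalents(list(c = 6, h = 12, o = 6, n = 0)), 24)
  expect_error(electron_equivalents(list(c = 0, h = 1, o = 2, n = 0)), "positive")
  expect_error(biomass_composition(5, 7, 2, 0), "n >= 1")
})

test_that("yields take the closed forms and their printed values", {
  y_aoo <- nitrifier_yield("ammonia_oxidation", f = 0.03, d = 20)
  y_noo <- nitrifier_yield("nitrite_oxidation", f = 0.03, d = 20)
  expect_equal(y_aoo, 1 / (1 + 20 / (6 * 0.03)))
  expect_equal(1 / y_aoo, 112.1, tolerance = 1e-3)
  expect_equal(y_noo, 2 * 0.03 / 20)
  expect_equal(1 / y_noo, 1000 / 3)
  # vanishing electron fraction gives vanishing yield
  expect_lt(nitrifier_yield("ammonia_oxidation", f = 1e-12, d = 20), 1e-10)
})

test_that("yield is increasing in f and decreasing in d for both kinds", {
  fs <- seq(0.005, 0.3, length.out = 40)
  ds <- seq(4, 60, length.out = 40)
  for (kind in c("ammonia_oxidation", "nitrite_oxidation")) {
    y_f <- vapply(fs, function(f) nitrifier_yield(kind, f, 20), numeric(1))
    y_d <- vapply(ds, function(d) nitrifier_yield(kind, 0.03, d), numeric(1))
    expect_true(all(diff(y_f) > 0))
    expect_true(all(diff(y_d) < 0))
  }
})

test_that("f inference inverts the yield formulas", {
  expect_equal(round(infer_f(1 / 112, "ammonia_oxidation", 20), 3), 0.030)
  expect_equal(round(infer_f(1 / 310, "nitrite_oxidation", 20), 3), 0.032)
  for (kind in c("ammonia_oxidation", "nitrite_oxidation")) {
    for (f in c(0.01, 0.05, 0.2)) {
      for (d in c(12, 20, 28)) {
        expect_equal(infer_f(nitrifier_yield(kind, f, d), kind, d), f)
      }
    }
  }
  expect_error(infer_f(1.2, "ammonia_oxidation"), "between 0 and 1")
})

test_that("whole-organism reactions carry the published coefficients", {
  aoo <- whole_organism_reaction("ammonia_oxidation", 0.03)
  expect_equal(aoo$nh4_consumed, 1 + 20 / (6 * 0.03))
  expect_equal(aoo$no2_produced, 20 / (6 * 0.03))
  expect_equal(aoo$o2_consumed, (1 - 0.03) * 20 / (4 * 0.03))
  expect_equal(aoo$co2_consumed, 5)
  expect_equal(round(aoo$nh4_consumed), 112)
  expect_equal(round(aoo$o2_consumed), 162)
  expect_equal(round(aoo$no2_produced), 111)

  noo <- whole_organism_reaction("nitrite_oxidation", 0.03)
  expect_equal(noo$no2_consumed, 20 / (2 * 0.03))
  expect_equal(noo$no3_produced, noo$no2_consumed)
  expect_equal(noo$nh4_consumed, 1)
  expect_equal(noo$o2_consumed, aoo$o2_consumed)
  # exact coefficient is 333.3; the published rounded form 334 is
  # within integer rounding of it
  expect_lt(abs(noo$no2_consumed - 334), 1)
})

test_that("every generated reaction balances N and C and inverts its yield", {
  set.seed(42)
  for (i in 1:50) {
    kind <- sample(c("ammonia_oxidation", "nitrite_oxidation"), 1)
    f <- runif(1, 0.005, 0.5)
    comp <- biomass_composition(sample(3:8, 1), sample(5:12, 1),
                                sample(1:3, 1), 1)
    rx <- whole_organism_reaction(kind, f, comp)
    n_in <- rx$nh4_consumed + rx$no2_consumed
    n_out <- 1 + rx$no2_produced + rx$no3_produced
    expect_equal(n_in, n_out)
    expect_equal(rx$co2_consumed, comp$cn_ratio)
    limiting <- if (kind == "ammonia_oxidation") rx$nh4_consumed else rx$no2_consumed
    expect_equal(rx$yield_y * limiting, 1)
  }
})

test_that("the O2:NH4 demand ratio matches its closed form and rounds to 1.45", {
  aoo <- whole_organism_reaction("ammonia_oxidation", 0.03)
  f <- 0.03; d <- 20
  expect_equal(aoo$o2_consumed / aoo$nh4_consumed,
               6 * (1 - f) * d / (4 * (d + 6 * f)))
  expect_equal(round(round(aoo$o2_consumed) / round(aoo$nh4_consumed), 2), 1.45)
})

test_that("linear uncertainty propagation matches its Monte-Carlo oracle", {
  aoo <- propagate_coefficient_uncertainty(
    whole_organism_reaction("ammonia_oxidation", 0.03), d_sd = 4)
  noo <- propagate_coefficient_uncertainty(
    whole_organism_reaction("nitrite_oxidation", 0.03), d_sd = 4)
  expect_equal(aoo$sd[["nh4_consumed"]], 4 / (6 * 0.03))
  expect_equal(aoo$sd[["o2_consumed"]], (1 - 0.03) / (4 * 0.03) * 4)
  expect_equal(noo$sd[["no2_consumed"]], 4 / (2 * 0.03))
  expect_equal(round(aoo$sd[["nh4_consumed"]]), 22)
  expect_equal(round(aoo$sd[["o2_consumed"]]), 32)
  expect_equal(round(noo$sd[["no2_consumed"]]), 67)

  set.seed(7)
  d_draw <- rnorm(1e5, 20, 4)
  mc <- function(coef_fun) sd(coef_fun(d_draw))
  expect_equal(aoo$sd[["nh4_consumed"]], mc(function(d) 1 + d / (6 * 0.03)),
               tolerance = 0.01)
  expect_equal(aoo$sd[["o2_consumed"]],
               mc(function(d) (1 - 0.03) * d / (4 * 0.03)), tolerance = 0.01)
  expect_equal(noo$sd[["no2_consumed"]], mc(function(d) d / (2 * 0.03)),
               tolerance = 0.01)
})

test_that("reaction report and culture-yield reader round-trip", {
  rx <- propagate_coefficient_uncertainty(
    whole_organism_reaction("ammonia_oxidation", 0.03))
  txt <- format(rx)
  expect_match(txt, "112")
  expect_match(txt, "162")
  expect_match(txt, "111")
  tab <- stoichiometry_table(rx)
  expect_true(all(c("species", "side", "value", "rounded", "sd") %in% names(tab)))
  expect_equal(tab$rounded[tab$species == "NH4+" & tab$side == "consumed"], 112)

  cultures <- data.frame(
    organism = c("Nitrosopumilus", "Nitrospina"),
    metabolism = c("ammonia_oxidation", "nitrite_oxidation"),
    yield_value = c(1 / 112, 1 / 310),
    yield_sd = c(0.001, 0.001)
  )
  tf <- tempfile(fileext = ".csv")
  write.csv(cultures, tf, row.names = FALSE)
  out <- infer_f_from_culture_yields(tf, d = 20)
  expect_equal(round(out$f, 3), c(0.030, 0.032))
  expect_true(all(out$f_sd > 0))
  expect_error(infer_f_from_culture_yields(data.frame(organism = "x")),
               "lacks columns")
  unlink(tf)
})
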