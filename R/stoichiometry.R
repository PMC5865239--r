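#' Generic biomass elemental composition
#'
#' Represents microbial biomass as the generic formula
#' \eqn{C_cH_hO_oN_n}. The default, \eqn{C_5H_7O_2N}, is the classic
#' composition for microbial biomass with a C:N of 5 mol/mol. The number
#' of electron equivalents released by full oxidation of one formula
#' unit is \eqn{d = 4c + h - 2o - 3n}; for the default composition
#' \eqn{d = 20}.
#'
#' @param c,h,o,n Non-negative integer atom counts. `n` must be at
#'   least 1 (biomass must contain nitrogen).
#' @return An object of class `biomass_composition` with fields `c`,
#'   `h`, `o`, `n`, the derived molar C:N `cn_ratio`, and the electron
#'   equivalents `d`.
#' @examples
#' bc <- biomass_composition()          # C5H7O2N
#' bc$d                                  # 20
#' bc$cn_ratio                           # 5
#' @export
biomass_composition <- function(c = 5, h = 7, o = 2, n = 1) {
  stopifnot(length(c) == 1, length(h) == 1, length(o) == 1, length(n) == 1)
  if (any(c(c, h, o, n) < 0) || n < 1) {
    stop("atom counts must be non-negative and n >= 1")
  }
  d <- 4 * c + h - 2 * o - 3 * n
  if (d <= 0) {
    stop("invalid composition: electron equivalents d = 4c + h - 2o - 3n must be positive")
  }
  structure(
    list(c = c, h = h, o = o, n = n, cn_ratio = c / n, d = d),
    class = "biomass_composition"
  )
}

#' Electron equivalents of a biomass composition
#'
#' Number of electrons transferred when one formula unit of
#' \eqn{C_cH_hO_oN_n} is fully oxidized (with N at the ammonium
#' oxidation level): \eqn{d = 4c + h - 2o - 3n}.
#'
#' @param comp A [biomass_composition()], or a list with fields `c`,
#'   `h`, `o`, `n` (the raw formula also applies to nitrogen-free
#'   molecules such as glucose).
#' @return Integer electron equivalents `d` (> 0).
#' @export
electron_equivalents <- function(comp) {
  if (inherits(comp, "biomass_composition")) return(comp$d)
  d <- 4 * comp$c + comp$h - 2 * comp$o - 3 * comp$n
  if (d <= 0) stop("invalid composition: d = 4c + h - 2o - 3n must be positive")
  d
}

#' Electron partition fraction
#'
#' The fraction `f` of electrons from the inorganic electron donor
#' routed to biomass synthesis rather than to respiration. Marine
#' nitrifier culture yields imply `f` on the order of 0.03 for both
#' ammonia and nitrite oxidizers, roughly one fifth of the value
#' inferred for wastewater bioreactors.
#'
#' @param f Fraction in (0, 1). Default 0.03.
#' @param f_sd Optional standard deviation of `f` (>= 0).
#' @return An object of class `electron_partition`.
#' @export
electron_partition <- function(f = 0.03, f_sd = 0) {
  stopifnot(is.numeric(f), length(f) == 1, is.numeric(f_sd), f_sd >= 0)
  if (f <= 0 || f >= 1) stop("f must lie strictly between 0 and 1")
  structure(list(f = f, f_sd = f_sd), class = "electron_partition")
}

metabolism_kinds <- c("ammonia_oxidation", "nitrite_oxidation")

as_metabolism <- function(kind) {
  match.arg(kind, metabolism_kinds)
}

#' Chemoautotroph growth yield from the electron partition
#'
#' Moles of biomass N synthesized per mole of the limiting DIN species
#' consumed. For ammonia oxidizers the limiting species (ammonium) is
#' both electron donor and N source, giving
#' \deqn{y_{NH4} = \frac{1}{1 + d/(6f)},}
#' while nitrite oxidizers assimilate reduced N separately, so
#' \deqn{y_{NO2} = \frac{2f}{d}.}
#' With `f = 0.03` and `d = 20` these evaluate to 1/112.1 and 1/333.3.
#'
#' @param kind `"ammonia_oxidation"` or `"nitrite_oxidation"`.
#' @param f Electron fraction to synthesis, in (0, 1), or an
#'   [electron_partition()].
#' @param d Electron equivalents of the biomass composition (> 0).
#' @return Yield in mol biomass N per mol DIN.
#' @seealso [infer_f()] for the algebraic inverse.
#' @export
nitrifier_yield <- function(kind, f = 0.03, d = 20) {
  kind <- as_metabolism(kind)
  if (inherits(f, "electron_partition")) f <- f$f
  stopifnot(is.numeric(f), is.numeric(d), d > 0, f >= 0, f < 1)
  if (kind == "ammonia_oxidation") {
    1 / (1 + d / (6 * f))
  } else {
    2 * f / d
  }
}

#' Infer the electron partition fraction from an observed yield
#'
#' Exact algebraic inverse of [nitrifier_yield()]: given an observed
#' culture yield (mol biomass N per mol DIN) it recovers `f`. For
#' ammonia oxidation \eqn{f = d\,y / (6 (1 - y))}; for nitrite
#' oxidation \eqn{f = d\,y / 2}. Round-trips with [nitrifier_yield()]
#' to machine precision.
#'
#' @param observed_yield Yield in (0, 1).
#' @param kind Metabolism kind.
#' @param d Electron equivalents (> 0).
#' @return The inferred fraction `f`.
#' @examples
#' infer_f(1 / 112, "ammonia_oxidation", 20)   # 0.030
#' infer_f(1 / 310, "nitrite_oxidation", 20)   # 0.032
#' @export
infer_f <- function(observed_yield, kind, d = 20) {
  kind <- as_metabolism(kind)
  stopifnot(is.numeric(observed_yield), d > 0)
  if (any(observed_yield <= 0) || any(observed_yield >= 1)) {
    stop("observed_yield must lie strictly between 0 and 1")
  }
  if (kind == "ammonia_oxidation") {
    d * observed_yield / (6 * (1 - observed_yield))
  } else {
    d * observed_yield / 2
  }
}

#' Whole-organism nitrifier stoichiometry
#'
#' Sums the electron-donor, oxygen-acceptor, and biomass-synthesis
#' half-reactions for one nitrifier metabolism and normalizes the
#' result to 1 mol biomass N produced. Water, protons, and bicarbonate
#' are not tracked (bicarbonate is lumped into the CO2 pool), and N2O
#' formation is neglected, so the stored coefficients are the N species,
#' O2, and CO2 only.
#'
#' Per mole biomass N, with electron fraction `f` and biomass electron
#' equivalents `d` (per N atom, i.e. `d/n`):
#' \itemize{
#'  \item ammonia oxidation: consumes \eqn{1 + d/(6f)} NH4+ and
#'    \eqn{(1-f)d/(4f)} O2; produces \eqn{d/(6f)} NO2-.
#'  \item nitrite oxidation: consumes \eqn{d/(2f)} NO2-, 1 NH4+ (the N
#'    source), and \eqn{(1-f)d/(4f)} O2; produces \eqn{d/(2f)} NO3-.
#' }
#' Both consume `cn_ratio` CO2 (carbon balance). Nitrogen balances
#' exactly: consumed N = 1 (biomass) + produced N.
#'
#' @param kind `"ammonia_oxidation"` or `"nitrite_oxidation"`.
#' @param f Electron fraction, scalar in (0,1) or [electron_partition()].
#' @param comp A [biomass_composition()].
#' @return An object of class `whole_organism_stoichiometry`: a list
#'   with `kind`, `f`, `d`, coefficient fields `nh4_consumed`,
#'   `no2_consumed`, `no2_produced`, `no3_produced`, `o2_consumed`,
#'   `co2_consumed` (mol per mol biomass N), the limiting-DIN yield
#'   `yield_y`, and (once [propagate_coefficient_uncertainty()] has
#'   been applied) per-coefficient standard deviations in `sd`.
#' @examples
#' rx <- whole_organism_reaction("ammonia_oxidation")
#' round(rx$nh4_consumed)   # 112
#' round(rx$o2_consumed)    # 162
#' @export
whole_organism_reaction <- function(kind, f = 0.03, comp = biomass_composition()) {
  kind <- as_metabolism(kind)
  if (inherits(f, "electron_partition")) f <- f$f
  stopifnot(f > 0, f < 1, inherits(comp, "biomass_composition"))
  # electrons routed through synthesis per mole biomass N: d/(f*n)
  epn <- comp$d / (f * comp$n)          # total donor electrons per mol biomass N
  o2 <- (1 - f) * epn / 4
  co2 <- comp$c / comp$n
  if (kind == "ammonia_oxidation") {
    donor_nh4 <- epn / 6                # 1/6 NH4+ oxidized per donor electron
    coef <- list(
      nh4_consumed = 1 + donor_nh4,     # donor + 1 assimilated
      no2_consumed = 0,
      no2_produced = donor_nh4,
      no3_produced = 0,
      o2_consumed = o2,
      co2_consumed = co2
    )
    yield <- 1 / coef$nh4_consumed
    limiting <- "nh4_consumed"
  } else {
    donor_no2 <- epn / 2                # 1/2 NO2- oxidized per donor electron
    coef <- list(
      nh4_consumed = 1,                 # assimilated N source only
      no2_consumed = donor_no2,
      no2_produced = 0,
      no3_produced = donor_no2,
      o2_consumed = o2,
      co2_consumed = co2
    )
    yield <- 1 / coef$no2_consumed
    limiting <- "no2_consumed"
  }
  structure(
    c(list(kind = kind, f = f, d = comp$d, comp = comp,
           limiting = limiting, yield_y = yield),
      coef, list(sd = NULL)),
    class = "whole_organism_stoichiometry"
  )
}

#' Linear uncertainty propagation through the electron equivalents
#'
#' Propagates a standard deviation on `d` (default 4, from the 1 mol/mol
#' s.d. of the biomass C:N with only the carbon count varying) through
#' each stoichiometric coefficient at fixed `f`:
#' \eqn{sd(\mathrm{coef}) = |\partial \mathrm{coef} / \partial d| \cdot sd(d)}.
#' All coefficients are linear in `d` at fixed `f`, so this is exact.
#'
#' @param reaction A [whole_organism_reaction()] result.
#' @param d_sd Standard deviation of `d` (>= 0).
#' @return The reaction with its `sd` field filled in (named numeric
#'   vector over the six coefficients plus `yield_y`).
#' @export
propagate_coefficient_uncertainty <- function(reaction, d_sd = 4) {
  stopifnot(inherits(reaction, "whole_organism_stoichiometry"), d_sd >= 0)
  f <- reaction$f
  n <- reaction$comp$n
  d <- reaction$d
  # d(coefficient)/dd at fixed f, per mole biomass N
  if (reaction$kind == "ammonia_oxidation") {
    grad <- c(
      nh4_consumed = 1 / (6 * f * n),
      no2_consumed = 0,
      no2_produced = 1 / (6 * f * n),
      no3_produced = 0,
      o2_consumed = (1 - f) / (4 * f * n),
      co2_consumed = 0
    )
    # y = 1/(1 + d/(6 f n)) => dy/dd = -(1/(6 f n)) * y^2
    grad["yield_y"] <- reaction$yield_y^2 / (6 * f * n)
  } else {
    grad <- c(
      nh4_consumed = 0,
      no2_consumed = 1 / (2 * f * n),
      no2_produced = 0,
      no3_produced = 1 / (2 * f * n),
      o2_consumed = (1 - f) / (4 * f * n),
      co2_consumed = 0
    )
    grad["yield_y"] <- (2 * f / d^2) * n   # |d/dd (2 f n / d)|
  }
  reaction$sd <- abs(grad) * d_sd
  reaction$d_sd <- d_sd
  reaction
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
format.whole_organism_stoichiometry <- function(x, ..., rounded = TRUE) {
  rnd <- function(v) if (rounded) format(round_half_up(v)) else format(signif(v, 4))
  pm <- function(name, v) {
    if (!is.null(x$sd) && x$sd[[name]] > 0) {
      sprintf("(%s ± %s)", rnd(v), rnd(x$sd[[name]]))
    } else rnd(v)
  }
  lhs <- character(0)
  rhs <- character(0)
  if (x$nh4_consumed > 0) {
    lhs <- c(lhs, paste0(if (x$nh4_consumed != 1) pm("nh4_consumed", x$nh4_consumed) else "",
                         "NH4+"))
  }
  if (x$no2_consumed > 0) lhs <- c(lhs, paste0(pm("no2_consumed", x$no2_consumed), "NO2-"))
  lhs <- c(lhs, paste0(pm("o2_consumed", x$o2_consumed), "O2"),
           paste0(rnd(x$co2_consumed), "CO2"))
  rhs <- c(rhs, "B")
  if (x$no2_produced > 0) rhs <- c(rhs, paste0(pm("no2_produced", x$no2_produced), "NO2-"))
  if (x$no3_produced > 0) rhs <- c(rhs, paste0(pm("no3_produced", x$no3_produced), "NO3-"))
  paste(paste(lhs, collapse = " + "), "->", paste(rhs, collapse = " + "))
}

#' @export
print.whole_organism_stoichiometry <- function(x, ...) {
  lab <- c(ammonia_oxidation = "Ammonia-oxidizer", nitrite_oxidation = "Nitrite-oxidizer")
  cat(sprintf("%s whole-organism stoichiometry (f = %.3g, d = %g)\n",
              lab[[x$kind]], x$f, x$d))
  cat("  ", format(x, rounded = TRUE), "\n", sep = "")
  cat("  (per 1 mol biomass N; exact coefficients: NH4 ",
      signif(x$nh4_consumed, 6), ", NO2 cons ", signif(x$no2_consumed, 6),
      ", O2 ", signif(x$o2_consumed, 6),
      ", NO2 prod ", signif(x$no2_produced, 6),
      ", NO3 prod ", signif(x$no3_produced, 6), ")\n", sep = "")
  cat(sprintf("  yield y = %.4g mol biomass N per mol %s\n", x$yield_y,
              if (x$kind == "ammonia_oxidation") "NH4+" else "NO2-"))
  invisible(x)
}

#' Tabulate a whole-organism stoichiometry
#'
#' Renders the reaction as a data frame (one row per tracked species)
#' suitable for CSV export; `value` holds the exact real coefficient,
#' `rounded` its half-up integer presentation, and `sd` the propagated
#' standard deviation where available.
#'
#' @param reaction A [whole_organism_reaction()] result.
#' @param file Optional path; when given the table is also written as CSV.
#' @return A data frame with columns `species`, `side`, `value`,
#'   `rounded`, `sd`.
#' @export
stoichiometry_table <- function(reaction, file = NULL) {
  stopifnot(inherits(reaction, "whole_organism_stoichiometry"))
  rows <- data.frame(
    species = c("NH4+", "NO2-", "O2", "CO2", "biomass_N", "NO2-", "NO3-"),
    side = c("consumed", "consumed", "consumed", "consumed",
             "produced", "produced", "produced"),
    value = c(reaction$nh4_consumed, reaction$no2_consumed,
              reaction$o2_consumed, reaction$co2_consumed,
              1, reaction$no2_produced, reaction$no3_produced),
    stringsAsFactors = FALSE
  )
  rows$rounded <- round_half_up(rows$value)
  sd_map <- c("nh4_consumed", "no2_consumed", "o2_consumed", "co2_consumed",
              NA, "no2_produced", "no3_produced")
  rows$sd <- vapply(sd_map, function(k) {
    if (is.na(k) || is.null(reaction$sd)) NA_real_ else unname(reaction$sd[[k]])
  }, numeric(1))
  rows <- rows[rows$value > 0 | rows$side == "produced" & rows$species == "biomass_N", ]
  rownames(rows) <- NULL
  if (!is.null(file)) utils::write.csv(rows, file, row.names = FALSE)
  rows
}

#' Batch electron-fraction inference from culture yields
#'
#' Reads a CSV of culture-derived growth yields (columns `organism`,
#' `metabolism`, `yield_value`, `yield_sd`; metabolism is
#' `ammonia_oxidation` or `nitrite_oxidation`) and infers `f` for each
#' row via [infer_f()]. The `f_sd` column propagates the yield s.d.
#' linearly through the inverse formula.
#'
#' @param file Path to the CSV, or a data frame with those columns.
#' @param d Electron equivalents used for all rows.
#' @return The input table with columns `f` and `f_sd` appended.
#' @examples
#' demo <- system.file("extdata", "culture_yields_synthetic.csv",
#'                     package = "nitricline")
#' infer_f_from_culture_yields(demo)
#' @export
infer_f_from_culture_yields <- function(file, d = 20) {
  tab <- if (is.data.frame(file)) file else utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("organism", "metabolism", "yield_value")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("culture yield table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(tab$yield_sd)) tab$yield_sd <- 0
  tab$f <- mapply(function(y, k) infer_f(y, k, d), tab$yield_value, tab$metabolism)
  # d f / d y: AOO d/(6 (1-y)^2); NOO d/2
  dfdy <- ifelse(tab$metabolism == "ammonia_oxidation",
                 d / (6 * (1 - tab$yield_value)^2), d / 2)
  tab$f_sd <- abs(dfdy) * tab$yield_sd
  tab
}
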