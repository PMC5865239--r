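#' Kinetic uptake traits for one resource
#'
#' Bundles the maximum biomass-specific uptake rate and the
#' half-saturation concentration of one resource, with declared units.
#' The half-saturation is stored internally in umol/L; nanomolar input
#' is converted on construction so that downstream arithmetic never
#' mixes units.
#'
#' @param vmax Maximum specific uptake rate, mol resource per mol
#'   biomass N per day (> 0).
#' @param k Half-saturation concentration (> 0), in the unit named by
#'   `k_unit`.
#' @param k_unit `"umol_l"` (default) or `"nmol_l"`.
#' @return An object of class `kinetic_traits` with fields `vmax`
#'   (per day), `k` (umol/L), and the derived `affinity`
#'   (L per umol biomass N per day).
#' @examples
#' aoa <- kinetic_traits(vmax = 50.8, k = 133, k_unit = "nmol_l")
#' aoa$affinity   # ~382
#' @export
kinetic_traits <- function(vmax, k, k_unit = c("umol_l", "nmol_l")) {
  k_unit <- match.arg(k_unit)
  stopifnot(is.numeric(vmax), is.numeric(k), vmax > 0, k > 0)
  k_um <- if (k_unit == "nmol_l") k / 1000 else k
  structure(
    list(vmax = vmax, k = k_um, affinity = vmax / k_um),
    class = "kinetic_traits"
  )
}

#' @export
print.kinetic_traits <- function(x, ...) {
  cat(sprintf(
    "kinetic traits: Vmax = %.4g /d, K = %.4g umol/L, affinity = %.4g L/umol biomass N/d\n",
    x$vmax, x$k, x$affinity))
  invisible(x)
}

N_G_PER_MOL <- 14    # nitrogen atomic mass used throughout (g/mol)
C_G_PER_MOL <- 12    # carbon atomic mass (g/mol)

#' Convert a protein-normalized rate to a biomass-N-specific rate
#'
#' Culture uptake rates are commonly reported per mg protein per hour.
#' With a protein nitrogen content of `n_fraction` (g N per g protein),
#' 1 mg protein contains `1000 * n_fraction / 14` umol N, so
#' \deqn{V = \mathrm{rate} \cdot 24 / (1000\, n_\mathrm{fraction} / 14)}
#' in mol substrate per mol biomass N per day.
#'
#' @param rate Rate in umol substrate per mg protein per hour (>= 0).
#' @param n_fraction Protein N content, g/g, in (0, 1); default 0.16.
#' @return Rate in mol substrate per mol biomass N per day.
#' @examples
#' specific_rate_from_protein_rate(24.2)        # 50.8 (ammonia oxidizer Vmax)
#' @export
specific_rate_from_protein_rate <- function(rate, n_fraction = 0.16) {
  stopifnot(rate >= 0, n_fraction > 0, n_fraction < 1)
  rate * 24 / (1000 * n_fraction / N_G_PER_MOL)
}

#' Convert a protein-normalized rate to a per-cell rate
#'
#' umol per mg protein equals amol per fg protein, so multiplying by the
#' cellular protein content in fg gives amol per cell per hour; times 24
#' and divided by 1000 yields fmol per cell per day.
#'
#' @param rate Rate in umol per mg protein per hour (>= 0).
#' @param protein_per_cell Cellular protein content, fg per cell (> 0).
#' @return Rate in fmol per cell per day.
#' @examples
#' per_cell_rate(24.2, 10.2)   # 5.92 fmol NH4+ per cell per day
#' @export
per_cell_rate <- function(rate, protein_per_cell) {
  stopifnot(rate >= 0, protein_per_cell > 0)
  rate * protein_per_cell * 24 / 1000
}

#' Scale a standard deviation by a ratio of measured values
#'
#' Transfers a relative uncertainty from a reference measurement to a
#' derived value: `sd_ref * value / ref`. Used when the s.d. of a rate
#' is only reported for a covarying quantity (e.g. taking the relative
#' s.d. of oxygen uptake as that of ammonium uptake).
#'
#' @param sd_ref Standard deviation of the reference quantity.
#' @param value The derived value to which the relative s.d. applies.
#' @param ref The reference value (> 0).
#' @return Standard deviation in the units of `value`.
#' @examples
#' sd_by_ratio(3.35, 24.2, 36.29)   # 2.23
#' @export
sd_by_ratio <- function(sd_ref, value, ref) {
  stopifnot(ref > 0, sd_ref >= 0)
  sd_ref * value / ref
}

#' Nitrogen cell quota from protein content
#'
#' `protein_per_cell * n_fraction / 14` converts fg protein per cell to
#' fmol N per cell. The 10.2 fg protein measured for ammonia-oxidizing
#' archaea gives 0.12 fmol N per cell at 16% protein N.
#'
#' @param protein_per_cell fg protein per cell (> 0).
#' @param n_fraction Protein N content g/g (0, 1); default 0.16.
#' @return Quota in fmol N per cell.
#' @export
n_quota_from_protein <- function(protein_per_cell, n_fraction = 0.16) {
  stopifnot(protein_per_cell > 0, n_fraction > 0, n_fraction < 1)
  protein_per_cell * n_fraction / N_G_PER_MOL
}

#' Cell properties of a chemoautotroph functional type
#'
#' @param protein_per_cell fg protein per cell.
#' @param protein_n_fraction g N per g protein (default 0.16; plausible
#'   range 0.10-0.20).
#' @param cell_volume Cell volume in um^3, or a dimensionless volume
#'   factor relative to a reference cell.
#' @return An object of class `cell_properties` including the derived
#'   `n_quota` (fmol N per cell).
#' @export
cell_properties <- function(protein_per_cell, protein_n_fraction = 0.16,
                            cell_volume = NULL) {
  structure(
    list(
      protein_per_cell = protein_per_cell,
      protein_n_fraction = protein_n_fraction,
      n_quota = n_quota_from_protein(protein_per_cell, protein_n_fraction),
      cell_volume = cell_volume
    ),
    class = "cell_properties"
  )
}

#' Allometric scaling factors for uptake kinetics
#'
#' Diffusive-uptake allometry: the cellular uptake rate scales with
#' surface area (\eqn{r^2}) while cell quota scales with volume
#' (\eqn{r^3}), so the biomass-specific maximum rate scales as
#' \eqn{r^{-1}}; the half-saturation concentration scales as \eqn{r};
#' their quotient, the specific affinity, scales as \eqn{r^{-2}}. A
#' cell `volume_factor` times larger has radius factor
#' \eqn{\rho = \mathrm{volume\_factor}^{1/3}}.
#'
#' @param volume_factor Volume ratio relative to the reference cell
#'   (> 0; 10 for the default nitrite-oxidizer case).
#' @return List with `vmax_factor` (\eqn{\rho^{-1}}), `k_factor`
#'   (\eqn{\rho}), `affinity_factor` (\eqn{\rho^{-2}}).
#' @examples
#' allometric_scaling(10)$affinity_factor   # 1/4.64
#' @export
allometric_scaling <- function(volume_factor) {
  stopifnot(volume_factor > 0)
  rho <- volume_factor^(1 / 3)
  list(vmax_factor = 1 / rho, k_factor = rho, affinity_factor = rho^-2)
}

#' Specific uptake affinity
#'
#' `vmax / k` with the half-saturation expressed in umol/L: the initial
#' slope of the Monod uptake curve, the trait that measures competitive
#' ability at low resource concentrations.
#'
#' @param t A [kinetic_traits()] object.
#' @return Affinity in L per umol biomass N per day.
#' @export
specific_affinity <- function(t) {
  stopifnot(inherits(t, "kinetic_traits"))
  t$vmax / t$k
}

#' Derive nitrite-oxidizer traits from ammonia-oxidizer traits
#'
#' Applies [allometric_scaling()] to a reference trait set: a
#' `volume_factor`-fold larger cell has `vmax` divided and `k`
#' multiplied by the cube root of the factor.
#'
#' @param aoo Reference [kinetic_traits()] (the ammonia oxidizer).
#' @param volume_factor Volume ratio (default 10).
#' @return A [kinetic_traits()] object for the larger cell.
#' @export
build_noo_traits <- function(aoo, volume_factor = 10) {
  stopifnot(inherits(aoo, "kinetic_traits"))
  s <- allometric_scaling(volume_factor)
  kinetic_traits(vmax = aoo$vmax * s$vmax_factor, k = aoo$k * s$k_factor)
}

#' Default allometric coefficient set for picophytoplankton traits
#'
#' Power-law coefficients `trait = a * v^b` (volume `v` in um^3) for
#' maximum growth rate (per day), maximum per-cell uptake rate (fmol N
#' per cell per day), half-saturation for uptake (umol/L), and minimum
#' N quota (fmol N per cell). The literature sources behind such
#' relationships report values for larger cells; this default set is
#' anchored so that a 0.6-um-diameter picoplankter (v = 0.113 um^3)
#' has mu_max near 0.7 per day and a specific affinity
#' Vmax/(Qmin*K_N) of order 100 L per umol biomass N per day, the
#' scale reported for Prochlorococcus.
#'
#' @return List of `a`/`b` pairs for `mu_max`, `vmax_up`, `k_n`, `q_min`.
#' @export
phyto_allometry_defaults <- function() {
  list(
    mu_max  = list(a = 1.08,  b = 0.20),   # /d; rising limb for small cells
    vmax_up = list(a = 12.97, b = 0.67),   # fmol N/cell/d; surface-area scaling
    k_n     = list(a = 0.351, b = 1 / 3),  # umol/L; ~ radius
    q_min   = list(a = 1.423, b = 0.90)    # fmol N/cell
  )
}

#' Phytoplankton growth traits from cell volume
#'
#' Evaluates the generic allometric power laws and converts the uptake
#' half-saturation `K_N` (with respect to uptake) into the effective
#' half-saturation with respect to growth,
#' \deqn{K_{NOx} = K_N(v)\,\mu_{max}(v)\,Q_{min}(v) / V_{max}(v),}
#' which is substantially lower than `K_N` because phytoplankton use
#' DIN as a building block with high yield rather than as an electron
#' donor. The ammonium half-saturation is assumed to be half that of
#' the oxidized species.
#'
#' @param v Cell volume in um^3 (> 0).
#' @param coeffs Allometric coefficients, as
#'   [phyto_allometry_defaults()]. Each trait needs fields `a` and `b`.
#' @return List with `mu_max` (per day), `k_nox` (umol/L), `k_nh4`
#'   (umol/L), and the intermediate `vmax_up`, `k_n`, `q_min`,
#'   `affinity` (L per umol N per day).
#' @export
phyto_traits_from_volume <- function(v, coeffs = phyto_allometry_defaults()) {
  stopifnot(v > 0)
  need <- c("mu_max", "vmax_up", "k_n", "q_min")
  missing <- setdiff(need, names(coeffs))
  if (length(missing)) {
    stop("incomplete allometric configuration; missing: ",
         paste(missing, collapse = ", "))
  }
  pw <- function(cf) {
    if (is.null(cf$a) || is.null(cf$b)) stop("allometric coefficient needs fields a and b")
    cf$a * v^cf$b
  }
  mu_max <- pw(coeffs$mu_max)
  vmax_up <- pw(coeffs$vmax_up)
  k_n <- pw(coeffs$k_n)
  q_min <- pw(coeffs$q_min)
  k_nox <- k_n * mu_max * q_min / vmax_up
  list(
    mu_max = mu_max, k_nox = k_nox, k_nh4 = 0.5 * k_nox,
    vmax_up = vmax_up, k_n = k_n, q_min = q_min,
    affinity = vmax_up / (q_min * k_n)
  )
}

#' Cell volume of a spherical cell from its diameter
#'
#' @param diameter_um Cell diameter in um.
#' @return Volume in um^3.
#' @export
sphere_volume <- function(diameter_um) {
  pi / 6 * diameter_um^3
}

#' Write a one-row-per-type trait table
#'
#' @param types Named list of lists, each with `traits` (a
#'   [kinetic_traits()]), optional `quota` (fmol N per cell), and
#'   optional `note` (provenance string).
#' @param file Optional CSV output path.
#' @return Data frame with columns `type`, `vmax_d`, `k_umol_l`,
#'   `affinity_l_per_umol_d`, `quota_fmol`, `note`.
#' @export
trait_table <- function(types, file = NULL) {
  rows <- do.call(rbind, lapply(names(types), function(nm) {
    x <- types[[nm]]
    data.frame(
      type = nm,
      vmax_d = x$traits$vmax,
      k_umol_l = x$traits$k,
      affinity_l_per_umol_d = x$traits$affinity,
      quota_fmol = if (is.null(x$quota)) NA_real_ else x$quota,
      note = if (is.null(x$note)) "" else x$note,
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  if (!is.null(file)) utils::write.csv(rows, file, row.names = FALSE)
  rows
}
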