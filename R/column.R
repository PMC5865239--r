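#' Vertical grid of the water column
#'
#' Uniform finite-volume grid: depth increases downward from the
#' surface at z = 0 to the bottom at z = H. Concentrations live at
#' cell centers; diffusive and sinking fluxes are evaluated at cell
#' faces.
#'
#' @param H Domain height in m (default 2000).
#' @param dz Cell height in m (default 5); `H/dz` must be an integer.
#' @return Object of class `column_grid` with `H`, `dz`, `n`,
#'   `z_center` (length n), `z_face` (length n+1).
#' @export
column_grid <- function(H = 2000, dz = 5) {
  stopifnot(H > 0, dz > 0)
  n <- H / dz
  if (abs(n - round(n)) > 1e-9) stop("H must be an integer multiple of dz")
  n <- as.integer(round(n))
  structure(
    list(H = H, dz = dz, n = n,
         z_face = seq(0, H, by = dz),
         z_center = seq(dz / 2, H - dz / 2, by = dz)),
    class = "column_grid"
  )
}

#' Physical parameters of the 1D column
#'
#' @param k_max Surface (mixed-layer) diffusivity, m^2/s.
#' @param k_min Background interior diffusivity, m^2/s.
#' @param z_mld Mixed-layer e-folding depth scale, m.
#' @param k_w Light attenuation by water, 1/m.
#' @param k_chl Light attenuation per chlorophyll, m^2 per mg Chl.
#' @param i_max Maximum surface irradiance, uEin m^-2 s^-1; the mean
#'   incoming irradiance is `0.5 * i_max`.
#' @param diel Resolve the daily light cycle? (default `FALSE`:
#'   steady mean light).
#' @param w_s Detritus sinking speed, m per day.
#' @return Object of class `physics_params`.
#' @export
physics_params <- function(k_max = 1e-2, k_min = 1e-5, z_mld = 20,
                           k_w = 0.04, k_chl = 0.02, i_max = 1400,
                           diel = FALSE, w_s = 10) {
  stopifnot(k_max >= k_min, k_min > 0, w_s >= 0, z_mld > 0, i_max >= 0)
  structure(
    list(k_max = k_max, k_min = k_min, z_mld = z_mld, k_w = k_w,
         k_chl = k_chl, i_max = i_max, diel = diel, w_s = w_s),
    class = "physics_params"
  )
}

#' Vertical diffusivity profile
#'
#' Mixed layer imposed as enhanced diffusivity decaying over `z_mld`,
#' a constant interior background, and a bottom boundary layer decaying
#' over a 100 m scale above the seafloor (which smooths numerical error
#' where sinking detritus accumulates):
#' \deqn{K_Z(z) = K_{max} e^{-z/z_{mld}} + K_{min} +
#'   K_{max} e^{-(H - z)/100}.}
#'
#' @param grid [column_grid()].
#' @param physics [physics_params()].
#' @return Diffusivity at the n+1 cell faces, m^2/s.
#' @export
kz_profile <- function(grid, physics) {
  z <- grid$z_face
  physics$k_max * exp(-z / physics$z_mld) + physics$k_min +
    physics$k_max * exp(-(grid$H - z) / 100)
}

#' Subtropical temperature profile
#'
#' Double-exponential fit to subtropical North Pacific observations,
#' 26 degrees C at the surface decaying to 2 degrees C at depth:
#' \eqn{T(z) = 12 e^{-z/150} + 12 e^{-z/500} + 2} with z the positive
#' downward depth (the sign adapter for the fit's negative-upward
#' convention is internal).
#'
#' @param grid [column_grid()], or a numeric vector of depths (m,
#'   positive downward).
#' @return Temperature at cell centers, degrees C.
#' @export
temperature_profile <- function(grid) {
  z <- if (inherits(grid, "column_grid")) grid$z_center else grid
  12 * exp(-z / 150) + 12 * exp(-z / 500) + 2
}

#' Chlorophyll concentration from the phytoplankton state
#'
#' Converts phytoplankton nitrogen biomass to chlorophyll:
#' mol N -> mol C (via the C:N ratio) -> g C (x12) -> g Chl (x theta),
#' reported in mg Chl per m^3. For reporting, theta is floored at
#' `0.1 * theta_max` (the floor is cosmetic: state variables never see
#' it).
#'
#' @param p Phytoplankton biomass, mol N per m^3.
#' @param theta Chl:C ratio profile (g/g), as returned by
#'   [phyto_growth()].
#' @param params [ecosystem_params()].
#' @param floor Apply the reporting floor? Default `TRUE`.
#' @return Chlorophyll in mg per m^3.
#' @export
chlorophyll_from_state <- function(p, theta, params, floor = TRUE) {
  stopifnot(all(p >= 0))
  if (floor) theta <- pmax(theta, 0.1 * params$phyto$theta_max)
  p * params$phyto$cn_ratio * C_G_PER_MOL * theta * 1000
}

#' Irradiance profile for a given chlorophyll profile
#'
#' Beer-Lambert attenuation by water and chlorophyll,
#' \eqn{I(z) = I_{in} \exp(-(k_w z + k_{Chl}\int_0^z \mathrm{Chl}\,dz))},
#' evaluated at cell centers (the chlorophyll integral includes half of
#' the local cell). `I_in` is `0.5 * i_max` for steady light, or
#' `0.5 * i_max (cos(2 pi t) + 1)` when the daily cycle is resolved
#' (`t` in days), whose daily mean is again `0.5 * i_max`.
#'
#' @param grid [column_grid()].
#' @param chl Chlorophyll at cell centers, mg per m^3 (scalar or
#'   length n).
#' @param physics [physics_params()].
#' @param t Time of day in days (only used when `physics$diel`).
#' @return Irradiance at cell centers, uEin m^-2 s^-1.
#' @export
light_profile <- function(grid, chl, physics, t = 0) {
  chl <- rep_len(chl, grid$n)
  stopifnot(all(chl >= 0))
  i_in <- if (isTRUE(physics$diel)) {
    0.5 * physics$i_max * (cos(2 * pi * t) + 1)
  } else {
    0.5 * physics$i_max
  }
  # optical depth to each cell center: water + chl above + half local cell
  tau_chl <- physics$k_chl * (cumsum(chl) - chl / 2) * grid$dz
  i_in * exp(-(physics$k_w * grid$z_center + tau_chl))
}

#' Diffusion tendency under no-flux boundaries
#'
#' Centered second-order flux divergence: the diffusive flux
#' \eqn{-K_Z \partial C/\partial z} is evaluated at interior faces and
#' set to zero at the surface and bottom, so the column inventory is
#' conserved exactly.
#'
#' @param profile Concentration at cell centers (any unit).
#' @param kz_faces Diffusivity at the n+1 faces, in m^2 per day.
#' @param grid [column_grid()].
#' @return Tendency at cell centers, per day.
#' @export
diffusion_tendency <- function(profile, kz_faces, grid) {
  n <- grid$n
  stopifnot(length(profile) == n, length(kz_faces) == n + 1)
  flux <- numeric(n + 1)                       # positive downward
  flux[2:n] <- -kz_faces[2:n] * (profile[2:n] - profile[1:(n - 1)]) / grid$dz
  -(flux[2:(n + 1)] - flux[1:n]) / grid$dz
}

#' Sinking tendency with the QUICK advection scheme
#'
#' Third-order upstream-weighted face reconstruction for the downward
#' flux `w_s * D`: linear interpolation between the adjacent cells
#' corrected by the upstream curvature,
#' \eqn{D_f = (D_U + D_D)/2 - (D_D - 2 D_U + D_{UU})/8}. Faces whose
#' far-upstream cell lies outside the domain fall back to first-order
#' upwind. No flux enters through the surface and none leaves through
#' the bottom: sinking detritus accumulates in the bottom cell,
#' conceptually a sediment layer, and the column-integrated tendency
#' is zero.
#'
#' @param det Detritus at cell centers.
#' @param w_s Sinking speed, m per day (>= 0).
#' @param grid [column_grid()].
#' @return Tendency at cell centers, per day.
#' @export
sinking_tendency <- function(det, w_s, grid) {
  n <- grid$n
  stopifnot(length(det) == n, w_s >= 0)
  face <- numeric(n + 1)                       # face value of D, flow downward
  if (n >= 2) face[2] <- det[1]                # upwind fallback at the first interior face
  if (n >= 3) {
    i <- 3:n                                   # face i sits atop cell i; upstream cell i-1
    face[i] <- (det[i - 1] + det[i]) / 2 - (det[i] - 2 * det[i - 1] + det[i - 2]) / 8
  }
  flux <- w_s * face
  flux[n + 1] <- 0                             # bottom accumulates
  -(flux[2:(n + 1)] - flux[1:n]) / grid$dz
}

#' One classical fourth-order Runge-Kutta step
#'
#' Generic utility used by the test problems and the zero-dimensional
#' chemostat; the column integrator applies the same scheme in
#' compiled code.
#'
#' @param f Right-hand side, `f(t, y)` returning dy/dt.
#' @param y State.
#' @param t Time.
#' @param dt Step size (> 0).
#' @return The state at `t + dt`.
#' @export
rk4_step <- function(f, y, t, dt) {
  stopifnot(dt > 0)
  k1 <- f(t, y)
  k2 <- f(t + dt / 2, y + dt / 2 * k1)
  k3 <- f(t + dt / 2, y + dt / 2 * k2)
  k4 <- f(t + dt, y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Automatic stable time step
#'
#' Half of the stricter of the explicit diffusive bound
#' \eqn{\Delta z^2 / (2 K_{max})} and the advective bound
#' \eqn{\Delta z / w_s}, additionally capped at `dt_bio` (default 0.01
#' d): nutrient turnover by high-affinity uptake during transient
#' blooms is much faster than either transport bound, and a fixed-step
#' scheme needs the reaction time scale resolved as well.
#'
#' @param grid [column_grid()].
#' @param physics [physics_params()].
#' @param safety Fraction of the stability bound to use (default 0.5).
#' @param dt_bio Biological reaction-time cap in days.
#' @return Time step in days.
#' @export
auto_dt <- function(grid, physics, safety = 0.5, dt_bio = 0.01) {
  kz_m2d <- max(kz_profile(grid, physics)) * 86400
  dt_diff <- grid$dz^2 / (2 * kz_m2d)
  dt_adv <- if (physics$w_s > 0) grid$dz / physics$w_s else Inf
  min(safety * min(dt_diff, dt_adv), dt_bio)
}

#' Default initial condition for the column
#'
#' Nutrient-at-depth start: nitrate at `no3_deep` umol/L below
#' `ramp_depth`, ramping linearly to zero at the surface; a small
#' uniform inoculum of every biomass; no ammonium, nitrite, or
#' detritus. Equilibrium solutions are checked to be independent of
#' this choice.
#'
#' @param grid [column_grid()].
#' @param no3_deep Deep nitrate, umol/L (default 20).
#' @param ramp_depth Depth (m) below which nitrate is uniform.
#' @param seed_biomass Initial biomass of each population, umol N/L.
#' @return State matrix (n x 9, mol N per m^3) with columns
#'   [state_vars].
#' @export
column_init <- function(grid, no3_deep = 20, ramp_depth = 250,
                        seed_biomass = 1e-3) {
  n <- grid$n
  S <- matrix(0, n, length(state_vars), dimnames = list(NULL, state_vars))
  no3 <- no3_deep * pmin(grid$z_center / ramp_depth, 1)
  S[, "no3"] <- umol_l_to_mol_m3(no3)
  for (v in c("b_het", "b_aoo", "b_noo", "p", "z")) {
    S[, v] <- umol_l_to_mol_m3(seed_biomass)
  }
  S
}

#' Irradiance and photoacclimation fields of a column state
#'
#' Reconstructs the light field the tendency computation sees: a
#' top-down sweep where each cell's Chl:C ratio is photoacclimated to
#' the light arriving at the cell and the cell's own chlorophyll
#' attenuates the light passed downward (its own mid-cell irradiance
#' includes half of its own attenuation).
#'
#' @param state State matrix (n x 9, mol N per m^3).
#' @param grid [column_grid()].
#' @param physics [physics_params()].
#' @param params [ecosystem_params()].
#' @param t Time in days (for diel forcing).
#' @return List with vectors `I` (uEin m^-2 s^-1), `theta` (g/g),
#'   `chl` (mg/m^3, un-floored).
#' @export
column_light_field <- function(state, grid, physics, params, t = 0) {
  n <- grid$n
  Tz <- temperature_profile(grid)
  nh4 <- mol_m3_to_umol_l(state[, "nh4"])
  no2 <- mol_m3_to_umol_l(state[, "no2"])
  no3 <- mol_m3_to_umol_l(state[, "no3"])
  p <- state[, "p"]
  gn <- gamma_n(nh4, no2, no3, params)
  gt <- temperature_factor(Tz, params)
  mu_cap <- params$phyto$mu_max * gn * gt
  theta_max <- params$phyto$theta_max
  gamma_coef <- params$phyto$phi * params$phyto$a_chl * 0.0864 * 12000
  i_in <- if (isTRUE(physics$diel)) 0.5 * physics$i_max * (cos(2 * pi * t) + 1)
          else 0.5 * physics$i_max
  I <- numeric(n); theta <- numeric(n); chl <- numeric(n)
  i_face <- i_in
  for (i in seq_len(n)) {
    acclimate <- function(i_mid) {
      g <- gamma_coef * i_mid
      th <- if (mu_cap[i] > 0) theta_max / (1 + g * theta_max / (2 * mu_cap[i])) else theta_max
      th
    }
    i_mid <- i_face * exp(-physics$k_w * grid$dz / 2)
    th <- acclimate(i_mid)
    ch <- chlorophyll_from_state(p[i], th, params, floor = FALSE)
    # refine once with the cell's own half attenuation
    i_mid <- i_face * exp(-(physics$k_w + physics$k_chl * ch) * grid$dz / 2)
    th <- acclimate(i_mid)
    ch <- chlorophyll_from_state(p[i], th, params, floor = FALSE)
    I[i] <- i_mid; theta[i] <- th; chl[i] <- ch
    i_face <- i_face * exp(-(physics$k_w + physics$k_chl * ch) * grid$dz)
  }
  list(I = I, theta = theta, chl = chl)
}

#' Full column right-hand side (reference implementation)
#'
#' Biological tendencies plus diffusion of every variable and sinking
#' of detritus, in mol N m^-3 per day. This R version mirrors the
#' compiled integrator's right-hand side and is used for diagnostics
#' and cross-checking.
#'
#' @param state State matrix (n x 9, mol N per m^3).
#' @param grid,physics,params Model configuration.
#' @param t Time in days.
#' @return Tendency matrix (n x 9).
#' @export
column_rhs <- function(state, grid, physics, params, t = 0) {
  lf <- column_light_field(state, grid, physics, params, t)
  Tz <- temperature_profile(grid)
  dS <- biological_tendencies(state, lf$I, Tz, params)
  kz_m2d <- kz_profile(grid, physics) * 86400
  for (j in seq_along(state_vars)) {
    dS[, j] <- dS[, j] + diffusion_tendency(state[, j], kz_m2d, grid)
  }
  dS[, "det"] <- dS[, "det"] + sinking_tendency(state[, "det"], physics$w_s, grid)
  dS
}
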