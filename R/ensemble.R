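#' Specification of a parameter-perturbation ensemble
#'
#' Encodes how uncertain biological parameters are perturbed around
#' their defaults: the nitrifier uptake kinetics are drawn from the
#' normal distributions of the culture measurements (Vmax 50.8 +/- 4.68
#' per day, K 133 +/- 38 nM for the ammonia oxidizer), the
#' nitrite-oxidizer cell-volume factor is uniform over 1-20 (entering
#' the kinetics through its cube root), and the remaining listed
#' parameters are uniform over +/-50% of their default: phytoplankton
#' mu_max and K_NOx (K_NH4 recomputed as half), the heterotroph
#' V_maxD, K_D, y_D, the grazing g_max and K_g, the mortalities m_B and
#' m_Z, and the grazer efficiency zeta.
#'
#' @param n_members Number of members (>= 1; desk-scale default 50,
#'   ~1000 for a full envelope).
#' @param seed Master seed; member draws are derived deterministically
#'   from `(seed, member index)` so membership and execution order
#'   cannot change them.
#' @param vmax_aoo_sd,k_aoo_sd Normal s.d. of the AOO Vmax (per day)
#'   and K (umol/L).
#' @param volume_range Range of the NOO:AOO volume factor.
#' @param pm50 Names of the +/-50% uniform parameters (subset of the
#'   default set).
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_members = 50, seed = 1,
                          vmax_aoo_sd = 4.68, k_aoo_sd = 0.038,
                          volume_range = c(1, 20),
                          pm50 = c("mu_max", "k_nox", "vmax_d", "k_d", "y_d",
                                   "g_max", "k_g", "m_b", "m_z", "zeta")) {
  stopifnot(n_members >= 1, length(volume_range) == 2,
            volume_range[1] > 0, diff(volume_range) >= 0)
  structure(
    list(n_members = as.integer(n_members), seed = as.integer(seed),
         vmax_aoo_sd = vmax_aoo_sd, k_aoo_sd = k_aoo_sd,
         volume_range = volume_range, pm50 = pm50),
    class = "ensemble_spec"
  )
}

# private per-member stream: decouples members from each other and from
# the caller's RNG state
member_seed <- function(seed, index) {
  (seed + 97561L * as.integer(index)) %% 2147483647L
}

#' Draw one perturbed parameter set
#'
#' Deterministic given `(spec$seed, index)`. Draws violating parameter
#' validity (yields or efficiencies outside (0,1), non-positive rates)
#' are redrawn; the redraw count is attached as attribute `"redraws"`.
#'
#' @param base Base [ecosystem_params()].
#' @param spec [ensemble_spec()].
#' @param index Member index (1-based).
#' @return A perturbed `ecosystem_params` object with attributes
#'   `"draw"` (named vector of the sampled values) and `"redraws"`.
#' @export
sample_parameters <- function(base, spec, index) {
  stopifnot(inherits(base, "ecosystem_params"), inherits(spec, "ensemble_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(member_seed(spec$seed, index))

  u50 <- function(x) x * stats::runif(1, 0.5, 1.5)
  redraws <- 0L
  repeat {
    draw <- c(
      vmax_aoo = stats::rnorm(1, base$aoo$traits$vmax, spec$vmax_aoo_sd),
      k_aoo = stats::rnorm(1, base$aoo$traits$k, spec$k_aoo_sd),
      volume_factor = stats::runif(1, spec$volume_range[1], spec$volume_range[2])
    )
    for (nm in spec$pm50) {
      draw[nm] <- switch(nm,
        mu_max = u50(base$phyto$mu_max),
        k_nox = u50(base$phyto$k_no2p),
        vmax_d = u50(base$het$vmax_d),
        k_d = u50(base$het$k_d),
        y_d = u50(base$het$y_d),
        g_max = u50(base$grazing$g_max),
        k_g = u50(base$grazing$k_g),
        m_b = u50(base$m_b),
        m_z = u50(base$grazing$m_z),
        zeta = u50(base$grazing$zeta),
        stop("unknown +/-50% parameter: ", nm)
      )
    }
    ok <- draw[["vmax_aoo"]] > 0 && draw[["k_aoo"]] > 0 &&
      (!("y_d" %in% names(draw)) || (draw[["y_d"]] > 0 && draw[["y_d"]] < 1)) &&
      (!("zeta" %in% names(draw)) || (draw[["zeta"]] > 0 && draw[["zeta"]] < 1))
    if (ok) break
    redraws <- redraws + 1L
    if (redraws > 1000L) stop("could not draw a valid parameter set")
  }

  p <- ecosystem_params(
    f = base$f, d = base$d,
    aoo_traits = kinetic_traits(draw[["vmax_aoo"]], draw[["k_aoo"]]),
    noo_volume_factor = draw[["volume_factor"]],
    het = utils::modifyList(base$het, list(
      vmax_d = if ("vmax_d" %in% names(draw)) draw[["vmax_d"]] else base$het$vmax_d,
      k_d = if ("k_d" %in% names(draw)) draw[["k_d"]] else base$het$k_d,
      y_d = if ("y_d" %in% names(draw)) draw[["y_d"]] else base$het$y_d)),
    phyto = utils::modifyList(base$phyto, {
      ph <- list()
      if ("mu_max" %in% names(draw)) ph$mu_max <- draw[["mu_max"]]
      if ("k_nox" %in% names(draw)) {
        ph$k_no2p <- draw[["k_nox"]]
        ph$k_no3p <- draw[["k_nox"]]
        ph$k_nh4p <- 0.5 * draw[["k_nox"]]
      }
      ph
    }),
    grazing = utils::modifyList(base$grazing, {
      gr <- list()
      for (nm in c("g_max", "k_g", "m_z", "zeta")) {
        if (nm %in% names(draw)) gr[[nm]] <- draw[[nm]]
      }
      gr
    }),
    m_b = if ("m_b" %in% names(draw)) draw[["m_b"]] else base$m_b,
    temperature = base$temperature,
    nitrifier_temperature_exempt = base$nitrifier_temperature_exempt,
    o2 = base$o2
  )
  if (!is.null(base$experiment)) p <- apply_experiment(p, base$experiment)
  attr(p, "draw") <- draw
  attr(p, "redraws") <- redraws
  p
}

#' Run a column-model ensemble
#'
#' Integrates one column to equilibrium per member, each with its own
#' deterministic parameter draw. Members are independent: results do
#' not depend on execution order. Non-converged members are flagged
#' and excluded from the mean/s.d. envelopes.
#'
#' @param spec [ensemble_spec()].
#' @param base Base [ecosystem_params()] (including any experiment
#'   tag applied with [apply_experiment()]).
#' @param grid,physics Column configuration.
#' @param ... Passed to [integrate_to_equilibrium()] (`tolerance`,
#'   `max_time`, ...).
#' @return Object of class `ensemble_result`: `manifest` (one row per
#'   member: seed, draw, converged flag, redraws), `profiles` (n x 9 x
#'   members array, mol N/m^3), `mean` and `sd` (n x 9 matrices over
#'   converged members), `n_converged`.
#' @export
run_ensemble <- function(spec, base = ecosystem_params(),
                         grid = column_grid(), physics = physics_params(),
                         ...) {
  stopifnot(inherits(spec, "ensemble_spec"))
  m <- spec$n_members
  profiles <- array(NA_real_, c(grid$n, length(state_vars), m),
                    dimnames = list(NULL, state_vars, NULL))
  converged <- logical(m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    pars <- sample_parameters(base, spec, i)
    sol <- integrate_to_equilibrium(params = pars, grid = grid,
                                    physics = physics, ...)
    profiles[, , i] <- sol$state
    converged[i] <- sol$converged
    rows[[i]] <- data.frame(
      member = i, seed = member_seed(spec$seed, i),
      t(attr(pars, "draw")), redraws = attr(pars, "redraws"),
      converged = sol$converged, time = sol$time
    )
  }
  keep <- which(converged)
  env_mean <- apply(profiles[, , keep, drop = FALSE], c(1, 2), mean)
  env_sd <- if (length(keep) > 1) {
    apply(profiles[, , keep, drop = FALSE], c(1, 2), stats::sd)
  } else {
    matrix(0, grid$n, length(state_vars), dimnames = dimnames(env_mean))
  }
  structure(
    list(spec = spec, grid = grid, manifest = do.call(rbind, rows),
         profiles = profiles, mean = env_mean, sd = env_sd,
         n_converged = length(keep)),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble: %d members (%d converged), seed %d\n",
              x$spec$n_members, x$n_converged, x$spec$seed))
  invisible(x)
}

#' Write the ensemble manifest as CSV
#'
#' @param result An `ensemble_result`.
#' @param file Output path.
#' @return The manifest data frame, invisibly.
#' @export
write_ensemble_manifest <- function(result, file) {
  utils::write.csv(result$manifest, file, row.names = FALSE)
  invisible(result$manifest)
}
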