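config_known_keys <- list(
  top = c("name", "experiment", "grid", "physics", "ecosystem", "init",
          "integration"),
  grid = c("H", "dz"),
  physics = c("k_max", "k_min", "z_mld", "k_w", "k_chl", "i_max", "diel", "w_s"),
  ecosystem = c("f", "d", "aoo_vmax", "aoo_k_nm", "noo_volume_factor",
                "het", "phyto", "grazing", "m_b", "temperature",
                "nitrifier_temperature_exempt"),
  init = c("no3_deep", "ramp_depth", "seed_biomass"),
  integration = c("dt", "tolerance", "max_time", "check_every")
)

check_keys <- function(block, where) {
  unknown <- setdiff(names(block), config_known_keys[[where]])
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s block: %s", where,
                 paste(unknown, collapse = ", ")))
  }
  invisible(block)
}

#' Run configuration for the column model
#'
#' Assembles and validates the structured configuration that fully
#' determines a column run: grid, physics, ecosystem overrides,
#' initial condition, integration controls, and the nitrifier
#' experiment tag. Unknown keys are rejected, guarding against silent
#' parameter-name typos.
#'
#' @param name Configuration name.
#' @param experiment Nitrifier experiment tag (see
#'   [apply_experiment()]).
#' @param grid,physics,ecosystem,init,integration Named lists
#'   overriding defaults; see `nitricline:::config_known_keys` for the
#'   accepted keys (`ecosystem$aoo_k_nm` is the AOO half-saturation in
#'   nM; nested `het`/`phyto`/`grazing`/`temperature` lists override
#'   individual entries).
#' @return Object of class `run_config` (a validated nested list).
#' @export
run_config <- function(name = "custom",
                       experiment = "both_differences",
                       grid = list(), physics = list(), ecosystem = list(),
                       init = list(), integration = list()) {
  for (blk in c("grid", "physics", "ecosystem", "init", "integration")) {
    check_keys(get(blk), blk)
  }
  experiment <- match.arg(experiment, c("both_differences", "yield_only",
                                        "affinity_only", "no_difference"))
  structure(
    list(name = name, experiment = experiment, grid = grid,
         physics = physics, ecosystem = ecosystem, init = init,
         integration = integration),
    class = "run_config"
  )
}

#' Materialize the model objects described by a configuration
#'
#' @param config A [run_config()].
#' @return List with `grid`, `physics`, `params` (experiment applied),
#'   `state` (initial condition), and `integration` (control list).
#' @export
config_to_objects <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grid <- do.call(column_grid, config$grid)
  physics <- do.call(physics_params, config$physics)
  eco <- config$ecosystem
  args <- list()
  for (k in c("f", "d", "noo_volume_factor", "m_b",
              "nitrifier_temperature_exempt")) {
    if (!is.null(eco[[k]])) args[[k]] <- eco[[k]]
  }
  if (!is.null(eco$aoo_vmax) || !is.null(eco$aoo_k_nm)) {
    args$aoo_traits <- kinetic_traits(
      vmax = if (is.null(eco$aoo_vmax)) 50.8 else eco$aoo_vmax,
      k = if (is.null(eco$aoo_k_nm)) 133 else eco$aoo_k_nm,
      k_unit = "nmol_l")
  }
  base <- do.call(ecosystem_params, args)
  for (blk in c("het", "phyto", "grazing", "temperature")) {
    if (!is.null(eco[[blk]])) {
      base[[blk]] <- utils::modifyList(base[[blk]], eco[[blk]])
    }
  }
  base <- validate_ecosystem_params(base)
  params <- apply_experiment(base, config$experiment)
  state <- do.call(column_init, c(list(grid = grid), config$init))
  list(grid = grid, physics = physics, params = params, state = state,
       integration = config$integration)
}

#' Run a column configuration to equilibrium
#'
#' @param config A [run_config()] (or fixture name accepted by
#'   [fixture_config()]).
#' @param ... Overrides passed to [integrate_to_equilibrium()].
#' @return A `column_solution`.
#' @export
run_column <- function(config, ...) {
  if (is.character(config)) config <- fixture_config(config)
  obj <- config_to_objects(config)
  args <- utils::modifyList(
    c(list(params = obj$params, grid = obj$grid, physics = obj$physics,
           state = obj$state), obj$integration),
    list(...))
  sol <- do.call(integrate_to_equilibrium, args)
  sol$config <- config
  sol
}

#' Named fixture configurations
#'
#' Three reference water columns:
#' \describe{
#'  \item{subtropical_stratified}{shallow mixed layer over a deep
#'    euphotic zone — the configuration in which a primary nitrite
#'    maximum forms below the deep chlorophyll maximum.}
#'  \item{high_mixing}{mixed layer deeper than the euphotic zone
#'    (strong surface diffusivity over 150 m, winter-level
#'    irradiance): DIN and nitrifiers are swept to the surface, which
#'    holds elevated nitrite.}
#'  \item{abiotic_control}{no biomass seeded; nutrients are inert and
#'    profiles only mix.}
#' }
#'
#' @param name Fixture name.
#' @return A [run_config()].
#' @export
fixture_config <- function(name = c("subtropical_stratified", "high_mixing",
                                    "abiotic_control")) {
  name <- match.arg(name)
  switch(name,
    subtropical_stratified = run_config(name = name),
    high_mixing = run_config(
      name = name,
      physics = list(z_mld = 150, k_max = 0.2, i_max = 400)),
    abiotic_control = run_config(
      name = name,
      init = list(seed_biomass = 0))
  )
}

config_as_list <- function(config) {
  # stable plain-list form for serialization
  lapply(unclass(config), function(x) x)
}

#' Read and write run configurations (YAML)
#'
#' The write-read round trip is idempotent; unknown keys in a file are
#' rejected with the offending names.
#'
#' @param config A [run_config()].
#' @param file Path to a YAML file.
#' @return `write_run_config` returns `file` invisibly;
#'   `read_run_config` returns a validated [run_config()].
#' @export
write_run_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_as_list(config), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  raw <- yaml::read_yaml(file)
  check_keys(raw, "top")
  do.call(run_config, raw)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical YAML serialization: changes iff the
#' configuration changes.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a column solution to a directory
#'
#' Plain-text serialization: long-format `state.csv` (state profiles
#' plus chlorophyll/light/temperature), `diagnostics.csv` (rates, loss
#' rate, R* profiles), `pnm.csv` (one-row PNM metrics),
#' `convergence.log`, and `config.yaml` with provenance metadata
#' (config hash, package version, elapsed time).
#'
#' @param sol A `column_solution` (from [run_column()], so it carries
#'   its configuration).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_solution <- function(sol, dir) {
  stopifnot(inherits(sol, "column_solution"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- as.data.frame(sol)
  # full double precision so stored-run diagnostics are bit-identical
  tab$mol_m3 <- sprintf("%.17g", tab$mol_m3)
  utils::write.csv(tab, file.path(dir, "state.csv"), row.names = FALSE)
  diag <- cbind(oxidation_rate_profiles(sol),
                loss = loss_rate(sol),
                as.data.frame(rstar_profile(sol))[-1])
  utils::write.csv(diag, file.path(dir, "diagnostics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(pnm_metrics(sol)), file.path(dir, "pnm.csv"),
                   row.names = FALSE)
  conv_lines <- c(
    sprintf("converged: %s after %g days (dt = %g d, tolerance = %g /d)",
            sol$converged, sol$time, sol$dt, sol$tolerance),
    sprintf("clipped mass: %g mol N/m^2", sum(sol$clipped)),
    sprintf("t = %8.1f d   metric = %.6e /d", sol$conv$time, sol$conv$metric))
  writeLines(conv_lines, file.path(dir, "convergence.log"))
  if (!is.null(sol$config)) {
    cfg <- sol$config
    meta <- list(provenance = list(
      config_hash = config_hash(cfg),
      package_version = as.character(utils::packageVersion("nitricline")),
      elapsed_days = sol$time))
    yaml::write_yaml(c(config_as_list(cfg), meta),
                     file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read observed water-column profiles for comparison plotting
#'
#' Accepts CSV files with columns `depth` (m), `variable`, `value`,
#' and optionally `sd`, e.g. bottle measurements of [NH4+]/[NO2-] or
#' chlorophyll to overlay on model output.
#'
#' @param file CSV path.
#' @return Validated data frame with a zero `sd` column filled in if
#'   absent.
#' @export
read_observation_profiles <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("depth", "variable", "value")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("observation profile lacks columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(tab$sd)) tab$sd <- 0
  stopifnot(is.numeric(tab$depth), is.numeric(tab$value))
  tab
}

#' Recompute diagnostics for a stored run
#'
#' Reads the configuration and state written by [write_solution()],
#' reconstructs the solution object, and recomputes all derived
#' diagnostics. Because the diagnostics are deterministic functions of
#' the state and configuration, the result is identical to the
#' original run's.
#'
#' @param dir Directory written by [write_solution()].
#' @return A `column_solution` (without convergence history).
#' @export
read_solution <- function(dir) {
  raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  raw$provenance <- NULL
  check_keys(raw, "top")
  config <- do.call(run_config, raw)
  obj <- config_to_objects(config)
  tab <- utils::read.csv(file.path(dir, "state.csv"))
  state <- sapply(state_vars, function(v) tab$mol_m3[tab$variable == v])
  colnames(state) <- state_vars
  sol <- structure(
    list(state = state, grid = obj$grid, physics = obj$physics,
         params = obj$params, time = NA_real_, converged = NA,
         clipped = stats::setNames(rep(NA_real_, length(state_vars)),
                                   state_vars),
         inventory = NULL, config = config),
    class = "column_solution"
  )
  sol$env <- solution_environment(sol)
  sol$rates <- solution_rates(sol)
  sol
}
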