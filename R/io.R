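# Scenario configuration files, result serialisation and run manifests.
# Configs are YAML; tabular outputs are CSV; everything is plain text.

scenario_top_keys <- c("design", "preset", "population", "system", "release",
                       "n_reps", "horizon", "seed", "out")
population_keys <- c("fecundity", "larval_survival", "carrying_capacity",
                     "critical_population_size", "polyandry_degree",
                     "max_generations", "allee_argument")
system_keys <- c("intended_fecundity_cost", "terminator_efficiency",
                 "dominance_degree", "unintended_reproductive_cost",
                 "unintended_viability_cost", "homing_efficiency",
                 "resistance_formation", "resistance_functionality",
                 "ffsd_dr_rule", "mating_success_model")
release_keys <- c("males_per_drive", "generations")

#' Assemble a scenario from a plain list
#'
#' Validates and expands a scenario description (as parsed from a YAML
#' config) into fully resolved configuration objects. The `preset` (`"IS"`
#' or `"RS"`) expands to the drive-activity defaults; explicit `system` keys
#' override it. Unknown keys anywhere are rejected.
#'
#' @param x named list with at least `design`; optional `preset`,
#'   `population`, `system`, `release`, `n_reps`, `horizon`, `seed`, `out`.
#' @return object of class `scenario_config`: list with `design_cfg`,
#'   `pop_cfg`, `release`, `n_reps`, `horizon`, `seed`, `out`.
#' @export
as_scenario <- function(x) {
  if (is.null(x$design)) stop("scenario must name a 'design'", call. = FALSE)
  unknown <- setdiff(names(x), scenario_top_keys)
  if (length(unknown)) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_keys <- function(lst, allowed, what) {
    bad <- setdiff(names(lst), allowed)
    if (length(bad)) {
      stop("unknown ", what, " keys: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(x$population, population_keys, "population")
  check_keys(x$system, system_keys, "system")
  check_keys(x$release, release_keys, "release")

  pop_cfg <- do.call(population_config, x$population %||% list())
  design_cfg <- do.call(design_config,
                        c(list(design = x$design, preset = x$preset %||% "RS"),
                          x$system %||% list()))
  release <- do.call(release_scheme,
                     c(list(design = x$design), x$release %||% list()))
  structure(list(
    design_cfg = design_cfg,
    pop_cfg = pop_cfg,
    release = release,
    n_reps = as.integer(x$n_reps %||% 100L),
    horizon = as.integer(x$horizon %||% pop_cfg$max_generations),
    seed = as.integer(x$seed %||% 1L),
    out = x$out %||% "."
  ), class = "scenario_config")
}

#' Load a scenario configuration file
#'
#' Reads a YAML scenario file (see [as_scenario()] for the layout) and
#' returns the fully validated configuration.
#'
#' @param path path to a YAML file.
#' @return a `scenario_config` (see [as_scenario()]).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  as_scenario(x)
}

# Serialisable plain-list form of a scenario (round-trips through YAML).
scenario_to_list <- function(sc) {
  dc <- sc$design_cfg
  list(
    design = dc$design,
    preset = dc$preset,
    population = unclass(sc$pop_cfg),
    system = dc[system_keys],
    release = sc$release[c("males_per_drive", "generations")],
    n_reps = sc$n_reps,
    horizon = sc$horizon,
    seed = sc$seed,
    out = sc$out
  )
}

#' Write a scenario to a YAML file
#'
#' Inverse of [load_scenario()]: `load_scenario(write_scenario(sc, path))`
#' reproduces `sc`.
#'
#' @param sc a `scenario_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  yaml::write_yaml(scenario_to_list(sc), path)
  invisible(path)
}

#' Run a scenario
#'
#' Convenience wrapper: [run_replicates()] with all settings taken from a
#' `scenario_config`.
#'
#' @param sc a `scenario_config` (see [as_scenario()]).
#' @return a `drive_sim` result.
#' @export
run_scenario <- function(sc) {
  run_replicates(sc$design_cfg, sc$pop_cfg, release = sc$release,
                 n_reps = sc$n_reps, horizon = sc$horizon, seed = sc$seed)
}

#' Write simulation outputs
#'
#' Writes three plain-text artifacts into a directory: `trajectories.csv`
#' (one row per replicate per censused generation: population size, relative
#' size, genetic load, per-locus allele frequencies, collapse flag),
#' `summary.csv` (one row: scenario parameters, fast elimination rate, mean
#' elimination generation) and `manifest.yaml` (the fully resolved scenario
#' including the seed, sufficient to reproduce the run byte-for-byte).
#'
#' @param sim a [run_replicates()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_outputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj_path <- file.path(dir, "trajectories.csv")
  summ_path <- file.path(dir, "summary.csv")
  man_path <- file.path(dir, "manifest.yaml")

  utils::write.csv(sim$trajectories, traj_path, row.names = FALSE)
  dc <- sim$design
  summary_row <- data.frame(
    design = dc$design, preset = dc$preset,
    homing_efficiency = dc$homing_efficiency,
    resistance_formation = dc$resistance_formation,
    unintended_reproductive_cost = dc$unintended_reproductive_cost,
    unintended_viability_cost = dc$unintended_viability_cost,
    dominance_degree = dc$dominance_degree,
    terminator_efficiency = dc$terminator_efficiency,
    intended_fecundity_cost = dc$intended_fecundity_cost,
    resistance_functionality = dc$resistance_functionality,
    fecundity = sim$pop$fecundity,
    carrying_capacity = sim$pop$carrying_capacity,
    polyandry_degree = sim$pop$polyandry_degree,
    critical_population_size = sim$pop$critical_population_size,
    males_per_drive = sim$release$males_per_drive,
    n_reps = sim$n_reps, horizon = sim$horizon, seed = sim$seed,
    fast_elimination_rate = sim$fast_elimination_rate,
    mean_elimination_generation = sim$mean_elimination_generation
  )
  utils::write.csv(summary_row, summ_path, row.names = FALSE)

  sc <- structure(list(design_cfg = sim$design, pop_cfg = sim$pop,
                       release = sim$release, n_reps = sim$n_reps,
                       horizon = sim$horizon, seed = sim$seed, out = dir),
                  class = "scenario_config")
  write_scenario(sc, man_path)
  invisible(c(trajectories = traj_path, summary = summ_path,
              manifest = man_path))
}

#' Default parameter tables
#'
#' The population and per-design system parameter defaults, including the
#' ideal-system (IS) and reference-system (RS) drive-activity presets.
#'
#' @return list of two data frames, `population` and `system`.
#' @export
preset_table <- function() {
  pop <- population_config()
  dq <- derived_quantities(pop)
  population <- data.frame(
    parameter = c("fecundity", "larval_survival", "carrying_capacity",
                  "critical_population_size", "polyandry_degree",
                  "max_generations", "Rm", "Lc"),
    value = c(pop$fecundity, pop$larval_survival, pop$carrying_capacity,
              pop$critical_population_size, pop$polyandry_degree,
              pop$max_generations, dq$Rm, round(dq$Lc, 2))
  )
  num_keys <- setdiff(system_keys, c("ffsd_dr_rule", "mating_success_model"))
  per_design <- lapply(DESIGNS, function(d) {
    lapply(c("IS", "RS"), function(p) {
      cfg <- design_config(d, preset = p)
      data.frame(design = d, preset = p, parameter = num_keys,
                 value = unlist(cfg[num_keys], use.names = FALSE))
    })
  })
  system <- do.call(rbind, unlist(per_design, recursive = FALSE))
  rownames(system) <- NULL
  list(population = population, system = system)
}
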