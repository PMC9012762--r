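# Initialization and release, replicate execution, elimination summaries and
# the parameter sweeps used to characterise each design.

#' Derived demographic quantities
#'
#' `Rm = F * Ls / 2` (low-density growth rate: expected adult female
#' offspring per adult female absent competition), the critical genetic load
#' `Lc = 1 - 1/Rm` above which deterministic collapse is expected, and the
#' Beverton-Holt half-saturation constant `N50 = K / (Ls - 2/F)`.
#'
#' @param cfg a [population_config()].
#' @return list with `Rm`, `Lc` and `N50`.
#' @export
#' @examples
#' derived_quantities(population_config())  # Rm = 12, Lc ~ 0.92
derived_quantities <- function(cfg) {
  rm_ <- cfg$fecundity * cfg$larval_survival / 2
  if (rm_ <= 1) {
    warning("Rm <= 1: population is not viable even without a drive")
  }
  list(Rm = rm_,
       Lc = 1 - 1 / rm_,
       N50 = cfg$carrying_capacity / (cfg$larval_survival - 2 / cfg$fecundity))
}

#' Release scheme
#'
#' Transgenic males released into the wild population. BED designs release
#' two cohorts of single-construct homozygotes (`DD/WW` transactivator-only
#' and `WW/DD` effector-only males, `males_per_drive` each); SD designs
#' release one cohort of `WD` heterozygous males (large numbers of drive
#' homozygotes being hard to produce). The default sizes are 250 males per
#' drive for BED designs and 500 for SD designs (1% of a 50,000 population
#' in total). Releases happen at the virgin-adult stage of the listed
#' generations (default: a single release at generation 0).
#'
#' @param design one of `"ffBED"`, `"sBED"`, `"ffSD"`.
#' @param males_per_drive males released per drive construct; `NULL` gives
#'   the design default (250 for BED, 500 for SD).
#' @param generations integer vector of release generations (default 0).
#' @return an object of class `release_scheme`.
#' @export
release_scheme <- function(design = c("ffBED", "sBED", "ffSD"),
                           males_per_drive = NULL,
                           generations = 0L) {
  design <- match.arg(design)
  if (is.null(males_per_drive)) {
    males_per_drive <- if (design == "ffSD") 500L else 250L
  }
  males_per_drive <- as.integer(males_per_drive)
  if (males_per_drive < 0L) stop("males_per_drive must be >= 0", call. = FALSE)
  generations <- sort(unique(as.integer(generations)))
  if (any(generations < 0L)) stop("release generations must be >= 0", call. = FALSE)
  structure(list(design = design, males_per_drive = males_per_drive,
                 generations = generations),
            class = "release_scheme")
}

add_release <- function(state, model, release) {
  for (i in model$release_indices) {
    state$m[i] <- state$m[i] + release$males_per_drive
  }
  state
}

#' Initial population state
#'
#' At generation zero the population sits at its carrying-capacity
#' equilibrium with equal numbers of wild-type virgin females and males;
#' released transgenic males (if the scheme releases at generation 0) are
#' appended to the virgin male pool.
#'
#' @param model a [build_model()] object.
#' @param release a [release_scheme()], or `NULL` for no release.
#' @return a state list with `generation = 0` and per-genotype counts `f`, `m`.
#' @export
initialize_population <- function(model, release = NULL) {
  K <- model$pop$carrying_capacity
  f <- integer(model$n_geno)
  m <- integer(model$n_geno)
  f[model$wild_index] <- K %/% 2L
  m[model$wild_index] <- K - K %/% 2L
  state <- list(generation = 0L, f = f, m = m)
  if (!is.null(release) && 0L %in% release$generations) {
    state <- add_release(state, model, release)
  }
  state
}

#' Run a single replicate
#'
#' Simulates one population from generation 0 until collapse or the horizon.
#' The census of each generation (virgin adults, before mating) is recorded
#' together with per-locus allele frequencies and the realised genetic load
#' of the transition it initiates.
#'
#' @param model a [build_model()] object.
#' @param release a [release_scheme()] (or `NULL`).
#' @param horizon maximum number of generations to simulate.
#' @param seed integer seed for this replicate.
#' @return list with `records` (data frame, one row per censused generation),
#'   `eliminated` flag and `elimination_generation` (`NA` if never).
#' @export
run_replicate <- function(model, release = NULL,
                          horizon = model$pop$max_generations,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- initialize_population(model, release)
  n_loci <- model$n_loci
  freq_cols <- as.vector(outer(ALLELES, seq_len(n_loci),
                               function(a, l) paste0("freq_", a, "_", l)))
  nrec <- horizon + 1L
  rec <- matrix(NA_real_, nrec, 5L + 3L * n_loci)
  colnames(rec) <- c("generation", "adults", "females", "relative_size",
                     "load", freq_cols)
  eliminated <- FALSE
  elim_gen <- NA_integer_
  row <- 0L
  for (t in 0:(horizon - 1L)) {
    if (t > 0L && !is.null(release) && t %in% release$generations) {
      state <- add_release(state, model, release)
    }
    cr <- census_record(state, model)
    row <- row + 1L
    rec[row, ] <- c(t, cr$adults, cr$females, cr$relative_size, NA,
                    as.vector(t(cr$freqs)))
    step <- generation_step(state, model)
    rec[row, "load"] <- step$load
    if (step$collapsed) {
      eliminated <- TRUE
      elim_gen <- t + 1L
      break
    }
    state <- step$state
  }
  if (!eliminated) {
    cr <- census_record(state, model)
    row <- row + 1L
    rec[row, ] <- c(horizon, cr$adults, cr$females, cr$relative_size, NA,
                    as.vector(t(cr$freqs)))
  }
  records <- as.data.frame(rec[seq_len(row), , drop = FALSE])
  records$collapsed <- FALSE
  if (eliminated) {
    # terminal row: the collapse generation, population gone
    terminal <- records[nrow(records), ]
    terminal$generation <- elim_gen
    terminal$adults <- 0
    terminal$females <- 0
    terminal$relative_size <- 0
    terminal$load <- NA_real_
    terminal[, grep("^freq_", names(terminal))] <- NA_real_
    terminal$collapsed <- TRUE
    records <- rbind(records, terminal)
    rownames(records) <- NULL
  }
  list(records = records, eliminated = eliminated,
       elimination_generation = elim_gen)
}

#' Run replicate simulations of one scenario
#'
#' Runs `n_reps` independent replicates (seeds derived from one root seed)
#' and summarises them: per-replicate elimination generation, the fast
#' elimination rate (percentage of replicates collapsing within the
#' horizon), the mean elimination generation among eliminated replicates,
#' and per-generation mean/min/max envelopes of population size and genetic
#' load. Eliminated replicates contribute size 0 from their collapse
#' generation onwards; their load is undefined (excluded) there.
#'
#' @param design_cfg a [design_config()].
#' @param pop_cfg a [population_config()].
#' @param release a [release_scheme()]; `NULL` gives the design default.
#' @param n_reps number of replicates (default 100).
#' @param horizon generations per replicate (default
#'   `pop_cfg$max_generations`).
#' @param seed root integer seed.
#' @return an object of class `drive_sim` with elements `trajectories`
#'   (per-replicate, per-generation data frame), `replicates` (one row per
#'   replicate), `envelope` (per-generation summary), scalar summaries and
#'   the resolved configuration.
#' @export
#' @examples
#' \donttest{
#' cfg <- design_config("sBED", preset = "IS")
#' pop <- population_config(carrying_capacity = 2000)
#' sim <- run_replicates(cfg, pop, n_reps = 5, seed = 1)
#' sim$fast_elimination_rate
#' }
run_replicates <- function(design_cfg,
                           pop_cfg = population_config(),
                           release = NULL,
                           n_reps = 100L,
                           horizon = pop_cfg$max_generations,
                           seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (is.null(release)) release <- release_scheme(design_cfg$design)
  if (release$design != design_cfg$design) {
    stop("release scheme design does not match the drive design", call. = FALSE)
  }
  model <- build_model(design_cfg, pop_cfg)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  runs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    runs[[i]] <- run_replicate(model, release, horizon, seed = rep_seeds[i])
  }

  elim <- vapply(runs, function(x) x$elimination_generation, integer(1))
  trajectories <- do.call(rbind, lapply(seq_len(n_reps), function(i) {
    cbind(replicate = i, runs[[i]]$records)
  }))

  # per-generation envelope; collapsed replicates count as size 0 afterwards
  gens <- 0:horizon
  size_mat <- matrix(0, n_reps, length(gens))
  load_mat <- matrix(NA_real_, n_reps, length(gens))
  for (i in seq_len(n_reps)) {
    r <- runs[[i]]$records
    size_mat[i, r$generation + 1L] <- r$adults
    load_mat[i, r$generation + 1L] <- r$load
  }
  envelope <- data.frame(
    generation = gens,
    mean_adults = colMeans(size_mat),
    min_adults = apply(size_mat, 2, min),
    max_adults = apply(size_mat, 2, max),
    mean_relative_size = colMeans(size_mat) / pop_cfg$carrying_capacity,
    mean_load = colMeans(load_mat, na.rm = TRUE),
    n_extant = colSums(size_mat > 0)
  )

  fast_rate <- 100 * sum(!is.na(elim) & elim <= horizon) / n_reps
  structure(list(
    design = design_cfg,
    pop = pop_cfg,
    release = release,
    n_reps = n_reps,
    horizon = horizon,
    seed = seed,
    replicates = data.frame(replicate = seq_len(n_reps),
                            eliminated = !is.na(elim),
                            elimination_generation = elim),
    trajectories = trajectories,
    envelope = envelope,
    fast_elimination_rate = fast_rate,
    mean_elimination_generation = if (any(!is.na(elim))) {
      mean(elim, na.rm = TRUE)
    } else NA_real_
  ), class = "drive_sim")
}

#' @export
print.drive_sim <- function(x, ...) {
  cat("<drive_sim> ", x$design$design, " (", x$design$preset, " activity), ",
      x$n_reps, " replicates x ", x$horizon, " generations\n", sep = "")
  cat("  fast elimination rate: ", x$fast_elimination_rate, "%\n", sep = "")
  if (!is.na(x$mean_elimination_generation)) {
    cat("  mean elimination generation: ",
        round(x$mean_elimination_generation, 2), "\n", sep = "")
  }
  invisible(x)
}

#' Mean population size over a generation window
#'
#' Average of the mean-across-replicates adult population size over an
#' inclusive generation window, with eliminated replicates counting as zero.
#'
#' @param sim a [run_replicates()] result.
#' @param from,to inclusive generation window.
#' @return mean adult count.
#' @export
mean_size_window <- function(sim, from, to) {
  e <- sim$envelope
  mean(e$mean_adults[e$generation >= from & e$generation <= to])
}

#' Mean genetic load over a generation window
#'
#' @inheritParams mean_size_window
#' @return mean realised genetic load (extant replicates only).
#' @export
mean_load_window <- function(sim, from, to) {
  e <- sim$envelope
  mean(e$mean_load[e$generation >= from & e$generation <= to], na.rm = TRUE)
}

#' Homing-efficiency x unintended-cost elimination grid
#'
#' For each combination of homing efficiency `h` and unintended fitness
#' cost `c`, sets the resistance-allele formation rate to half the
#' complement of homing (`(1 - h)/2`), sets both unintended costs to
#' `c`, runs replicates and tabulates the fast elimination rate.
#'
#' @param design drive design name.
#' @param h_values homing efficiencies.
#' @param cost_values unintended fitness costs (applied to both the
#'   reproductive and viability cost).
#' @param pop_cfg a [population_config()].
#' @param n_reps,horizon,seed passed to [run_replicates()].
#' @param ... further overrides for [design_config()].
#' @return data frame with one row per grid point.
#' @export
homing_cost_grid <- function(design, h_values, cost_values,
                             pop_cfg = population_config(),
                             n_reps = 100L, horizon = pop_cfg$max_generations,
                             seed = 1L, ...) {
  grid <- expand.grid(homing_efficiency = h_values,
                      unintended_cost = cost_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    h <- grid$homing_efficiency[i]
    cc <- grid$unintended_cost[i]
    cfg <- design_config(design,
                         homing_efficiency = h,
                         resistance_formation = (1 - h) / 2,
                         unintended_reproductive_cost = cc,
                         unintended_viability_cost = cc,
                         ...)
    sim <- run_replicates(cfg, pop_cfg, n_reps = n_reps, horizon = horizon,
                          seed = seed + i)
    data.frame(homing_efficiency = h, unintended_cost = cc,
               fast_elimination_rate = sim$fast_elimination_rate,
               mean_elimination_generation = sim$mean_elimination_generation)
  })
  do.call(rbind, res)
}

sweep_parameters <- c("dominance_degree", "fecundity", "rm",
                      "resistance_functionality", "polyandry_degree",
                      "terminator_efficiency", "critical_population_size",
                      "release_size")

#' One-parameter scenario sweep
#'
#' Runs [run_replicates()] at each value of one exposed parameter, holding
#' everything else at the given configuration. `"rm"` values are converted
#' to fecundity via `F = 2 * Rm / Ls`; `"release_size"` is the number of
#' released males per drive construct.
#'
#' @param parameter one of `"dominance_degree"`, `"fecundity"`, `"rm"`,
#'   `"resistance_functionality"`, `"polyandry_degree"`,
#'   `"terminator_efficiency"`, `"critical_population_size"`,
#'   `"release_size"`.
#' @param values numeric vector of parameter values.
#' @param design_cfg a [design_config()] used as the base scenario.
#' @param pop_cfg a [population_config()].
#' @param n_reps,horizon,seed passed to [run_replicates()].
#' @return data frame with one row per value (fast elimination rate, mean
#'   elimination generation, mean relative size over generations 16-25).
#' @export
scalar_sweep <- function(parameter, values, design_cfg,
                         pop_cfg = population_config(),
                         n_reps = 100L, horizon = pop_cfg$max_generations,
                         seed = 1L) {
  if (!parameter %in% sweep_parameters) {
    stop("unknown sweep parameter '", parameter, "'; expected one of: ",
         paste(sweep_parameters, collapse = ", "), call. = FALSE)
  }
  res <- lapply(seq_along(values), function(i) {
    v <- values[i]
    dc <- design_cfg
    pc <- pop_cfg
    release <- NULL
    if (parameter %in% c("dominance_degree", "resistance_functionality",
                         "terminator_efficiency")) {
      dc[[parameter]] <- v
      dc <- validate_design_config(dc)
    } else if (parameter == "fecundity") {
      pc$fecundity <- v
    } else if (parameter == "rm") {
      pc$fecundity <- 2 * v / pc$larval_survival
    } else if (parameter %in% c("polyandry_degree", "critical_population_size")) {
      pc[[parameter]] <- as.integer(v)
    } else if (parameter == "release_size") {
      release <- release_scheme(dc$design, males_per_drive = v)
    }
    validate_population_config(pc)
    sim <- run_replicates(dc, pc, release = release, n_reps = n_reps,
                          horizon = horizon, seed = seed + i)
    data.frame(parameter = parameter, value = v,
               fast_elimination_rate = sim$fast_elimination_rate,
               mean_elimination_generation = sim$mean_elimination_generation,
               mean_relative_size_16_25 =
                 mean_size_window(sim, 16, min(25, horizon)) /
                 pc$carrying_capacity)
  })
  do.call(rbind, res)
}
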