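# One generation of the population: mating with mate-finding Allee effect and
# terminator kills, reproduction with homing, egg mortality, Beverton-Holt
# larval survival, sex assignment, record keeping and collapse detection.

#' Population configuration
#'
#' Demographic parameters of the target population. `fecundity` is the
#' Poisson mean clutch size of an unimpaired mother; `larval_survival` the
#' density-independent larva-to-adult survival. Together they set the
#' low-density growth rate `Rm = fecundity * larval_survival / 2` (expected
#' adult female offspring per adult female absent competition), which must
#' exceed 1 for the population to be viable, and the critical genetic load
#' `Lc = 1 - 1/Rm` above which deterministic collapse is expected.
#'
#' @param fecundity expected fertile eggs per mother (Poisson mean; default 48).
#' @param larval_survival density-independent larval-to-adult survival
#'   fraction (default 0.5). Must exceed `2/fecundity`.
#' @param carrying_capacity adult population size at equilibrium (default 50000).
#' @param critical_population_size number of virgin adult males below which the
#'   mate-finding Allee effect bites; the mating-probability sigmoid is reduced
#'   by 50% at this size (default 250).
#' @param polyandry_degree maximum (and modal) number of mates per female
#'   (default 3). Mate numbers are drawn from a Poisson truncated to
#'   `1..polyandry_degree` with mean `2 * polyandry_degree` (scaled down by
#'   the Allee factor at low male numbers).
#' @param max_generations default simulation horizon in generations (36).
#' @param allee_argument which census the Allee sigmoid is evaluated on:
#'   `"adults"` (all virgin adults, default — the sigmoid takes the
#'   population size) or `"males"` (virgin adult males only, a stronger
#'   Allee effect engaging at twice the size).
#' @return an object of class `population_config`.
#' @export
#' @examples
#' population_config()
population_config <- function(fecundity = 48,
                              larval_survival = 0.5,
                              carrying_capacity = 50000,
                              critical_population_size = 250,
                              polyandry_degree = 3,
                              max_generations = 36,
                              allee_argument = c("adults", "males")) {
  allee_argument <- match.arg(allee_argument)
  cfg <- list(
    fecundity = fecundity,
    larval_survival = larval_survival,
    carrying_capacity = carrying_capacity,
    critical_population_size = critical_population_size,
    polyandry_degree = as.integer(polyandry_degree),
    max_generations = as.integer(max_generations),
    allee_argument = allee_argument
  )
  validate_population_config(cfg)
  structure(cfg, class = "population_config")
}

validate_population_config <- function(cfg) {
  if (!is.numeric(cfg$fecundity) || cfg$fecundity <= 0) {
    stop("fecundity must be positive", call. = FALSE)
  }
  if (cfg$larval_survival <= 0 || cfg$larval_survival > 1) {
    stop("larval_survival must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$larval_survival <= 2 / cfg$fecundity) {
    stop("larval_survival must exceed 2/fecundity: ",
         "the population cannot replace itself (Rm <= 1)", call. = FALSE)
  }
  if (cfg$carrying_capacity < 2) stop("carrying_capacity too small", call. = FALSE)
  if (cfg$critical_population_size < 0) {
    stop("critical_population_size must be non-negative", call. = FALSE)
  }
  if (cfg$polyandry_degree < 1L) stop("polyandry_degree must be >= 1", call. = FALSE)
  if (cfg$max_generations < 1L) stop("max_generations must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.population_config <- function(x, ...) {
  cat("<population_config>\n")
  for (nm in names(x)) cat("  ", format(nm, width = 26), x[[nm]], "\n", sep = " ")
  dq <- derived_quantities(x)
  cat("  (Rm =", signif(dq$Rm, 4), ", Lc =", signif(dq$Lc, 4),
      ", N50 =", signif(dq$N50, 6), ")\n")
  invisible(x)
}

#' Mate-finding Allee factor
#'
#' Sigmoid reduction of mating opportunity at low male abundance:
#' `1 - 1/(1 + exp(0.01 * (count - critical)))`. Equals 0.5 exactly at the
#' critical population size, saturates to 1 at large counts, and is strictly
#' increasing in `count`. Scales both the probability that a virgin female
#' achieves mating and the mean of the mate-number distribution.
#'
#' @param count virgin adult male count (non-negative).
#' @param critical critical population size.
#' @return factor in `(0, 1)`.
#' @export
#' @examples
#' allee_factor(250, 250)  # 0.5
allee_factor <- function(count, critical) {
  stopifnot(all(count >= 0))
  1 - 1 / (1 + exp(0.01 * (count - critical)))
}

#' Truncated-Poisson mate-number distribution
#'
#' Probability mass function of the number of mates per mating female: a
#' Poisson with mean `2 * P * nm` truncated to `{1, ..., P}`, where `P` is
#' the polyandry degree and `nm` the Allee factor. With `nm = 1` and
#' `P = 3` the pmf is `(0.1, 0.3, 0.6)`.
#'
#' @param P polyandry degree (integer >= 1).
#' @param nm Allee scaling of the Poisson mean, in `(0, 1]`.
#' @return numeric vector of length `P` summing to 1.
#' @export
mate_count_pmf <- function(P, nm = 1) {
  P <- as.integer(P)
  if (P < 1L) stop("polyandry degree must be >= 1", call. = FALSE)
  stopifnot(nm >= 0, nm <= 1)
  k <- seq_len(P)
  w <- stats::dpois(k, lambda = 2 * P * nm)
  if (!any(w > 0)) {         # lambda ~ 0: all mass collapses onto one mate
    w <- c(1, rep(0, P - 1L))
  }
  w / sum(w)
}

#' Sample mate numbers
#'
#' Draws `n` mate counts from the truncated-Poisson distribution of
#' [mate_count_pmf()].
#'
#' @param n number of draws.
#' @inheritParams mate_count_pmf
#' @return integer vector in `1..P`.
#' @export
sample_mate_count <- function(n, P, nm = 1) {
  pmf <- mate_count_pmf(P, nm)
  if (length(pmf) == 1L) return(rep(1L, n))
  sample.int(length(pmf), n, replace = TRUE, prob = pmf)
}

#' Beverton-Holt larval survival probability
#'
#' Compensatory density-dependent survival
#' `s(N) = Ls * N50 / (N + N50)` with
#' `N50 = K / (Ls - 2/F)`, where `N` is the larval population size, `Ls` the
#' density-independent larval survival, `F` the fecundity and `K` the
#' carrying capacity. This parameterisation has its fixed point at `K`: a
#' wild-type population of `K` adults produces about `K/2 * F` larvae whose
#' expected survivor count is again `K`.
#'
#' @param n_larvae larval population size (non-negative).
#' @param cfg a [population_config()].
#' @return survival probability in `(0, Ls]`.
#' @export
#' @examples
#' beverton_holt_survival(1.2e6, population_config())  # 1/24
beverton_holt_survival <- function(n_larvae, cfg) {
  stopifnot(all(n_larvae >= 0))
  n50 <- derived_quantities(cfg)$N50
  cfg$larval_survival * n50 / (n_larvae + n50)
}

#' Genetic load of one generation
#'
#' Reduction of the expected number of adult female offspring produced per
#' adult female in the absence of intraspecific competition:
#' `L = 1 - W / Rm` with `W = 0.5 * Ls * viable_eggs / females` (density-
#' dependent mortality excluded) and `Rm = F * Ls / 2`. Zero for an
#' unimpaired wild-type generation in expectation; 1 when all mothers are
#' sterile. Returns 1 when no virgin females are present.
#'
#' @param virgin_female_count virgin adult females at the generation census.
#' @param viable_larval_eggs eggs of the generation surviving to the larval
#'   stage (before density-dependent mortality).
#' @param cfg a [population_config()].
#' @return load in `(-Inf, 1]`; negative values arise only from Poisson noise.
#' @export
genetic_load <- function(virgin_female_count, viable_larval_eggs, cfg) {
  if (virgin_female_count < 1) return(1)
  1 - viable_larval_eggs / (cfg$fecundity * virgin_female_count)
}

# ---------------------------------------------------------------------------
# Internal model: everything per-genotype precomputed for one scenario.

#' Build a simulation model
#'
#' Precomputes, for one design and population configuration, the genotype
#' table, the offspring kernel under homing, and all per-genotype quantities
#' (mating weight, terminator kill probability, expected clutch size, egg
#' survival, allele counts) used by the aggregated life-cycle sampler.
#'
#' @param design_cfg a [design_config()].
#' @param pop_cfg a [population_config()].
#' @return an object of class `drive_model`.
#' @export
build_model <- function(design_cfg, pop_cfg = population_config()) {
  validate_design_config(design_cfg)
  validate_population_config(pop_cfg)
  n_loci <- n_loci_for(design_cfg$design)
  if (n_loci == 1L) {
    geno <- data.frame(label = LOCUS_GENOTYPES, l1 = LOCUS_GENOTYPES,
                       stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(l1 = LOCUS_GENOTYPES, l2 = LOCUS_GENOTYPES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # locus A varies fastest, matching offspring_distribution()
    geno <- data.frame(label = paste(grid$l1, grid$l2, sep = "/"),
                       l1 = grid$l1, l2 = grid$l2, stringsAsFactors = FALSE)
  }
  nG <- nrow(geno)
  h <- design_cfg$homing_efficiency
  r <- design_cfg$resistance_formation
  K1 <- locus_offspring_kernel(h, r)

  # offspring kernel as matrix: row = (gm, gf) pair, column = child genotype
  O <- matrix(0, nG * nG, nG)
  li1 <- match(geno$l1, LOCUS_GENOTYPES)
  if (n_loci == 1L) {
    for (gm in seq_len(nG)) for (gf in seq_len(nG)) {
      O[(gf - 1L) * nG + gm, ] <- K1[li1[gm], li1[gf], ]
    }
  } else {
    li2 <- match(geno$l2, LOCUS_GENOTYPES)
    child1 <- li1
    child2 <- li2
    for (gm in seq_len(nG)) for (gf in seq_len(nG)) {
      p1 <- K1[li1[gm], li1[gf], ]   # locus A child distribution
      p2 <- K1[li2[gm], li2[gf], ]   # locus B child distribution
      O[(gf - 1L) * nG + gm, ] <- p1[child1] * p2[child2]
    }
  }

  per_geno <- function(f) vapply(seq_len(nG), function(i) {
    g <- unlist(geno[i, -1], use.names = FALSE)
    f(g)
  }, numeric(1))

  kill <- per_geno(function(g) terminator_kill_probability(g, design_cfg))
  u <- design_cfg$unintended_reproductive_cost
  male_weight <- per_geno(function(g) unintended_reproductive_factor(g, u))
  fec_factor <- per_geno(function(g)
    intended_fecundity_factor(g, design_cfg) * unintended_reproductive_factor(g, u))
  egg_surv <- per_geno(function(g) egg_survival_probability(g, design_cfg))

  # allele copy counts per genotype, locus and allele (for frequency records)
  allele_counts <- array(0L, c(nG, n_loci, 3L),
                         dimnames = list(geno$label, NULL, ALLELES))
  for (i in seq_len(nG)) {
    for (l in seq_len(n_loci)) {
      a <- strsplit(geno[i, l + 1L], "", fixed = TRUE)[[1]]
      for (al in a) {
        allele_counts[i, l, al] <- allele_counts[i, l, al] + 1L
      }
    }
  }

  wild_label <- paste(rep("WW", n_loci), collapse = "/")
  release_labels <- switch(design_cfg$design,
                           ffSD = "WD",
                           ffBED = c("DD/WW", "WW/DD"),
                           sBED = c("DD/WW", "WW/DD"))

  structure(list(
    design = design_cfg,
    pop = pop_cfg,
    n_loci = n_loci,
    n_geno = nG,
    genotypes = geno$label,
    offspring_kernel = O,
    kill = kill,
    male_weight = male_weight,
    fec_lambda = pop_cfg$fecundity * fec_factor,
    egg_surv = egg_surv,
    allele_counts = allele_counts,
    wild_index = match(wild_label, geno$label),
    release_indices = match(release_labels, geno$label),
    N50 = derived_quantities(pop_cfg)$N50
  ), class = "drive_model")
}

#' @export
print.drive_model <- function(x, ...) {
  cat("<drive_model> ", x$design$design, " (", x$n_loci, " locus/loci, ",
      x$n_geno, " genotypes), K = ", x$pop$carrying_capacity, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Stages. State is a list(generation, f, m) with per-genotype integer counts
# of virgin adult females and males.

#' Mating stage of one generation
#'
#' Applies the mate-finding Allee effect, draws mating females and their
#' mate-attempt numbers, samples males uniformly with replacement for each
#' attempt, thins attempts by the male's mating success (drive-carrying
#' males fail to copulate with probability `1 - (1 - u)^d`), and (sBED)
#' applies terminator kills on successful copulations. A female becomes a
#' mother only if at least one attempt succeeds and no successful mate
#' kills her.
#'
#' All sampling is aggregated by genotype and is distributionally identical
#' to per-individual draws: the mate attempts of one female are i.i.d., so
#' her survival with `k` attempts is `s1^k` where
#' `s1 = 1 - sbar * E[kill]` is the per-attempt survival (an attempt kills
#' only if it succeeds, probability `sbar`, with a killing male); conditional
#' on survival the attempts remain i.i.d., succeeding with probability
#' `a / s1` (`a` = per-attempt probability of a successful, non-killing
#' copulation) and carrying the success- and kill-tilted father
#' distribution.
#'
#' @param state list with per-genotype counts `f` (virgin females) and `m`
#'   (virgin males).
#' @param model a [build_model()] object.
#' @return list with `n_mothers`, `mothers` (matrix genotype x realised mate
#'   count of surviving mothers with >= 1 mate) and `slot_fathers` (array
#'   genotype x mate count x father genotype of successful-mate counts), or
#'   `n_mothers = 0` when no female becomes a mother.
#' @export
mating_stage <- function(state, model) {
  nG <- model$n_geno
  P <- model$pop$polyandry_degree
  empty <- list(n_mothers = 0L, mothers = NULL, slot_fathers = NULL, allee = NA_real_)
  nM <- sum(state$m)
  nF <- sum(state$f)
  if (nM == 0L || nF == 0L) return(empty)

  allee_count <- if (model$pop$allee_argument == "males") nM else nM + nF
  cm <- allee_factor(allee_count, model$pop$critical_population_size)

  # females achieving mating
  cand <- stats::rbinom(nG, state$f, cm)
  if (sum(cand) == 0L) return(empty)

  # mate-attempt numbers per mating female, aggregated by genotype
  pk <- mate_count_pmf(P, cm)
  n_gk <- matrix(0L, nG, P)
  nz <- which(cand > 0L)
  for (g in nz) {
    n_gk[g, ] <- if (P == 1L) cand[g] else
      as.integer(stats::rmultinom(1, cand[g], pk))
  }

  # per-attempt outcome probabilities; the father distribution of a
  # successful copulation is proportional to male count x mating success in
  # both semantics, they differ only in whether an attempt can fail
  wsum <- sum(state$m * model$male_weight)
  if (wsum == 0) return(empty)           # no male can achieve mating
  q0 <- state$m * model$male_weight / wsum
  sbar <- if (model$design$mating_success_model == "attempt_failure") {
    wsum / nM                            # attempt succeeds
  } else {
    1                                    # resampling: every slot is filled
  }
  killq <- min(1, max(0, sum(q0 * model$kill)))
  kill_rate <- sbar * killq
  s1 <- 1 - kill_rate                    # attempt does not kill her
  a <- max(0, sbar - kill_rate)          # successful and non-killing

  # females surviving all their attempts, per (genotype, attempt count)
  alive <- matrix(0L, nG, P)
  for (k in seq_len(P)) {
    alive[, k] <- stats::rbinom(nG, n_gk[, k], s1 ^ k)
  }

  # realised successful-mate counts among survivors: Binomial(k, a/s1);
  # females with zero successful copulations do not become mothers
  psucc <- if (s1 > 0) min(1, a / s1) else 0
  if (psucc >= 1) {
    surv <- alive
  } else {
    surv <- matrix(0L, nG, P)            # column = number of successful mates
    for (k in seq_len(P)) {
      nz <- which(alive[, k] > 0L)
      for (g in nz) {
        kk <- tabulate(stats::rbinom(alive[g, k], k, psucc) + 1L, P + 1L)
        surv[g, ] <- surv[g, ] + kk[-1L] # drop the zero-success class
      }
    }
  }
  n_mothers <- sum(surv)
  if (n_mothers == 0L) return(empty)

  # successful-mate genotypes, i.i.d. from the kill-tilted distribution
  q <- pmax(q0 * (1 - model$kill), 0)
  if (sum(q) == 0) return(empty)
  q <- q / sum(q)
  slot_fathers <- array(0L, c(nG, P, nG))
  for (g in seq_len(nG)) {
    for (k in seq_len(P)) {
      ns <- surv[g, k] * k
      if (ns > 0L) {
        slot_fathers[g, k, ] <- as.integer(stats::rmultinom(1, ns, q))
      }
    }
  }

  list(n_mothers = n_mothers, mothers = surv, slot_fathers = slot_fathers,
       allee = cm)
}

#' Reproduction stage of one generation
#'
#' Each surviving mother produces a Poisson clutch with mean
#' `fecundity x intended fecundity factor x unintended reproductive factor`,
#' each egg taking its maternal haplotype from the mother's gamete
#' distribution and its paternal haplotype from a uniformly chosen mate
#' (mothers carry equal sperm shares from all mates). Aggregation: a Poisson
#' clutch split uniformly over k mates yields independent Poisson(lambda/k)
#' egg counts per mate slot, so eggs are drawn per (mother genotype, father
#' genotype) cell and their genotypes from the multinomial offspring kernel.
#' Unintended viability costs and resistance-allele lethality then thin the
#' eggs to viable larvae.
#'
#' @param mating result of [mating_stage()].
#' @param model a [build_model()] object.
#' @return list with per-genotype `eggs` and `viable` counts.
#' @export
reproduction_stage <- function(mating, model) {
  nG <- model$n_geno
  P <- model$pop$polyandry_degree
  eggs <- integer(nG)
  if (mating$n_mothers == 0L) {
    return(list(eggs = eggs, viable = eggs))
  }
  # expected eggs per (mother genotype, father genotype) cell
  lam <- matrix(0, nG, nG)
  for (k in seq_len(P)) {
    lam <- lam + mating$slot_fathers[, k, ] * (model$fec_lambda / k)
  }
  nz <- which(lam > 0)
  if (length(nz) > 0L) {
    cell_eggs <- stats::rpois(length(nz), lam[nz])
    O <- model$offspring_kernel
    for (i in seq_along(nz)) {
      if (cell_eggs[i] > 0L) {
        idx <- nz[i]
        gm <- (idx - 1L) %% nG + 1L
        gf <- (idx - 1L) %/% nG + 1L
        eggs <- eggs + as.integer(stats::rmultinom(1, cell_eggs[i],
                                                   O[(gf - 1L) * nG + gm, ]))
      }
    }
  }
  viable <- stats::rbinom(nG, eggs, model$egg_surv)
  list(eggs = eggs, viable = viable)
}

#' Advance the population by one generation
#'
#' Composes the mating and reproduction stages with Beverton-Holt density-
#' dependent larval survival and independent Bernoulli(1/2) sex assignment,
#' and detects collapse: the population collapses when no female becomes a
#' mother, no mother produces viable eggs, or no larva survives to become an
#' adult virgin female.
#'
#' @param state list with `generation` and per-genotype virgin adult counts
#'   `f` and `m`.
#' @param model a [build_model()] object.
#' @return list with the new `state` (or `NULL` on collapse), the realised
#'   `load` ([genetic_load()]) of the parental generation, `collapsed` flag
#'   and collapse `reason`.
#' @export
generation_step <- function(state, model) {
  nF <- sum(state$f)
  mating <- mating_stage(state, model)
  if (mating$n_mothers == 0L) {
    return(list(state = NULL, load = 1, collapsed = TRUE, reason = "no_mothers"))
  }
  rep <- reproduction_stage(mating, model)
  n_viable <- sum(rep$viable)
  load <- genetic_load(nF, n_viable, model$pop)
  if (n_viable == 0L) {
    return(list(state = NULL, load = load, collapsed = TRUE,
                reason = "no_viable_eggs"))
  }
  s <- model$pop$larval_survival * model$N50 / (n_viable + model$N50)
  adults <- stats::rbinom(model$n_geno, rep$viable, s)
  new_f <- stats::rbinom(model$n_geno, adults, 0.5)
  new_m <- adults - new_f
  if (sum(new_f) == 0L) {
    return(list(state = NULL, load = load, collapsed = TRUE,
                reason = "no_adult_females"))
  }
  list(state = list(generation = state$generation + 1L, f = new_f, m = new_m),
       load = load, collapsed = FALSE, reason = NA_character_)
}

# Census record of a state: size, relative size and per-locus allele
# frequencies among virgin adults.
census_record <- function(state, model) {
  counts <- state$f + state$m
  n <- sum(counts)
  freqs <- matrix(NA_real_, model$n_loci, 3L,
                  dimnames = list(NULL, ALLELES))
  if (n > 0L) {
    for (l in seq_len(model$n_loci)) {
      freqs[l, ] <- colSums(model$allele_counts[, l, ] * counts) / (2 * n)
    }
  }
  list(adults = n, females = sum(state$f), males = sum(state$m),
       relative_size = n / model$pop$carrying_capacity, freqs = freqs)
}
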