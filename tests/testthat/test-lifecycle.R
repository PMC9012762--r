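test_that("Allee factor matches the sigmoid and saturates correctly", {
  expect_equal(allee_factor(250, 250), 0.5)
  expect_equal(allee_factor(50000, 250), 1, tolerance = 1e-12)
  expect_equal(allee_factor(0, 250), 1 - 1 / (1 + exp(-2.5)))
  counts <- seq(0, 2000, by = 50)
  vals <- allee_factor(counts, 250)
  expect_true(all(diff(vals) > 0))            # strictly increasing
  expect_true(all(vals > 0 & vals < 1))
})

test_that("mate numbers follow a truncated Poisson with mean 2P", {
  expect_equal(mate_count_pmf(3, 1), c(0.1, 0.3, 0.6))
  expect_equal(mate_count_pmf(1, 1), 1)
  expect_equal(mate_count_pmf(2, 1), c(1, 2) / 3)
  # Allee scaling concentrates mass on a single mate
  low <- mate_count_pmf(3, 1e-3)
  expect_gt(low[1], 0.99)
  # sampled frequencies agree with the pmf
  set.seed(42)
  draws <- sample_mate_count(20000, 3, 1)
  expect_true(all(draws >= 1 & draws <= 3))
  gof <- chisq.test(tabulate(draws, 3), p = c(0.1, 0.3, 0.6))
  expect_gt(gof$p.value, 1e-4)
  expect_error(mate_count_pmf(0), ">= 1")
})

test_that("Beverton-Holt survival has the documented fixed point at K", {
  cfg <- population_config()                  # F = 48, Ls = 0.5, K = 50000
  expect_equal(derived_quantities(cfg)$N50, 50000 / (0.5 - 1 / 24))
  expect_equal(derived_quantities(cfg)$N50, 109090.909090909, tolerance = 1e-10)
  # at the equilibrium egg production (K/2 mothers x F eggs), survival is
  # exactly the rate that returns K adults
  expect_equal(beverton_holt_survival(25000 * 48, cfg), 1 / 24)
  expect_equal(beverton_holt_survival(25000 * 48, cfg) * 25000 * 48, 50000)
  # limits
  expect_equal(beverton_holt_survival(0, cfg), 0.5)
  n50 <- derived_quantities(cfg)$N50
  expect_equal(beverton_holt_survival(n50, cfg), 0.25)
  # strictly decreasing in larval density
  nn <- seq(0, 2e6, length.out = 100)
  expect_true(all(diff(beverton_holt_survival(nn, cfg)) < 0))
  expect_error(population_config(fecundity = 4, larval_survival = 0.4),
               "replace itself")
})

test_that("genetic load is zero at wild-type equilibrium and one for sterile broods", {
  cfg <- population_config()
  expect_equal(genetic_load(25000, 25000 * 48, cfg), 0)
  expect_equal(genetic_load(25000, 0, cfg), 1)
  expect_equal(genetic_load(0, 0, cfg), 1)    # degenerate: no females
  # realised load over a drive-free generation is zero in expectation
  model <- build_model(design_config("ffSD", preset = "IS"),
                       population_config(carrying_capacity = 5000))
  state <- initialize_population(model)
  set.seed(101)
  loads <- replicate(20, generation_step(state, model)$load)
  expect_lt(abs(mean(loads)), 0.01)
  expect_true(all(loads > -0.05 & loads <= 1))
})

test_that("drive-free populations fluctuate around carrying capacity", {
  pop <- population_config(carrying_capacity = 2000)
  model <- build_model(design_config("ffSD", preset = "IS"), pop)
  set.seed(7)
  finals <- replicate(15, {
    state <- initialize_population(model)
    for (t in 1:20) state <- generation_step(state, model)$state
    sum(state$f + state$m)
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 2000), 3 * se + 1)
  # allele bookkeeping: population stays purely wild type
  state <- initialize_population(model)
  for (t in 1:5) state <- generation_step(state, model)$state
  rec <- drivesim:::census_record(state, model)
  expect_equal(unname(rec$freqs[1, ]), c(1, 0, 0))
})

test_that("aggregated egg sampling matches the offspring-distribution oracle", {
  # 200 drive-heterozygous mothers x wild-type fathers, no fitness costs:
  # egg genotypes must follow the exact cross distribution
  cfg <- design_config("ffSD", preset = "IS", homing_efficiency = 0.9,
                       resistance_formation = 0.05)
  model <- build_model(cfg, population_config(carrying_capacity = 50000))
  state <- list(generation = 0L,
                f = c(0L, 200L, 0L, 0L, 0L, 0L),   # WD mothers
                m = c(100000L, 0L, 0L, 0L, 0L, 0L))
  set.seed(99)
  mating <- mating_stage(state, model)
  expect_gt(mating$n_mothers, 150)
  rep_ <- reproduction_stage(mating, model)
  eggs <- rep_$eggs
  names(eggs) <- model$genotypes
  expected <- offspring_distribution("WD", "WW", 0.9, 0.05)
  expect_equal(sum(eggs[expected == 0]), 0)
  gof <- chisq.test(eggs[expected > 0], p = expected[expected > 0])
  expect_gt(gof$p.value, 1e-4)
  # clutch sizes are Poisson(F) per mother in expectation
  expect_lt(abs(sum(eggs) / mating$n_mothers - 48), 3 * sqrt(48 / 200) + 1)
})

test_that("population collapse fires under exactly the three terminal conditions", {
  pop <- population_config(carrying_capacity = 1000)
  model <- build_model(design_config("sBED", preset = "IS"), pop)
  nG <- model$n_geno
  wt <- model$wild_index
  set.seed(3)

  # no males: no female becomes a mother
  state <- list(generation = 0L, f = replace(integer(nG), wt, 500L),
                m = integer(nG))
  step <- generation_step(state, model)
  expect_true(step$collapsed)
  expect_equal(step$reason, "no_mothers")

  # all males are full terminators with perfect efficiency: every mating
  # female is killed
  term <- design_config("sBED", preset = "IS", terminator_efficiency = 1)
  mterm <- build_model(term, pop)
  aabb <- match("DD/DD", mterm$genotypes)
  state <- list(generation = 0L,
                f = replace(integer(nG), wt, 500L),
                m = replace(integer(nG), aabb, 500L))
  step <- generation_step(state, mterm)
  expect_true(step$collapsed)
  expect_equal(step$reason, "no_mothers")

  # every mother sterile: no viable eggs
  ffbed <- build_model(design_config("ffBED", preset = "IS"), pop)
  aabb2 <- match("DD/DD", ffbed$genotypes)
  state <- list(generation = 0L,
                f = replace(integer(nG), aabb2, 500L),
                m = replace(integer(nG), wt, 500L))
  step <- generation_step(state, ffbed)
  expect_true(step$collapsed)
  expect_equal(step$reason, "no_viable_eggs")

  # a healthy wild-type population does not collapse
  state <- list(generation = 0L, f = replace(integer(nG), wt, 500L),
                m = replace(integer(nG), wt, 500L))
  step <- generation_step(state, model)
  expect_false(step$collapsed)
})

test_that("replicates are reproducible from their seed", {
  model <- build_model(design_config("sBED"),
                       population_config(carrying_capacity = 2000))
  rel <- release_scheme("sBED", 25)
  a <- run_replicate(model, rel, horizon = 10, seed = 123)
  b <- run_replicate(model, rel, horizon = 10, seed = 123)
  expect_identical(a, b)
  c <- run_replicate(model, rel, horizon = 10, seed = 124)
  expect_false(identical(a$records, c$records))
})
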