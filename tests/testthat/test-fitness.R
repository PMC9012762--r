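bed_genos <- function() {
  as.vector(outer(LOCUS_GENOTYPES, LOCUS_GENOTYPES, paste, sep = "/"))
}

test_that("dominance-scaled system effect follows the carrier classes", {
  # BED: AABB full effect, AaBb = dominance, one-homozygous = midpoint
  expect_equal(system_effect_multiplier(c("DD", "DD"), 0.6), 1)
  expect_equal(system_effect_multiplier(c("WD", "WD"), 0.6), 0.6)
  expect_equal(system_effect_multiplier(c("DD", "WD"), 0.6), 0.8)
  expect_equal(system_effect_multiplier(c("WD", "DD"), 0.6), 0.8)
  expect_equal(system_effect_multiplier(c("WD", "WW"), 0.6), 0)
  expect_equal(system_effect_multiplier(c("WW", "DD"), 0.9), 0)
  # resistance alleles count as non-drive: DR is a single-copy carrier
  expect_equal(system_effect_multiplier(c("DR", "DR"), 0.6), 0.6)
  # SD: Cc = dominance, CC = 1
  expect_equal(system_effect_multiplier("WD", 0.25), 0.25)
  expect_equal(system_effect_multiplier("DD", 0.25), 1)
  expect_equal(system_effect_multiplier("WR", 0.25), 0)
})

test_that("system effect is monotone in drive copy number at each locus", {
  for (dd in c(0, 0.3, 0.6, 1)) {
    copies_mult <- function(c1, c2) {
      lg <- c("WW", "WD", "DD")
      system_effect_multiplier(c(lg[c1 + 1], lg[c2 + 1]), dd)
    }
    for (c1 in 0:2) for (c2 in 0:1) {
      expect_gte(copies_mult(c1, c2 + 1), copies_mult(c1, c2))
      expect_gte(copies_mult(c2 + 1, c1), copies_mult(c2, c1))
    }
  }
})

test_that("terminator kill probability applies only to sBED males", {
  sbed <- design_config("sBED")   # efficiency 0.95, dominance 0.6
  expect_equal(terminator_kill_probability(c("DD", "DD"), sbed), 0.95)
  expect_equal(terminator_kill_probability(c("WD", "WD"), sbed), 0.57)
  expect_equal(terminator_kill_probability(c("WW", "WW"), sbed), 0)
  expect_equal(terminator_kill_probability(c("DD", "WW"), sbed), 0)
  ffbed <- design_config("ffBED")
  expect_equal(terminator_kill_probability(c("DD", "DD"), ffbed), 0)
  ffsd <- design_config("ffSD")
  expect_equal(terminator_kill_probability("DD", ffsd), 0)
})

test_that("intended fecundity costs follow design and dominance", {
  ffbed <- design_config("ffBED")  # cost 1, dominance 0.6
  expect_equal(intended_fecundity_factor(c("DD", "DD"), ffbed), 0)
  expect_equal(intended_fecundity_factor(c("WD", "WD"), ffbed), 0.4)
  expect_equal(intended_fecundity_factor(c("WW", "WW"), ffbed), 1)
  ffsd <- design_config("ffSD")    # cost 1, dominance 0 (haplosufficient)
  expect_equal(intended_fecundity_factor("WD", ffsd), 1)
  expect_equal(intended_fecundity_factor("DD", ffsd), 0)
  sbed <- design_config("sBED")    # intended effect via kills, not fecundity
  expect_equal(intended_fecundity_factor(c("DD", "DD"), sbed), 1)
})

test_that("unintended costs are dominant and imposed per drive", {
  expect_equal(unintended_reproductive_factor(c("DD", "WD"), 0.025), 0.950625)
  expect_equal(unintended_reproductive_factor(c("WD", "WW"), 0.025), 0.975)
  expect_equal(unintended_reproductive_factor(c("DD", "WW"), 0.025), 0.975)
  expect_equal(unintended_reproductive_factor(c("WW", "WR"), 0.025), 1)
})

test_that("egg survival combines viability costs with resistance lethality", {
  rs <- design_config("ffBED")     # v = 0.025, rho = 0
  expect_equal(egg_survival_probability(c("RR", "WW"), rs), 0)
  expect_equal(egg_survival_probability(c("WD", "WW"), rs), 0.975)
  expect_equal(egg_survival_probability(c("WW", "WW"), rs), 1)
  expect_equal(egg_survival_probability(c("WR", "DR"), rs), 0.975)
  expect_equal(egg_survival_probability(c("WD", "DR"), rs), 0.950625)
  part <- design_config("sBED", resistance_functionality = 0.4)
  expect_equal(egg_survival_probability(c("RR", "WW"), part), 0.4)
  # SD targets affect fertility, not viability: RR eggs survive
  ffsd <- design_config("ffSD")
  expect_equal(egg_survival_probability("RR", ffsd), 1)
  expect_equal(egg_survival_probability("WD", ffsd), 0.975)
})

test_that("ffSD mother fecundity reflects functional target copies", {
  cfg <- design_config("ffSD")     # cost 1, dominance 0, rho 0
  expect_equal(ffsd_fecundity_factor("WW", cfg), 1)
  expect_equal(ffsd_fecundity_factor("DD", cfg), 0)
  expect_equal(ffsd_fecundity_factor("WD", cfg), 1)
  expect_equal(ffsd_fecundity_factor("RR", cfg), 0)
  expect_equal(ffsd_fecundity_factor("WR", cfg), 1)
  # no functional copy at all: sterile under the default rule
  expect_equal(ffsd_fecundity_factor("DR", cfg), 0)
  # semidominant target disruption
  semi <- design_config("ffSD", dominance_degree = 0.25,
                        resistance_functionality = 0.4)
  expect_equal(ffsd_fecundity_factor("WD", semi), 0.75)
  expect_equal(ffsd_fecundity_factor("WR", semi), 0.25 * 0.4 + 0.75)
  expect_equal(ffsd_fecundity_factor("RR", semi), 0.4)
  # literal interpolation alternative: DR sits between DD and wild type
  lit <- design_config("ffSD", ffsd_dr_rule = "interpolate")
  expect_equal(ffsd_fecundity_factor("DR", lit), 1)
})

test_that("all fitness factors stay in [0, 1] over exhaustive genotypes", {
  cfgs <- list(design_config("sBED"), design_config("ffBED", preset = "IS"),
               design_config("sBED", resistance_functionality = 0.4,
                             dominance_degree = 1),
               design_config("ffBED", unintended_reproductive_cost = 0.3,
                             unintended_viability_cost = 0.2))
  for (cfg in cfgs) {
    for (g in bed_genos()) {
      vals <- c(system_effect_multiplier(g, cfg$dominance_degree),
                terminator_kill_probability(g, cfg),
                intended_fecundity_factor(g, cfg),
                unintended_reproductive_factor(g, cfg$unintended_reproductive_cost),
                egg_survival_probability(g, cfg))
      expect_true(all(vals >= 0 & vals <= 1))
    }
  }
  ffsd <- design_config("ffSD", dominance_degree = 0.5,
                        resistance_functionality = 0.3,
                        intended_fecundity_cost = 0.8)
  for (g in LOCUS_GENOTYPES) {
    v <- ffsd_fecundity_factor(g, ffsd)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("ideal preset carriers are cost-free apart from the intended effect", {
  cfg <- design_config("sBED", preset = "IS")
  for (g in bed_genos()) {
    expect_equal(unintended_reproductive_factor(g, cfg$unintended_reproductive_cost), 1)
    expect_equal(intended_fecundity_factor(g, cfg), 1)
    # no resistance alleles can form under IS, so rho never engages for
    # drive-bearing genotypes; only RR homozygotes (absent under IS) differ
    if (!any(as_genotype(g) == "RR")) {
      expect_equal(egg_survival_probability(g, cfg), 1)
    }
  }
})

test_that("design configuration validates parameters and expands presets", {
  rs <- design_config("sBED", preset = "RS")
  expect_equal(rs$homing_efficiency, 0.9)
  expect_equal(rs$resistance_formation, 0.05)
  expect_equal(rs$unintended_reproductive_cost, 0.025)
  is_ <- design_config("ffSD", preset = "IS")
  expect_equal(is_$homing_efficiency, 1)
  expect_equal(is_$resistance_formation, 0)
  expect_equal(is_$dominance_degree, 0)       # haplosufficient target
  expect_equal(design_config("ffBED")$dominance_degree, 0.6)
  expect_error(design_config("sBED", homing_efficiency = 1.2), "\\[0, 1\\]")
  expect_error(design_config("sBED", homing_efficiency = 0.9,
                             resistance_formation = 0.2), "exceed 1")
})
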