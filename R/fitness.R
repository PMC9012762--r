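# Intended drive effects (terminator kills, fecundity suppression) with
# dominance interpolation, dominant per-drive unintended costs, and
# resistance-allele functionality rules.

DESIGNS <- c("ffBED", "sBED", "ffSD")

# Design-specific intended-effect defaults: intended fecundity cost,
# terminator efficiency, dominance degree.
design_intended_defaults <- list(
  ffBED = list(intended_fecundity_cost = 1,    terminator_efficiency = 0,    dominance_degree = 0.6),
  sBED  = list(intended_fecundity_cost = 0,    terminator_efficiency = 0.95, dominance_degree = 0.6),
  ffSD  = list(intended_fecundity_cost = 1,    terminator_efficiency = 0,    dominance_degree = 0)
)

# Drive-activity presets: ideal system (perfect conversion, no unintended
# costs) and reference system (imperfect conversion, mild costs).
activity_presets <- list(
  IS = list(homing_efficiency = 1,   resistance_formation = 0,
            unintended_reproductive_cost = 0,     unintended_viability_cost = 0),
  RS = list(homing_efficiency = 0.9, resistance_formation = 0.05,
            unintended_reproductive_cost = 0.025, unintended_viability_cost = 0.025)
)

#' Drive system configuration
#'
#' Assembles the parameters of one drive design. `design` selects the
#' architecture: `"ffSD"` is a single female-fertility suppression drive at
#' one locus (released as `WD` heterozygous males); `"ffBED"` and `"sBED"`
#' are binary-expression double drives at two unlinked autosomal loci (locus
#' A carries the transactivator, locus B the effector), sterilising carrier
#' mothers (ffBED) or killing mated females via a seminal toxin delivered by
#' "terminator" males (sBED).
#'
#' The `preset` fills the drive-activity parameters: `"IS"` (ideal system:
#' homing 1, resistance formation 0, no unintended costs) or `"RS"`
#' (reference system: homing 0.9, resistance formation 0.05, unintended
#' reproductive and viability costs of 0.025 each). Explicit arguments
#' override the preset.
#'
#' @param design one of `"ffBED"`, `"sBED"`, `"ffSD"`.
#' @param preset drive-activity preset, `"RS"` (default) or `"IS"`.
#' @param intended_fecundity_cost relative reduction of fecundity in mothers
#'   expressing the full system effect (defaults: ffBED 1, sBED 0, ffSD 1).
#' @param terminator_efficiency probability that a female mated by a
#'   full-effect sBED terminator male dies after mating (default 0.95 for
#'   sBED, 0 otherwise).
#' @param dominance_degree fraction of the full system effect experienced by
#'   double (or single-locus) drive heterozygotes (defaults: BED designs
#'   0.6, ffSD 0).
#' @param unintended_reproductive_cost dominant per-drive reduction of female
#'   fecundity and male mating success.
#' @param unintended_viability_cost dominant per-drive probability that a
#'   drive-carrying egg dies before hatching.
#' @param homing_efficiency probability that the wild-type target is
#'   converted to a drive allele during gametogenesis in `WD` heterozygotes.
#' @param resistance_formation probability that it is converted to a
#'   cleavage-resistant allele instead.
#' @param resistance_functionality relative functionality of resistance
#'   alleles (0 = fully nonfunctional, the default). In BED designs the
#'   probability that an egg homozygous for resistance alleles at either
#'   locus develops into a larva; in ffSD the fraction of fecundity retained
#'   by resistance-homozygous mothers.
#' @param mating_success_model how the unintended cost on male mating
#'   success enters the mating process: `"resampling"` (default) treats it
#'   as a relative sampling weight (every mate slot of a female is filled,
#'   drive-carrying males are simply drawn less often); `"attempt_failure"`
#'   treats it as an absolute per-copulation failure probability (a drawn
#'   drive-carrying male fails to copulate with probability `1 - (1-u)^d`,
#'   so females can realise fewer mates than drawn, possibly none).
#' @param ffsd_dr_rule fecundity rule for ffSD drive/resistance (`DR`)
#'   heterozygous mothers: `"functional_copies"` (default) interpolates
#'   between the fecundities implied by each allele's target-gene
#'   functionality (so a `DR` mother with a fully disruptive drive and
#'   nonfunctional resistance allele is sterile); `"interpolate"`
#'   interpolates between the drive-homozygote and wild-type fecundities by
#'   the dominance degree (under which `DR` mothers are fully fertile when
#'   the target is haplosufficient).
#' @return an object of class `design_config` (a named list).
#' @export
#' @examples
#' design_config("sBED", preset = "RS")
#' design_config("ffSD", preset = "IS", dominance_degree = 0.25)
design_config <- function(design = c("ffBED", "sBED", "ffSD"),
                          preset = c("RS", "IS"),
                          intended_fecundity_cost = NULL,
                          terminator_efficiency = NULL,
                          dominance_degree = NULL,
                          unintended_reproductive_cost = NULL,
                          unintended_viability_cost = NULL,
                          homing_efficiency = NULL,
                          resistance_formation = NULL,
                          resistance_functionality = 0,
                          ffsd_dr_rule = c("functional_copies", "interpolate"),
                          mating_success_model = c("resampling", "attempt_failure")) {
  design <- match.arg(design)
  preset <- match.arg(preset)
  ffsd_dr_rule <- match.arg(ffsd_dr_rule)
  mating_success_model <- match.arg(mating_success_model)
  intended <- design_intended_defaults[[design]]
  act <- activity_presets[[preset]]
  cfg <- list(
    design = design,
    preset = preset,
    intended_fecundity_cost = intended_fecundity_cost %||% intended$intended_fecundity_cost,
    terminator_efficiency = terminator_efficiency %||% intended$terminator_efficiency,
    dominance_degree = dominance_degree %||% intended$dominance_degree,
    unintended_reproductive_cost = unintended_reproductive_cost %||% act$unintended_reproductive_cost,
    unintended_viability_cost = unintended_viability_cost %||% act$unintended_viability_cost,
    homing_efficiency = homing_efficiency %||% act$homing_efficiency,
    resistance_formation = resistance_formation %||% act$resistance_formation,
    resistance_functionality = resistance_functionality,
    ffsd_dr_rule = ffsd_dr_rule,
    mating_success_model = mating_success_model
  )
  validate_design_config(cfg)
  structure(cfg, class = "design_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_design_config <- function(cfg) {
  num <- c("intended_fecundity_cost", "terminator_efficiency", "dominance_degree",
           "unintended_reproductive_cost", "unintended_viability_cost",
           "homing_efficiency", "resistance_formation", "resistance_functionality")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("design parameter '", nm, "' must be a single value in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$homing_efficiency + cfg$resistance_formation > 1) {
    stop("homing_efficiency + resistance_formation must not exceed 1", call. = FALSE)
  }
  if (!cfg$design %in% DESIGNS) stop("unknown design '", cfg$design, "'", call. = FALSE)
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config> ", x$design, " (activity preset ", x$preset, ")\n", sep = "")
  flds <- setdiff(names(x), c("design", "preset"))
  for (nm in flds) cat("  ", format(nm, width = 30), x[[nm]], "\n", sep = " ")
  invisible(x)
}

n_loci_for <- function(design) if (design == "ffSD") 1L else 2L

#' Dominance-scaled intended system effect
#'
#' Fraction of the full intended effect (terminator efficiency or intended
#' fecundity cost) expressed by a genotype. BED designs require both the
#' transactivator and the effector: the multiplier is 0 if either locus
#' lacks a drive allele, `dominance` for double heterozygotes (one drive
#' allele at each locus), 1 for double drive homozygotes, and the arithmetic
#' midpoint `(1 + dominance)/2` when exactly one locus is drive-homozygous.
#' Single-drive designs: 0 without a drive allele, `dominance` for
#' heterozygotes, 1 for homozygotes.
#'
#' @param g genotype (see [as_genotype()]); 1 locus for SD, 2 for BED.
#' @param dominance dominance degree in `[0, 1]`.
#' @return multiplier in `[0, 1]`.
#' @export
#' @examples
#' system_effect_multiplier("DD/WD", dominance = 0.6)  # 0.8
system_effect_multiplier <- function(g, dominance) {
  stopifnot(dominance >= 0, dominance <= 1)
  g <- as_genotype(g)
  copies <- drive_copies[g]
  if (any(copies == 0L)) return(0)
  if (length(copies) == 1L) {
    return(if (copies == 2L) 1 else dominance)
  }
  n_hom <- sum(copies == 2L)
  switch(as.character(n_hom),
         "0" = dominance,
         "1" = (1 + dominance) / 2,
         "2" = 1)
}

#' Probability that a terminator male kills his mate
#'
#' In the sBED design a male carrying both system components transfers a
#' seminal toxin during copulation; a full-effect (`DD/DD`) male kills the
#' female with probability `terminator_efficiency`, scaled by the dominance
#' multiplier for partial carriers. Zero for all other designs.
#'
#' @param male male genotype.
#' @param cfg a [design_config()].
#' @return kill probability in `[0, 1]`.
#' @export
terminator_kill_probability <- function(male, cfg) {
  if (cfg$design != "sBED") return(0)
  cfg$terminator_efficiency * system_effect_multiplier(male, cfg$dominance_degree)
}

#' Intended fecundity factor of a mother
#'
#' Multiplier on the expected clutch size from the intended drive effect.
#' ffBED: `1 - cost * multiplier`. ffSD: determined by the single-locus
#' fecundity table (see [ffsd_fecundity_factor()]), which reduces to
#' `1 - cost * multiplier` when no resistance allele is carried. sBED: 1
#' (its intended effect acts through mating-induced female death).
#'
#' @param mother mother genotype.
#' @param cfg a [design_config()].
#' @return fecundity multiplier in `[0, 1]`.
#' @export
intended_fecundity_factor <- function(mother, cfg) {
  switch(cfg$design,
         sBED = 1,
         ffBED = 1 - cfg$intended_fecundity_cost *
           system_effect_multiplier(mother, cfg$dominance_degree),
         ffSD = ffsd_fecundity_factor(mother, cfg))
}

#' Dominant per-drive unintended reproductive factor
#'
#' Unintended drive activity reduces female fecundity and male mating
#' success by `u` per drive carried; the cost is dominant (independent of
#' copy number) and imposed by each drive separately, giving
#' `(1 - u)^d` where `d` is the number of distinct drives carried
#' ([count_drive_types()]).
#'
#' @param g genotype.
#' @param u unintended reproductive cost in `[0, 1]`.
#' @return multiplier in `[0, 1]`.
#' @export
#' @examples
#' unintended_reproductive_factor("DD/WD", 0.025)  # (1 - 0.025)^2
unintended_reproductive_factor <- function(g, u) {
  stopifnot(u >= 0, u <= 1)
  (1 - u) ^ count_drive_types(g)
}

#' Egg survival probability to the larval stage
#'
#' Combines the dominant per-drive unintended viability cost,
#' `(1 - v)^d`, with resistance-allele lethality in BED designs: both
#' target loci are essential for embryonic development, so an egg homozygous
#' for resistance alleles at either locus survives only with probability
#' `resistance_functionality` (deleterious effects of resistance alleles are
#' recessive; heterozygotes are unaffected). In SD designs the target gene
#' affects female fertility, not viability, so only the viability cost
#' applies.
#'
#' @param egg egg genotype.
#' @param cfg a [design_config()].
#' @return survival probability in `[0, 1]`.
#' @export
egg_survival_probability <- function(egg, cfg) {
  g <- as_genotype(egg)
  s <- (1 - cfg$unintended_viability_cost) ^ count_drive_types(g)
  if (cfg$design != "ffSD" && any(g == "RR")) {
    s <- s * cfg$resistance_functionality
  }
  s
}

#' ffSD mother fecundity table
#'
#' Fecundity multiplier of an ffSD mother as a function of her single-locus
#' genotype. The target gene is essential for female fertility, and each
#' allele carries a target-gene functionality: wild type 1, drive
#' `1 - cost` (a fully disruptive drive, `cost = 1`, leaves no function),
#' resistance allele `rho` (the resistance functionality). Homozygotes
#' express their allele's functionality; a heterozygote's fecundity lies
#' between the fecundities of her better and worse allele, with the
#' dominance degree giving the closeness to the worse (affected) phenotype:
#' `fec = (1 - Dd) * max(f) + Dd * min(f)`. This reproduces the canonical
#' cases `WD -> 1 - cost * Dd` and `WR -> Dd * rho + (1 - Dd)`, and makes a
#' `DR` mother with a disruptive drive and a nonfunctional resistance allele
#' sterile (she has no functional target copy). The alternative
#' `"interpolate"` rule instead places `DR` between the drive homozygote
#' and the wild type, `Dd * (1 - cost) + (1 - Dd)`.
#'
#' @param mother single-locus mother genotype.
#' @param cfg a [design_config()] with `design = "ffSD"`.
#' @return fecundity multiplier in `[0, 1]`.
#' @export
ffsd_fecundity_factor <- function(mother, cfg) {
  stopifnot(cfg$design == "ffSD")
  g <- as_genotype(mother)
  if (length(g) != 1L) stop("ffSD genotypes have a single locus", call. = FALSE)
  cost <- cfg$intended_fecundity_cost
  dd <- cfg$dominance_degree
  rho <- cfg$resistance_functionality
  func <- c(W = 1, D = 1 - cost, R = rho)
  a <- func[strsplit(g, "", fixed = TRUE)[[1]]]
  if (g == "DR" && cfg$ffsd_dr_rule == "interpolate") {
    return(dd * (1 - cost) + (1 - dd))
  }
  unname((1 - dd) * max(a) + dd * min(a))
}
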