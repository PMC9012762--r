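---
title: "Modelling population suppression by homing gene drives and binary expression drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population suppression by homing gene drives and binary expression drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesim)
```

## The suppression problem

A homing gene drive biases its own inheritance: in a drive/wild-type
heterozygote the CRISPR nuclease cuts the wild-type target during
gametogenesis and homology-directed repair copies the drive across, so the
drive is transmitted to a fraction $(1 + h)/2 > 1/2$ of gametes, where $h$
is the *homing efficiency*. A *suppression* drive exploits this to push a
fertility-destroying allele through a pest population until the population
can no longer replace itself and collapses.

`drivesim` simulates three suppression architectures in a polyandrous,
density-regulated insect population with discrete, non-overlapping
generations:

* **ffSD** — a classic female-fertility single drive disrupting a
  haplosufficient female-fertility gene at one autosomal locus. Only
  drive-homozygous mothers lose fertility.
* **ffBED** — a *binary expression drive*: two unlinked autosomal drives,
  one carrying a transactivator, the other a transactivator-dependent toxin
  expressed in the ovary. Only mothers carrying both components are
  sterilised, so each drive alone spreads almost cost-free from rare.
* **sBED** — a binary expression drive whose effector is a seminal toxin.
  Males carrying both components become "terminators" whose ejaculate kills
  the females they mate. In a polyandrous population one terminator can kill
  several females per generation.

Each target locus carries one of three alleles — wild type (`W`), drive
(`D`) or a cleavage-resistant *resistance* allele (`R`) produced by
error-prone repair — giving six diploid states per locus and 36 genotypes
for the two-locus designs.

## Life cycle

One generation is composed of mating, reproduction, egg mortality,
density-dependent larval survival and sex assignment.

**Mating.** Every virgin female becomes a mating candidate with probability
$CM$ and draws a number of mates from a Poisson distribution with mean
$2P \cdot NM$ truncated to $\{1, \dots, P\}$, where $P$ is the polyandry
degree (default 3; the truncated pmf at $NM = 1$ is $0.1/0.3/0.6$ for
1/2/3 mates). $CM = NM$ is a mate-finding Allee sigmoid of the virgin adult
population size $N$,

$$CM = NM = 1 - \frac{1}{1 + e^{0.01\,(N - N_c)}},$$

equal to $1/2$ at the critical population size $N_c$ (default 250) and
saturating to 1 at ordinary sizes. Mates are sampled with replacement;
drive-carrying males suffer a dominant mating-success reduction
$(1-u)^d$, where $d$ is the number of distinct drives carried. In sBED,
each terminator mate kills the female after copulation with probability
(terminator efficiency) × (dominance multiplier); killed females leave no
offspring.

**Reproduction.** Each surviving mother oviposits a Poisson clutch with
mean $F$ (fecundity, default 48) times her fecundity factors: the intended
cost of the design (see below) and the unintended reproductive factor
$(1-u)^d$. Every egg samples a maternal gamete from the mother's gamete
distribution and a paternal gamete from a uniformly chosen mate (equal
sperm shares). Gamete distributions implement homing: in `WD`
heterozygotes the wild-type allele is converted to `D` with probability
$h$, to `R` with probability $r$, and segregates fairly afterwards;
resistance alleles are never re-cut.

**Egg-to-adult survival.** Drive-carrying eggs die with dominant per-drive
probability $1-(1-v)^d$. In the BED designs both target loci are essential
for embryonic development, so eggs homozygous for resistance alleles at
either locus survive only with probability $\rho$ (the resistance-allele
functionality, default 0 — fully nonfunctional, "r2", alleles). Surviving
eggs become larvae and pass Beverton–Holt density regulation with survival

$$s(N_{\text{larvae}}) = \frac{L_s N_{50}}{N_{\text{larvae}} + N_{50}},
\qquad N_{50} = \frac{K}{L_s - 2/F},$$

which has its fixed point at the carrying capacity $K$: a wild-type
population of $K$ adults produces $\approx KF/2$ larvae whose expected
survivor count is again $K$. (The denominator is the standard
Beverton–Holt form $N + N_{50}$; with this $N_{50}$ no other form admits
the equilibrium at $K$.) Sex is assigned independently with probability
1/2, and the population collapses when no female becomes a mother, no
mother produces viable eggs, or no larva survives to become an adult
virgin female.

**Summary statistics.** The low-density growth rate is
$R_m = F L_s / 2$ (12 by default) and the critical genetic load
$L_c = 1 - 1/R_m \approx 0.92$: a drive imposing a load above $L_c$
deterministically extinguishes the population. The realised genetic load
of a generation is $L = 1 - V / (F \cdot n_F)$ where $V$ is the number of
viable (pre-density-regulation) eggs and $n_F$ the number of virgin
females; it is 0 in expectation for a wild-type generation.

## Intended effects and dominance

The intended effect of a design — the terminator efficiency in sBED, the
intended fecundity cost in ffBED/ffSD — scales with the carrier class. In
BED designs the multiplier is 0 unless both loci carry a drive allele,
$D_d$ (the dominance degree) for double heterozygotes, 1 for double
homozygotes, and the arithmetic midpoint $(1+D_d)/2$ when exactly one
locus is homozygous (the drives' descriptions state only that this class
is intermediate; the midpoint is the least-informative choice). Defaults
are $D_d = 0.6$ for the BED designs (a semidominant toxin) and $D_d = 0$
for ffSD (a fully haplosufficient target).

For ffSD mothers the fecundity rule is expressed through allele
functionalities: `W` contributes 1, `D` contributes $1 - \text{cost}$, `R`
contributes $\rho$. Homozygotes express their allele's functionality and a
heterozygote lies between her better and worse allele, the dominance degree
giving the closeness to the worse:
$\text{fec} = (1 - D_d)\max(f) + D_d \min(f)$. This reproduces the
canonical cases (`WD` $\to 1 - \text{cost}\cdot D_d$, `WR` $\to D_d\rho +
(1-D_d)$) and, importantly, makes a `DR` mother sterile when the drive is
fully disruptive and the resistance allele nonfunctional — she has no
functional copy of a gene essential for female fertility. We examined the
alternative reading in which `DR` interpolates between the drive
homozygote and the wild type (available as
`design_config(ffsd_dr_rule = "interpolate")`): under a haplosufficient
target it leaves `DR` mothers fully fertile, the drive and resistance
alleles settle into a stable polymorphism with a load far below $L_c$, and
the reference ffSD never eliminates the population — inconsistent with the
behaviour this class of drive is known to show, so the functional-copies
rule is the default.

## Design decisions taken where the specification was open

* **Allee argument.** The sigmoid is evaluated on the total virgin adult
  population size (its printed argument), not on the male count alone;
  both are available via `population_config(allee_argument=)`. Simulated
  side by side, the male-count variant roughly doubles the strength of the
  Allee effect and makes the near-threshold scenarios (reduced polyandry,
  partially functional resistance) eliminate noticeably faster; the
  population-size variant reproduces the documented behaviour of those
  scenarios.
* **Mate numbers.** "Truncated between 1 and $P$" is implemented as true
  truncation (the pmf is renormalised over $\{1..P\}$). The alternative —
  censoring draws onto the bounds — concentrates 94% of mass on $P$ mates
  at $P = 3$ and makes a polyandry-2 population collapse two decades of
  generations too early; it was rejected.
* **Mating-success semantics.** The dominant unintended cost on male
  mating success is a relative sampling weight by default (every mate slot
  is filled, drive males are drawn less often). The alternative — each
  copulation attempt fails outright with probability $1-(1-u)^d$, leaving
  some females with fewer or no mates — is available as
  `design_config(mating_success_model = "attempt_failure")`; it weakens
  kill pressure near drive fixation and delays elimination in the
  reduced-polyandry regime beyond what the design is expected to show.
* **Collapse accounting.** A replicate's elimination generation is the
  index of the first generation with no mothers, no viable eggs or no
  surviving adult female; "fast elimination" counts collapse at any
  generation $\le 36$ after the release at generation 0.
* **Genetic load** is computed from realised (sampled) egg counts, not
  expectations, so it inherits Poisson noise of order
  $1/\sqrt{F \cdot n_F}$.

## Exact aggregated sampling

The simulator never loops over individuals. Three observations make
genotype-level sampling exact, not approximate:

1. A female's mate slots are independent draws from the male pool, so her
   survival probability under terminator kills with $k$ mates is $s_1^k$
   ($s_1$ = per-slot survival), and conditional on surviving, her slots
   remain i.i.d. with the kill-tilted father distribution.
2. A Poisson($\lambda$) clutch split uniformly over $k$ mates yields
   independent Poisson($\lambda/k$) egg counts per mate slot.
3. Egg genotypes for a (mother genotype, father genotype) pair are a
   multinomial draw from the exact cross distribution
   (`offspring_distribution()`), the product over unlinked loci of the
   parental gamete outer products.

Counts therefore flow through binomial, multinomial and Poisson draws per
genotype cell, and a generation costs the same whether the population has
fifty or fifty thousand individuals. The test suite verifies the
equivalence with a goodness-of-fit test of aggregated egg output against
the enumerated cross distribution.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| Fecundity $F$ | 48 | Poisson mean eggs per mother |
| Larval survival $L_s$ | 0.5 | density-independent egg-to-adult survival |
| Carrying capacity $K$ | 50,000 | adult equilibrium size |
| Critical population size $N_c$ | 250 | 50%-reduction point of the Allee sigmoid |
| Polyandry degree $P$ | 3 | maximum and modal mates per female |
| Homing efficiency $h$ | 1 (IS) / 0.9 (RS) | conversion probability in `WD` germline |
| Resistance formation $r$ | 0 (IS) / 0.05 (RS) | `W` $\to$ `R` conversion probability |
| Unintended costs $u = v$ | 0 (IS) / 0.025 (RS) | dominant per-drive reproductive/viability cost |
| Dominance degree $D_d$ | 0.6 (BED) / 0 (ffSD) | heterozygote share of the intended effect |
| Terminator efficiency | 0.95 (sBED) | kill probability of a full terminator mating |
| Intended fecundity cost | 1 (ffBED, ffSD) / 0 (sBED) | sterility of full-effect mothers |
| Resistance functionality $\rho$ | 0 | target function retained by `R` homozygotes |

The ideal system (IS) and reference system (RS) presets bundle the
drive-activity values above; releases default to 250 males per construct
for the BED designs (homozygous single-construct `DD/WW` and `WW/DD`
cohorts) and 500 `WD` heterozygous males for ffSD, at generation 0 into a
wild-type population at carrying capacity. Multi-bout release schedules
are supported (`release_scheme(generations = ...)`) but no default
scenario uses them.

## What the simulations show

```{r, eval = FALSE}
sim <- run_replicates(design_config("sBED", preset = "RS"),
                      population_config(), n_reps = 100, seed = 1)
sim$fast_elimination_rate      # 100: every replicate collapses within 36
```

With ideal drive activity all three designs eliminate the population in
every replicate. With reference activity the designs separate sharply:
sBED eliminates every replicate in ~20 generations; ffSD eliminates ~95%
of replicates a few generations later; ffBED never eliminates — it halves
the population by generation 16 and its genetic load plateaus near 0.84,
below the critical load of 0.92, because double-heterozygous mothers are
only partially sterilised and the two drives segregate away from each
other every generation. Suppression by sBED degrades gracefully with
homing efficiency and unintended costs, tolerates partially functional
resistance alleles (still ~80–85% elimination at $\rho = 0.4$), but
depends critically on polyandry: at $P = 2$ elimination slips almost
entirely past generation 36, and a monandrous population is only
suppressed to roughly half its size — a terminator male who kills his only
mate leaves no offspring, so the toxin cannot fix.

## Numerical and scale choices

Probability computations are closed-form; the only tolerances in the
package are float-epsilon clamps on probabilities entering binomial
samplers. Replicate seeds are drawn from one root seed, making batches
bit-reproducible. The test suite exercises reduced problem sizes
($K$ = 1,000–5,000, 8–30 replicates) for speed, with the headline
scenarios at full study scale ($K$ = 50,000, 100 replicates, 36–60
generations); a full-scale scenario takes a few seconds because the
aggregated sampler's cost is independent of population size.

## Limitations

The model is panmictic and unstructured: no spatial clustering, age
structure, sperm competition or sequential remating across oviposition
bouts, all of which can weaken suppression in real populations. Maternal
nuclease deposition and embryo cutting are not modelled, and the two BED
loci are assumed fully unlinked. The synthetic populations all start at a
deterministic equilibrium; real pre-release dynamics, seasonality and
migration are out of scope, so passing the packaged scenarios demonstrates
correctness of the model's arithmetic, not field efficacy of any design.
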