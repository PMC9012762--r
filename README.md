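# drivesim

Stochastic simulation of CRISPR homing gene drives for insect population
suppression.

Suppression gene drives bias their own inheritance (a drive/wild-type
heterozygote transmits the drive to a fraction (1 + *h*)/2 of gametes,
with *h* the homing efficiency) to push fertility-destroying alleles
through a pest population until the load they impose exceeds the critical
genetic load *L*<sub>c</sub> = 1 − 1/*R*<sub>m</sub> and the population
collapses. `drivesim` implements three architectures in a common
discrete-generation life cycle:

* **ffSD** — a female-fertility single drive disrupting a haplosufficient
  fertility gene (drive-homozygous mothers are sterile);
* **ffBED** — a binary expression double drive: a transactivator and a
  transactivator-dependent ovary toxin on two unlinked loci, sterilising
  only mothers that carry both components;
* **sBED** — a binary expression drive whose effector is a seminal toxin:
  double-carrier "terminator" males kill the females they mate, which is
  especially potent in polyandrous populations.

The life cycle couples homing and resistance-allele formation during
gametogenesis, dominance-scaled intended effects, dominant per-drive
unintended fitness costs, truncated-Poisson polyandry, a mate-finding
Allee effect (a sigmoid halving mating opportunity at the critical
population size), Beverton–Holt density-dependent larval survival
(*s* = *L*<sub>s</sub>*N*<sub>50</sub>/(*N* + *N*<sub>50</sub>),
*N*<sub>50</sub> = *K*/(*L*<sub>s</sub> − 2/*F*)), and collapse
detection. All sampling is aggregated by genotype and exactly equivalent
to per-individual draws, so a generation costs the same at *K* = 50,000
as at *K* = 500. See the vignette
(`vignettes/gene-drive-suppression.Rmd`) for the full model description.

## Worked example

A reference-activity seminal drive released into a small population
(25 males per construct into 5,000 adults, 0.5% of carrying capacity):

```r
library(drivesim)

cfg <- design_config("sBED", preset = "RS")   # h = 0.9, r = 0.05, u = v = 0.025
pop <- population_config(carrying_capacity = 5000)
sim <- run_replicates(cfg, pop, release = release_scheme("sBED", 25),
                      n_reps = 20, seed = 42)
sim
#> <drive_sim> sBED (RS activity), 20 replicates x 36 generations
#>   fast elimination rate: 100%
#>   mean elimination generation: 18.65

derived_quantities(pop)
#> $Rm  12        expected daughters per female at low density
#> $Lc  0.9166667 critical genetic load
#> $N50 10909.09  Beverton-Holt half-saturation constant

subset(sim$envelope, generation %in% c(0, 5, 10, 14, 16, 18))
#>  generation mean_adults min_adults max_adults mean_relative_size mean_load n_extant
#>           0     5050.00       5050       5050              1.010     0.000       20
#>           5     5034.30       4910       5146              1.007     0.022       20
#>          10     4723.95       4529       4859              0.945     0.646       20
#>          14     1247.05        497       2165              0.249     0.959       20
#>          16      240.60          0        749              0.048     0.970       19
#>          18       51.65          0        286              0.010     0.982       11
```

Every replicate collapses (fast elimination rate 100%, i.e. within 36
generations), on average at generation 18.65. The envelope shows why: the
drives spread quietly for ~8 generations, the genetic load (reduction in
per-female reproductive output) then crosses the critical value 0.92
around generation 12–14, and the population falls from near carrying
capacity to extinction in a handful of generations, accelerated by the
Allee effect below ~250 adults.

Scenario files (YAML) and CSV outputs are supported through
`load_scenario()` / `run_scenario()` / `write_outputs()`, and a thin CLI
lives at `inst/cli/drivesim.R`:

```sh
Rscript inst/cli/drivesim.R run --config inst/extdata/example-scenario.yaml
Rscript inst/cli/drivesim.R sweep --design sBED --parameter polyandry_degree \
    --values 1,2,3 --reps 20
Rscript inst/cli/drivesim.R presets
```

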