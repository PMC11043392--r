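# patriseg

Forward-time, agent-based simulation of **patrilineal segmentary systems**
and their footprint on uniparental genetic diversity.

## The problem

Y-chromosome surveys show that male effective population size collapsed
worldwide a few millennia after the transition to agro-pastoral
subsistence, while the mtDNA-based female effective size kept growing. One
proposed driver is warfare between patrilineal kin groups; an alternative
is the internal demography of *segmentary* patrilineal systems themselves:
descent groups that differ in reproductive success, transmit that success
to daughter groups, split along paternal lines when they grow large, and
go extinct by chance. Because men of one group share recent paternal
ancestry, group extinction prunes whole Y-chromosome clades while barely
touching mtDNA.

`patriseg` is for population geneticists and quantitative anthropologists
who want to simulate these dynamics explicitly and measure their genetic
consequences. It models villages of monogamous (optionally polygynous)
couples with sex-biased migration, descent-group exogamy, group-level
fitness transmission, random or lineal fission, optional violent
competition, and post-fission group migration. Every individual's parent
links are recorded, so Y and mtDNA gene trees of any sample are extracted
exactly from the pedigree, grafted onto a coalescent model of the
pre-structure population, and dressed with mutations.

The core statistic is nucleotide diversity converted to effective size for
a haploid marker:

    Ne_Y  = pi_Y  / (2 * mu_Y)        mu_Y  = 2.5e-8 /site/generation, 1 Mb
    Ne_mt = pi_mt / (2 * mu_mt)       mu_mt = 5.5e-7 /site/generation, 10 kb

with the male **reduction factor** defined as 750 (the founder male count)
divided by the mean within-village `Ne_Y` at the generation of interest,
and the female-to-male ratio `Ne_mt / Ne_Y` tracked over time with BCa
bootstrap confidence intervals across replicates.

## Worked example

Ten replicates of the strongest non-violent scenario — patrilineal
descent, lineal fission, transmitted variance in group reproductive
success ("2g") — against the bilateral control ("1"):

```r
library(patriseg)

ctrl <- run_scenario("1",  n_replicates = 10, seed = 1)
seg  <- run_scenario("2g", n_replicates = 10, seed = 1)

ctrl$summary$male_reduction_factor
#> [1] 1.435583
seg$summary$male_reduction_factor
#> [1] 19.49384
round(subset(seg$summary$per_generation,
             select = c(generation, ne_Y_mean, ne_mt_mean, ratio)), 1)
#>   generation ne_Y_mean ne_mt_mean ratio
#> 1          0     742.6      945.2   1.3
#> 2         20     537.1      917.6   1.7
#> 3         40     303.0      889.9   2.9
#> 4         60     100.6      961.3   9.6
#> 5         80      55.7      926.4  16.6
#> 6        100      38.5      970.4  25.2
seg$demography
#> <group_demography>
#>   mean growth rate of successful groups: 0.124 per generation
#>   extinction rate: 2.83% per group per generation
#>   1433 fissions, 1041 extinctions over 36816 group-generations
```

Reading: in the bilateral control a century of patrilocality leaves the
male effective size near 750/1.44 ≈ 520, while under segmentary
patrilineal dynamics it falls to ~39 — a twenty-fold reduction with *no*
violence in the model. The female effective size never declines (at 10
replicates its Monte-Carlo error is visibly wide; with 50+ replicates the
mtDNA trajectory stays flat near 750), so the female-to-male ratio climbs
past 20. The descent-group demography matches ethnographic calibration
ranges (successful groups growing ~0.12 per generation; ~3% of groups
going extinct per generation).

Single replicates, custom configurations and exports:

```r
run <- simulate_replicate("2g", seed = 7, keep_state = TRUE)
export_sample(run, "out/", formats = c("fasta", "newick", "nexus", "vcf"))
cfg <- sim_config(sigma2 = 0.2, post_fission_migration = TRUE)
```

A thin CLI wrapper ships in `inst/scripts/patriseg-run`:

```sh
Rscript inst/scripts/patriseg-run --scenario 2g --replicates 200 --seed 42 \
    --out-dir out/ --override male_mig_rate=0.02 --export
```

## Package layout

| Where | What |
|---|---|
| `R/config.R`, `R/presets.R` | validated configuration, scenario grid, phase schedules |
| `R/population.R`, `R/simulate.R` | population state, generation cycle, replicate driver |
| `R/demography.R`, `R/fission.R` | migration, exogamous pairing, fitness-weighted reproduction, polygyny, violence, random/lineal fission |
| `R/pedigree.R`, `R/genealogy.R`, `R/mutations.R` | pedigree store, coalescent initialiser, gene-tree extraction, mutation overlay, pi |
| `R/statistics.R` | Ne conversion, BCa replicate summaries, group demography |
| `R/runner.R`, `R/export.R` | seeded orchestration, CSV/JSON outputs, FASTA/Newick/NEXUS/VCF writers |

See the methods vignette (`vignettes/segmentary-dynamics.Rmd`) for the
model in full, the calibration choices, and known limitations.
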