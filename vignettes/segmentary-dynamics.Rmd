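---
title: "Segmentary patrilineal dynamics and uniparental diversity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentary patrilineal dynamics and uniparental diversity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patriseg)
```

## The question the simulator addresses

Genetic surveys of contemporary populations report a pronounced decline of
the *male* effective population size (inferred from the non-recombining Y
chromosome) a few thousand years after the spread of agro-pastoralism, while
the female effective size (from mtDNA) kept growing. `patriseg` implements
an agent-based, forward-time model to ask how much of such a sex-specific
bottleneck can be generated by *social structure alone*: villages organised
into patrilineal descent groups that practice exogamy, differ in reproductive
success, and split along paternal lines when they grow too large — with and
without violent inter-group competition.

The package simulates the full generation cycle, tracks every individual's
paternal and maternal links, extracts coalescent gene trees for sampled
individuals, overlays mutations, and converts nucleotide diversity
($\pi$) into effective sizes:

$$N_e^Y = \frac{\pi_Y}{2\mu_Y}, \qquad
  N_e^{mt} = \frac{\pi_{mt}}{2\mu_{mt}}, \qquad
  N_e^{mt/Y} = \frac{N_e^{mt}}{N_e^Y}.$$

## Population and generation cycle

The founder population holds `n_total = 1500` individuals in
`n_villages = 5` villages of `N0 = 300` with alternating sexes. Villages
grow deterministically: the cohort born at generation $t$ has size
$\mathrm{round}(N_0 e^{rt})$ per village with $r = 0.01$ per generation, a
growth rate typical of early farming populations. Generations do not
overlap. Each cycle applies, in order:

1. **Individual migration.** Under patrilocal residence 10% of females and
   0% (or 2%) of males move to a uniformly chosen other village;
   matrilocality swaps the sex bias (10% of males), multilocality moves 5%
   of each sex. In patrilineal phases a migrant joins a uniformly chosen
   descent group of the destination village.
2. **Reproduction.** Couples are monogamous and formed at the village
   level. In patrilineal phases couples practice descent-group exogamy:
   males and females of different groups are matched at random, and only
   individuals who can no longer find a cross-group partner are paired
   within their own group, so the number of singles is minimised. Each
   child then draws a father group $j$ with probability
   $$P_j = \frac{2 M_j e^{r_j}}{\sum_i 2 M_i e^{r_i}},$$
   where $M_j$ is the male count and $r_j$ the *relative fitness* of group
   $j$ in the village, and a uniformly chosen couple of that group. Sexes
   alternate male/female along a randomly permuted birth order, so the
   cohort sex ratio is balanced to within one.
3. **Violent competition** (optional). A fraction $e = 0.15$ of the male
   cohort is killed. Kills per group are
   $D_j \sim \mathrm{Poisson}\!\left(\rho \left[\sum_{i \ne j} N_i\right]
   \sqrt{N_j}\right)$ with $N$ the male counts pooled over villages and
   $\rho$ rescaled every generation so the expected total equals
   $e \times$ the male population. Per capita this targets small groups.
   Draws are truncated at the group male count; the rare shortfall against
   the 15% target is not redistributed.
4. **Fission and extinction.** A group splits when twice its male count
   exceeds `N_max = 150` and its last fission is more than 3 generations
   past (the cooldown keeps group genealogical depth near 20 generations).
   The male split fraction is drawn from a normal distribution with mean
   0.5 and variance 0.5 truncated to $[0,1]$; *random* fission samples the
   males accordingly, *lineal* fission cuts the group's internal paternal
   genealogy into complete clades (below). Females follow so that both
   daughters keep balanced sex ratios; daughters draw fresh fitnesses
   around the parent's and inherit the fission timestamp. Groups whose
   membership reaches zero are removed and logged as extinctions. With
   post-fission migration enabled, the smaller daughter relocates —
   uniformly when it is the only mover, by exchange when several villages
   fission at once.

### Relative fitness and its transmission

Group relative fitnesses are drawn at initialisation from a normal
distribution centred on $r$, and redrawn around the parent's value at every
fission, so reproductive advantage is culturally transmitted along group
lineages with noise. The dispersion parameter `sigma2` (grid 0, 0.05, 0.1,
0.2) is applied as the **standard deviation** of those draws. This is a
deliberate calibration choice: with the intermediate setting 0.1 the
simulator produces about 100 group extinctions per 100 generations, an
extinction rate near 3% per group per generation and a mean growth rate of
successful groups near 0.12–0.14 per generation — the ranges reported for
real patrilineal lines in ethnographic compilations that do not involve
warfare. Interpreting the grid values as variances (standard deviation
$\approx 0.32$ at the intermediate setting) roughly doubles the extinction
churn (about 145 extinctions per 100 generations, 6% per group-generation,
successful growth above 0.22), which falls outside those ranges; the
package therefore uses the standard-deviation reading throughout.

### Lineal fission

`lineal_partition()` rebuilds the paternal genealogy of a group's living
males from the pedigree. The top-level clades are the male-line descendants
of the children of the group MRCA (or the distinct founder patrilines when
no within-pedigree MRCA exists). Clades are packed greedily, largest first,
each clade joining the first daughter set whenever this moves the realised
male fraction closer to the drawn target; both daughter groups are
therefore unions of complete paternal clades with distinct most recent
common ancestors. A star genealogy (all
males sons of one father) carries no clade structure and degenerates to a
random split, which the result flags. The anthropological observation this
operationalises is that men stay with their paternal kin when a group
segments. Greedy packing rather than exhaustive
enumeration is a deliberate choice: it is order $k \log k$ in the number of
clades, and on realistic clade-size distributions it attains the exhaustive
optimum in the overwhelming majority of splits (the unit tests include an
exhaustive-enumeration oracle on a fixed genealogy).

### Polygyny

The optional polygyny mode (bilateral villages) draws a mating weight
$X_i \sim 1 + \mathrm{Geometric}(p = 1/2)$ for every male — support
$\{1, 2, \dots\}$, so each male has positive weight — and assigns every
female a husband with probability $X_i / \sum X$. This emulates strongly
polygynous societies in which a minority of men accumulate several wives,
and raises the male-to-female variance ratio of reproductive success well
above the monogamous baseline.

## Genealogies, the pre-structure phase, and mutations

Every individual's father and mother ids are recorded, so the Y genealogy
of any male sample and the mtDNA genealogy of any sample can be extracted
by walking the pedigree one generation at a time and merging lineages that
hit a common ancestor. Lineages still distinct among the founders are
joined through a standard neutral (Kingman) coalescent tree of the founder
lineages at constant haploid size 750 — the 750 founder males for the Y,
the 750 founder females for mtDNA. This backward initialisation replaces a
very long forward burn-in of a panmictic constant-size population: for a
neutral non-recombining locus the two are statistically equivalent
(the expected pairwise coalescence time of two founder lineages is 750
generations, giving $E[\pi_Y] = 2 \times 750 \times \mu_Y$ at $t_0$), and
it removes hours of dead compute per replicate.

Mutations are overlaid on the extracted gene tree as a Poisson process with
rate $\mu L$ per branch-generation ($\mu_Y = 2.5\times10^{-8}$ per site per
generation over $L_Y = 1\,$Mb; $\mu_{mt} = 5.5\times10^{-7}$ over
$L_{mt} = 10\,$kb). Sites follow infinite-sites bookkeeping with
Jukes–Cantor state assignment at each hit position. At the diversities
these parameters produce ($\pi \sim 10^{-5}$–$10^{-3}$) the probability of
a repeated hit is negligible, so no multi-hit correction is applied; this
matters only if the mutation rates are raised by orders of magnitude.

$\pi$ is the mean per-site pairwise difference. Within-village diversity is
averaged over the five villages before conversion to $N_e$; the global
variant pools the five village samples. Sampling uses 20 males per village
for the Y and 20 females per village for mtDNA (mtDNA is tracked through
mothers for both sexes, but the female-only sample matches the female
effective size being estimated; `measure_diversity` documents the toggle).

## Scenarios

`scenario_preset()` encodes the study grid: a bilateral patrilocal control
("1"); the eight patrilineal variants "2a"–"2h" crossing fission type
(random/lineal), fitness dispersion (0/0.1) and violence (0/0.15); the
two-transition scenarios "3a"–"3c" (100 bilateral generations under
patrilocal/multilocal/matrilocal residence, then 100 patrilineal
generations with the "2g" settings); the long-run variants "4a"–"4c"; and a
Kipsigis-like "polygyny" scenario. Migration variants (2% male migration,
post-fission migration) are configuration overrides rather than separate
presets.

## Replicate statistics

`run_scenario()` runs seeded replicates (per-replicate seeds are a pure
function of the base seed, so results do not depend on batching),
summarises per-generation means of $N_e^Y$, $N_e^{mt}$ and their ratio
with 95% bias-corrected and accelerated (BCa) bootstrap confidence
intervals over replicates (10,000 resamples by default, via the `boot`
package; degenerate all-equal samples fall back to percentile intervals),
and reports:

* the **male reduction factor**: 750 divided by the across-replicate mean
  within-village $N_e^Y$ at the final patrilineal generation (the mean is
  taken before the reciprocal);
* the **maximum female-to-male ratio**: the maximum over the 20-generation
  sampling grid of (mean $N_e^{mt}$)/(mean $N_e^Y$) — the ratio of means,
  which is robust to near-zero single-replicate $N_e^Y$ values late in
  strongly bottlenecked scenarios.

`group_demography()` reads the event and size logs: each group's growth
rate is the mean of its per-generation relative size changes over its
recorded lifetime (trajectories never straddle a fission, because fission
replaces the parent id by two daughter ids); *successful* groups are those
with a positive mean rate, and the extinction rate divides extinction
events by group-generations at risk. The growth statistic is defined per
group rather than per group-generation on purpose: pooling all positive
single-generation jumps would mostly measure demographic noise (it roughly
doubles the statistic), while the per-group mean reflects the sustained
advantage of growing lineages, which is what ethnographic growth-rate
estimates for descent groups record.

## Numerical and design choices

* **Deterministic village sizes.** Village targets come from the
  continuous law $\mathrm{round}(N_0 e^{rt})$, not from iterated
  multiplication, so all villages remain equal and rounding cannot drift.
  The at-birth census satisfies this exactly; violence then removes males
  from the standing cohort.
* **Operator order.** Violence is applied to the newborn male cohort after
  reproduction and before fission checks. The widows of a generation are
  implicit: because cohorts are born sex-balanced, removing 15% of newborn
  males leaves 15% of the cohort's females without partners at the next
  pairing.
* **Exogamous matching** is implemented as bulk rejection matching:
  shuffle both sexes, accept cross-group couples, reshuffle the remainder,
  force a single cross-group couple if a round stalls, and pair
  within-group only when every remaining single belongs to one group. This
  is a vectorised equivalent of drawing couples one at a time and keeps the
  guarantee that within-group couples appear only when unavoidable.
* **Split-proportion redraws.** A drawn proportion that would leave a
  daughter group empty is redrawn (up to 50 times, then an even split is
  forced); the truncated-normal draw itself uses rejection sampling.
* **Degenerate violence.** With fewer than two groups the size-targeted
  rates vanish; the operator falls back to uniformly killing
  $\mathrm{round}(e \times \text{males})$ and flags the event.
* **RNG.** One base-R RNG stream per replicate, seeded from a
  deterministically derived per-replicate seed. All operators draw from
  that stream in a fixed order, so a `(seed, config)` pair reproduces a
  replicate bit-identically.
* **Phase transitions.** Entering a patrilineal phase partitions each
  village into three equal balanced-sex groups with fresh fitness draws and
  sets their fission timestamps to the transition generation (a
  three-generation grace period); leaving one dissolves the registry.
  Between two patrilineal phases group membership persists and fitnesses
  are redrawn under the new dispersion.

## What the generator does and does not emulate

Synthetic populations here have deterministic equal-size villages, strictly
balanced cohort sex ratios, non-overlapping generations, no age structure,
no spatial arrangement of villages, no individual-level inheritance of
status, and mutation without recombination or selection. These choices
isolate the effect of kinship structure on uniparental diversity; passing
tests therefore demonstrate the internal consistency of that mechanism, not
that real populations satisfy the model's demographic idealisations.
Coalescent-based (skyline) re-inference of $N_e$ from the exported samples
is intentionally out of scope: the package writes the FASTA/NEXUS/VCF/
Newick inputs such tools need, and stops there.

## Problem sizes used by the test-suite and acceptance runs

Monte-Carlo checks in the package run 50–75 replicates per headline
scenario and 50–100 in the acceptance script, while a full desk run
completes in minutes. The early-generation male Ne is a heavy-tailed
quantity across replicates (a single replicate whose village genealogies
retain a deep founder split can carry several times the median diversity),
so the scenarios whose checks hinge on generation-20 values use the larger
replicate counts; even so, across-replicate bootstrap intervals for these
means under-cover slightly at desk scale. Property-style checks use
down-scaled populations (five villages of 30) where exactness, not power,
is at stake. The 200-replicate scale of a full study is available through
`run_scenario()` unchanged.

## Known limitations

* The quantities that depend on the *speed* of the
  violence-driven decline are sensitive to micro-mechanics of how kills
  interact with group elimination; under the size-targeted Poisson model
  implemented here (rates $\propto [\sum_{i\ne j} N_i]\sqrt{N_j}$,
  truncated at the group male count), violence accelerates the decline
  modestly at 20 generations while matching the 100-generation outcome.
  Alternative raid-style mechanisms (annihilating whole groups up to the
  same 15% male quota) produce a faster early decline but overshoot the
  long-run bottleneck; see the package's event logs to explore these
  dynamics.
* BCa intervals need at least two distinct replicate values; degenerate
  sets fall back to percentile intervals with a warning.
* `lineal_partition()` requires the sampled males' pedigree back to the
  founders; it is not applicable to populations initialised without
  pedigree records.
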