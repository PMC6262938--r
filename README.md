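# palmflow

Gene flow, parentage and spatial genetic structure from mapped
microsatellite genotypes of natural plant populations.

`palmflow` is aimed at population geneticists working on stand-scale samples
of a long-lived plant — the motivating case is an Amazonian açaí palm
population of ~250 mapped individuals in four ontogenetic stages, genotyped
at 18 SSR loci — who want, from one dataset, the full chain of analyses that
such studies report:

* **Diversity and inbreeding** per ontogenetic stage: allele counts, rarefied
  allelic richness, private alleles, observed/expected heterozygosity, and
  the fixation index `F = 1 − Ho/HE` with a Monte Carlo permutation test of
  `F = 0` (alleles shuffled among plants within locus, Bonferroni-corrected
  across stages).
* **Spatial genetic structure** (SGS): Loiselle pairwise coancestry
  `θij`, correlograms over 10 equal-frequency distance classes with 95%
  permutation envelopes, the regression slope `bk` of `θij` on `ln(dij)`
  with a coordinate-permutation test, and the comparative intensity
  statistic `Sp = −bk / (1 − θ1)`.
* **Group coancestry and status effective size**:
  `Θ = [0.5 n (1+F) + Σi Σj≠i θij] / n²` and `Ne = 0.5/Θ`.
* **Categorical parentage** (CERVUS-style): parent-pair LOD scores with an
  error-tolerant transition model, a simulation-calibrated critical `Δ`
  (LOD gap) at 80% confidence, a mismatch cap, selfing pairs, parent-pair
  exclusion probability (Dow & Ashley), and the resulting gene-flow rates —
  selfing `s`, pollen immigration `mp`, seed immigration — plus
  pollen/seed dispersal-distance summaries, the effective pollination
  neighbourhood `Aep = 2π σp²`, and a Kolmogorov–Smirnov comparison of
  realised pollen distances with the intermate-distance distribution.
* **Neighborhood mating model**: a spatially explicit mixed-mating
  likelihood decomposing each offspring into selfing / immigrant siring /
  kernel-weighted within-plot siring with an exponential-power dispersal
  kernel `p(r) ∝ exp[−(r/a)^b]`, fitted by multi-start maximum likelihood;
  mean dispersal distance `δ = a Γ(3/b) / Γ(2/b)`.
* **A forward simulator** (`simulatePopulation()`) of mapped SSR populations
  with known pedigree and mating parameters, used throughout the tests to
  verify that every estimator recovers the truth it was fed.

The methods vignette (`vignettes/palmflow-methods.Rmd`) documents the
models, estimators, numerical conventions and their rationale.

## Worked example

Simulate a study-scale population (59 reproductive adults, 189 offspring,
18 loci, selfing 0.04, pollen immigration 0.4) and run the analyses:

```r
library(palmflow)

sim <- simulatePopulation(simulationConfig(seed = 42))
sim$data
#> GenotypeDataset: 248 individuals, 18 loci
#>   stages: immature (70), reproductive (59), seedling (59), young (60)
#>   missing calls: 1.8%

diversitySummary(sim$data, nPerm = 200, seed = 1)
#>          stage  n   k   Ar Ap    A    Ho    HE       F    F_p F_significant
#> 1 reproductive 59 160 8.86  3 8.89 0.786 0.774 -0.0156 0.3234         FALSE
#> 2     seedling 59 151 8.36  0 8.39 0.754 0.766  0.0156 0.3085         FALSE
#> 3     immature 70 159 8.64  2 8.83 0.751 0.770  0.0247 0.0547         FALSE
#> 4        young 60 153 8.45  3 8.50 0.749 0.768  0.0240 0.1045         FALSE
```

`F` is indistinguishable from zero in every stage, as it should be for a
random-mating simulation. SGS and effective size of the adults:

```r
ad <- subsetStage(sim$data, "reproductive")
co <- loiselleCoancestry(ad)
spStatistic(co, pairwiseDistances(ad), nPerm = 1000, seed = 2)
#> theta1 = 0.0050, bk = -0.00096 (p = 0.437), Sp = 0.0010

groupCoancestry(co, F = -0.0156)
#> Theta = 0.009, Ne = 58.0, Ne/n = 0.98
```

Adults were simulated unrelated, so there is no SGS (`bk` non-significant,
`Sp ≈ 0.001`) and the effective size is essentially the census size. Now
parentage and gene flow — the truth here is `s = 0.04`, `mp = 0.40`:

```r
res <- assignParentage(sim$data, parentageModel(nSim = 1000), seed = 3)
res$summary
#> offspring = 189: pairs = 100, selfed = 13, no father = 76, no parent = 0
#> s = 0.069, mp = 0.402, seed immigration = 0.000

dispersalSummaries(res, sim$data)
#> pollen: mean = 166 m, median = 121 m, sd = 145 m; Aep = 6.6 ha (radius 145 m)
#> KS vs intermate distances: D = 0.513, p = 0.00

mothers <- setNames(res$assignments$mother, res$assignments$offspring)
pre <- nmPrecompute(sim$data, mothers = mothers, errorRate = 0.01)
fitNeighborhoodModel(pre, starts = 4, seed = 4)
#> NM fit: s = 0.069, mp = 0.409, a = 254 m, b = 1.33, delta = 326 m
```

The estimated immigration rate lands on the truth (0.402 vs 0.40); the
selfing estimate (0.069 vs realised 13/189 = 0.069) matches the realised
count in this replicate. The significant KS test reflects the kernel-driven
distance dependence of mating built into this simulation (pollen kernel mean
400 m in a 1.5 km plot, so realised matings are much closer than random
intermate pairs).

`runPipeline(x, seed = 1, out = "report.json")` chains all stages and writes
a JSON report with full provenance (seeds, parameters, versions). A thin
command-line wrapper for shell use is installed at
`inst/scripts/palmflow` (e.g. `palmflow run genotypes.csv --profile default
--seed 1 --out report.json`).

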