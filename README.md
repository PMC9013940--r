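# schoolnet

Agent-based simulation of **school social network interventions for
adolescent health behavior**, with explicit gender structure. The package
is for researchers in social epidemiology and network intervention design
who want to compare *who to train as influential peers* — the top 15% of
students by betweenness, closeness, eigenvector or PageRank centrality,
or a random sample — before committing to a costly field intervention.

Three components:

1. **Gendered small-world networks.** Watts–Strogatz-style generation with
   a gender attribute per agent: ring lattice of degree *k*, gender layout
   (contiguous blocks by default), and rewiring of each edge with
   probability *p*, homophilously (same gender as the kept endpoint) with
   probability *q*. `calibrate_spec()` grid-searches (*k*, *p*, *q*,
   layout) against target structural metrics — clustering coefficient,
   average path length, link-type proportions.
2. **Contagion with gender-specific parameters.** Per tick, an
   uninfluenced agent is adopted with probability
   `1 − Π(1 − s_e)` over its influenced-neighbour links
   (*s* = 0.20 male–male, 0.25 female–female, 0.10 male–female), and
   influenced agents may fail to persevere (male 0.10, female 0.20) under
   two reversion readings (`per_tick`, `on_influence`). Runs stop at
   equilibrium, absorption, or a tick cap; summaries report diffusion
   speed (points/tick, population and per gender) and success rate.
3. **Cohort statistics.** Gender-stratified overweight/obesity prevalence
   arithmetic with exact integer reconstruction from printed percentages,
   pooled two-proportion z-tests, Pearson chi-square tests, correlations,
   and a synthetic three-round cohort generator (n = 234, 113 girls) that
   reproduces configured prevalence margins exactly.

## Worked example

```r
library(schoolnet)

# calibrate the generator against the published structural targets
cal <- calibrate_spec(n_reps = 24, seed = 1)
cal$spec
#> network_spec: n=234 (113 F / 121 M), k=6, p=0.100, q=0.00, layout=blocks
cal$achieved[1:2, ]
#>  metric      mean          sd
#>      cc 0.4413483 0.016838418
#>     apl 4.5401764 0.148318344

# replicated intervention experiment: 500 runs per seeding condition
cfg <- experiment_config(network_spec = cal$spec, seed = 1)
res <- run_experiment(cfg)
for (s in res) print(s)
#> condition random       (n=500): success 100.00%, speed 7.01, female 7.01, male 7.00 points/tick
#> condition betweenness  (n=500): success 100.00%, speed 7.26, female 7.23, male 7.28 points/tick
#> condition closeness    (n=500): success 100.00%, speed 6.18, female 6.13, male 6.22 points/tick
#> condition eigenvector  (n=500): success 100.00%, speed 5.55, female 5.51, male 5.59 points/tick
#> condition pagerank     (n=500): success 100.00%, speed 7.54, female 7.53, male 7.55 points/tick

cmp <- compare_conditions(res)
round(cmp$pooled_centrality, 2)
#>        speed speed_female   speed_male      success
#>         6.63         6.60         6.66       100.00
```

Reading: under the calibrated network (ring degree 6, 10% rewiring,
gender blocks) every run reaches essentially full adoption; PageRank
seeding spreads fastest (7.54 points of the population adopted per tick),
random seeding reaches 7.01, and the four centrality conditions pool to
6.63. `cmp$pairwise` holds Welch t-tests between conditions on the
per-replicate speeds.

Cohort side:

```r
coh <- generate_synthetic_cohort(default_cohort_config(seed = 11))
prev <- cohort_prevalence(coh)
subset(prev, gender == "female")
#>   gender   round   n count prevalence_percent
#>   female 2018.11 113    36           31.85841
#>   female 2019.11 113    36           31.85841
#>   female 2020.11 113    46           40.70796
prevalence_change(36, 46, 113)    # girls, 2019 -> 2020, percentage points
#> [1] 8.849558
two_proportion_z_test(46, 113, 57, 121)$p
#> [1] 0.3243588
```

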