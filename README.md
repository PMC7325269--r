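# rhoclock

Coalescence-age (TMRCA) estimation from rooted, mutation-annotated
phylogenies with a **time-dependent modified rho statistic**, motivated by
human mtDNA haplogroup dating.

## The problem

The classic rho statistic dates the root of a clade as the mean number of
mutations separating the sampled sequences from their common ancestral type,
divided by the mutation rate. But rho treats the sampled lineages as
independent, which they are not: in a real genealogy lineages share ancestry,
so mutations in older coalescent periods are carried by several sampled
lineages at once and the apparent substitution rate declines with depth —
the familiar time dependency of the molecular clock.

`rhoclock` implements an estimator that works period by period. The
genealogy is decomposed into **coalescent periods**: the interval during
which exactly *i* ancestral lineages exist, bounded by successive coalescent
events. With γ<sub>i</sub> the mutations accumulated during period *i*, the
per-period rho is ρ<sub>i</sub> = γ<sub>i</sub>/i and the modified rho is

> ρ<sub>m</sub> = Σ<sub>i</sub> ρ<sub>i</sub>

Because the number of extant lineages proxies the effective population size
going backward in time, the mutation rate μ applied in each internal period
is scaled by i/(i+1), leaving the germline rate untouched in the most recent
(tip) period i = n. Each period then contributes
ρ<sub>i</sub> · (1/μ) / factor<sub>i</sub> years, and the root age is the sum.
The default clock is the whole-molecule human mtDNA germline rate — one
mutation every 4651 years (1.3 × 10⁻⁸ /site/year over 16,569 bp).

The package also provides:

* Newick I/O where branch lengths are mutation counts, coalescent-period
  decomposition, and the internode-weighted apportionment of mutations on
  "isolate" branches that span several periods;
* classic diversity statistics for comparison: rho, pairwise π, segregating
  sites S;
* two uncertainty conventions: the Poisson-kiloyear rule
  (sd = √(1000 · age) years, the convention behind the published confidence
  intervals this package reproduces) and an explicit compound-Poisson
  propagation of the per-period mutation counts;
* neutral fixation probability and substitution-rate relations under
  fluctuating population size, q = (N₁/N₀)(1/N₀) and Ɵ = (N₁/N₀)·μ, with a
  backward-time inversion flag;
* a haploid Kingman coalescent simulator (piecewise population-size
  schedules, Poisson mutations) and a parameter-recovery harness.

## Worked example

The five-lineage example genealogy has four coalescent periods with
(lineages, mutations) = (2,3), (3,6), (4,2), (5,5):

```r
library(rhoclock)
fit <- rho_age(period_table(c(2, 3, 4, 5), c(3, 6, 2, 5)))
summary(fit)
```

```
Time-dependent rho age estimate

 period lineages mutations rho factor scaled_rate years_per_mutation years
      2        2         3 1.5   0.67    1.44e-04               6944 10416
      3        3         6 2.0   0.75    1.61e-04               6211 12422
      4        4         2 0.5   0.80    1.72e-04               5814  2907
      5        5         5 1.0   1.00    2.15e-04               4651  4651

Coalescence age: 30,396 +/- 5,513 years  (95% CI 19,591 - 41,201)

modified rho (rho_m): 5 over 4 periods, n = 5 lineages
rounding: table; scaling: period
sd, Poisson-kiloyear rule:  5,513 years (default convention)
sd, compound Poisson:       8,392 years (alternative)
```

Reading the table: each period's ρ<sub>i</sub> = mutations/lineages is
converted to years with a scaled rate (`factor` × 1/4651, the `scaled_rate`
column), giving an effective years-per-mutation and the period's age
contribution in the `years` column. The total, 30,396 years, is the age of
the root; the unscaled classic treatment of the same table would give
ρ<sub>m</sub> × 4651 = 23,255 years, showing how much the time-dependent
correction deepens the estimate. The default `"table"` rounding mode mirrors
hand calculation (factors to 2 decimals, rates to 3 significant figures,
years to integers); `rate_model(rounding = "exact")` skips intermediate
rounding and yields 30,425 years here (within 0.1%).

The same analysis runs from a tree or a TSV on the command line:

```sh
Rscript inst/cli/rhoclock age --periods inst/extdata/five_lineage_periods.tsv \
    --mode table --format json --no-timestamp
Rscript inst/cli/rhoclock stats --tree inst/extdata/five_lineage_tree_synthetic.nwk
Rscript inst/cli/rhoclock simulate --n 10 --reps 5 --seed 7 --out-dir scratch/sims
```

Simulation-based validation of the estimators:

```r
rec <- recovery_experiment(sim_config(n_tips = 10, Ne = 1000, reps = 2000, seed = 42))
rec   # unscaled rho_m age is unbiased for the true TMRCA under constant N
```

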