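---
title: "Dating coalescences with a time-dependent rho statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating coalescences with a time-dependent rho statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoclock)
```

## The model

`rhoclock` dates the root of a rooted genealogy whose branches carry
mutation counts. The input is either such a tree (Newick, branch lengths =
whole-molecule mutation counts) or directly a *coalescent-period table*.

Going from the tips toward the root, every coalescent event reduces the
number of extant ancestral lineages; the interval during which exactly $i$
lineages exist is the coalescent period $i$. Writing $\gamma_i$ for the
mutations accumulated across all lineages during period $i$, the per-period
rho is $\rho_i = \gamma_i / i$ — the classic rho statistic restricted to
that period — and the modified rho is $\rho_m = \sum_i \rho_i$.

Mutations accumulate along each lineage as independent Poisson processes
with rate $\mu$ (per molecule per year). In a star-like genealogy the
lineages are independent and classic rho is optimal; in a real genealogy
the deeper periods have fewer, shared lineages, and the apparent
substitution rate declines with depth. Taking the number of extant lineages
as a backward-in-time proxy for the effective population size, the rate
applied in the period with $i$ lineages is scaled by $i/(i+1)$, with the
most recent (tip) period $i = n$ left at the unscaled germline rate. Each
period contributes

$$\text{years}_i = \rho_i \cdot \frac{1}{\mu} \cdot \frac{1}{f_i},
\qquad f_i = \begin{cases} i/(i+1) & i < n \\ 1 & i = n \end{cases}$$

and the root age is the sum over periods. A closely related printed form of
the estimator sums $(i+1)/i \cdot \rho_i$ over *all* periods, which would
scale the tip period too; the worked examples this package reproduces use
the tip-period exemption, so that convention is implemented (the
`scale_factor()` documentation records it).

Assumptions worth making explicit:

* **No homoplasy.** The tree is taken at face value: each branch mutation is
  a distinct site. Pairwise differences and segregating sites are computed
  from path sums, which is only exact when multiple hits have been resolved
  upstream of this package.
* **Neutrality and a Poisson clock.** All uncertainty statements treat
  mutation counts (or the age in kiloyears) as Poisson.
* **Lineage-count-as-population-size.** The $i/(i+1)$ scaling is a
  first-order demographic correction, not a fitted demographic model.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `years_per_mutation` | 4651 | years | whole-molecule germline clock (human mtDNA) |
| `mu_per_site_per_year` | 1.3e-8 | /site/year | per-site form of the same clock |
| `sequence_length` | 16569 | bp | molecule length (human mtDNA), for per-site conversions |
| `generation_time_years` | 20 | years | metadata only; the clock is already in years |
| `rounding` | `"table"` | — | hand-calculation rounding chain vs `"exact"` |

The two rate forms are linked by
$\texttt{years\_per\_mutation} = 1/(\mu_{site} \cdot L)$; the year scalar is
authoritative when both are given. Note the published pairing of 4651 with
1.3e-8 is itself rounded ($1/(1.3\times 10^{-8} \cdot 16569) = 4642.5$), so
`rate_model()` keeps whichever form the user supplied.

## Numerical conventions

**Table rounding mode** (default) reproduces hand calculation cell by cell:
scale factors are rounded to two decimals, the scaled rate $f_i \cdot \mu$
to three significant figures, its inverse (the period's effective
years-per-mutation) to an integer, and each period's years to an integer.
All "nearest integer" roundings are half-away-from-zero, the desk
convention, not banker's rounding. **Exact mode** does none of this; on the
five-lineage worked example the two modes differ by less than 0.1%
(30,425 vs 30,396 years).

**Event ordering.** A cladogram only partially orders its coalescences: two
internal nodes on different branches of the tree can coalesce in either
order. `decompose_periods()` ranks events from most recent to most ancient
by (1) mean mutation-count distance to descendant tips, ascending, (2)
number of descendant tips, ascending, (3) smallest descendant tip label,
choosing greedily among nodes whose internal descendants are already ranked
— the greedy constraint keeps the total order consistent with the tree's
partial order even when the mutation-distance key alone would invert an
ancestor and its descendant (possible, since a parent averages over more
tips than its child). This is one deterministic, reproducible convention;
published decompositions done by hand may have ordered ambiguous events
differently, which is why the period-table TSV route is the authoritative
way to reproduce printed tables.

**Apportionment.** A branch spanning $k > 1$ periods (an *isolate*
radiating directly from a deep node) has its mutations distributed
proportionally to the mutations on the *internodes* — branches confined to
a single period — of each spanned period. When every spanned period has
zero internode mutations the allocation falls back to uniform, with a
message. Allocations are kept fractional: $\gamma_i / i$ is fractional
anyway, and re-rounding would break the conservation invariant (the
decomposition always preserves the tree's total mutation count exactly; the
last allocation is set by subtraction to keep the sum exact in floating
point).

**Plausibility window.** Under a Poisson clock at the mtDNA time scale,
tip branches confined to a single period plausibly carry roughly 0–5
mutations; `decompose_periods()` warns (but does not alter anything) when a
single-period tip branch exceeds 5.

**Degenerate inputs.** Unifurcations are collapsed into the parent branch
on read; a root branch length is ignored with a warning; a multifurcation
joining $c$ lineages drops the lineage count by $c-1$ in one event, so the
skipped lineage counts simply do not appear as periods (no zero rows are
fabricated); an all-zero-mutation tree yields age 0.

## Uncertainty

Two conventions are provided:

* **Poisson-kiloyear rule** (default): the point age expressed in kiloyears
  is treated as a Poisson mean, so $\mathrm{sd} = \sqrt{1000 \cdot
  \text{age}}$ years, and the 95% interval is $\text{age} \pm 1.96 \cdot
  \mathrm{sd}$ computed from the *integer-rounded* sd. The source material
  for this estimator states only that a Poisson confidence interval was
  used; this rule is the unique simple reading that reproduces all five
  independently printed standard deviations (ages 22,277 / 30,396 /
  112,829 / 165,610 / 37,701 years) and the printed interval bounds to the
  year — the bounds additionally pin down that the sd is rounded before the
  $\pm 1.96$ step. It is deliberately bit-compatible rather than derived
  from first principles.
* **Compound Poisson** (`uncertainty = "compound"`): each $\gamma_i$ is a
  Poisson count, the period contribution is $\gamma_i \cdot
  \mathrm{ypm}_i/i$, so $\mathrm{Var} = \sum_i \gamma_i
  (\mathrm{ypm}_i/i)^2$. This is the statistically explicit alternative; it
  is reported alongside the default in `summary()` but is *not* the
  convention behind the published intervals (it is generally wider, e.g.
  8,392 vs 5,513 years on the worked example).

The kiloyear rule has no deeper statistical justification than its
reproduction of the printed values: treating "age in kyr" as a Poisson
count is a units-dependent convention. Users wanting a defensible interval
should prefer the compound form or simulation.

## Fluctuating population size

For a haploid locus, when the effective size changes between generations
the neutral fixation probability is $q = (N_1/N_0)(1/N_0)$ and the
substitution rate is $\theta = (N_1/N_0)\,\mu$, reducing to $1/N$ and $\mu$
at constant size. Because dating looks backward from a recently expanding
population, `fluctuating_substitution_rate(..., backward = TRUE)` inverts
the ratio ($N_0/N_1$) — this is the qualitative motivation for the
$i/(i+1)$ period scaling above. Only the single-generation-step relation is
implemented: whether the ratio should compound across generations (the
product would telescope to $N_{\text{final}}/N_{\text{initial}}$) is left
open, and nothing in the estimator depends on it. $q > 1$ (extreme growth
from a tiny $N_0$) is clamped to 1 with a warning, the relation being a
first-order approximation.

## The simulator and what passing tests show

`simulate_kingman_tree()` draws a haploid Kingman coalescent: with $i$
lineages the coalescence rate is $i(i-1)/2 \cdot 1/N(t)$ per generation
($N$ = female effective size; piecewise-constant schedules supported), pairs
join uniformly at random, and each branch receives a Poisson mutation count
with mean duration$_\text{years}$ / `years_per_mutation`. Under this model
$E[\gamma_i] = i \cdot \mu \cdot E[\text{duration}_i]$, so the *unscaled*
$\rho_m$ age is an unbiased TMRCA estimator — the property the recovery
harness verifies (n = 10 tips, constant $N = 1000$, 2000 replicates, mean
within three standard errors of the analytic $2N(1-1/n)$ generations; the
replicate count and sizes are chosen to make the Monte-Carlo error a small
fraction of the effect being checked while keeping the suite quick). The
scaled estimator is, by construction, strictly deeper whenever any internal
period carries mutations.

Defaults are chosen once as realistic study conditions for the motivating
system: constant $N = 1000$ (a plausible long-term human female effective
size, and large enough that internal periods essentially always carry
mutations), generation time 20 years, one mutation per 4651 years.

What the simulator does **not** emulate: rate heterogeneity among lineages,
homoplasy/saturation, selection, recombination, sequence-level evolution,
or any fitted human demographic history. Passing recovery tests therefore
show the estimator arithmetic is faithful to the coalescent model it
assumes — not that the $i/(i+1)$ scaling recovers true ages for real mtDNA
data, whose demography is unknown. Indeed under the simulator's constant-N
conditions the scaled estimator is *biased upward* relative to truth; its
justification is empirical congruence with externally calibrated dates,
which is outside what synthetic data can establish.

## The shipped example tree

`inst/extdata/five_lineage_tree_synthetic.nwk` is a synthetic five-lineage
genealogy constructed so that its period decomposition reproduces the
worked-example table exactly ($\gamma$ = 3, 6, 2, 5 for $i$ = 2…5, total 16
mutations). A period table does not determine how mutations are shared
among lineages, and with integer branch counts the decomposition constraint
forces all 16 mutations onto single-period branches of a pectinate
topology; the resulting classic rho is $39/5 = 7.8$ (classic-rho age
36,278 years), deeper than the $\approx 4.79$ (22,277 years) associated
with the original genealogy behind the same table. The discrepancy is
documented rather than forced: matching both the table and the classic rho
would require fractional "observed" mutation counts, i.e. tuning the
fixture to a number it is supposed to test.

## Known limitations

* The event-ordering convention affects $\gamma_i$ for topologically
  ambiguous trees; use period tables when reproducing hand-built analyses.
* The default uncertainty rule is a reproduction convention, not a model.
* The scaling assumes strictly bifurcating, fully sampled coalescent
  structure between periods; multifurcations are handled but interpreted as
  single events.
* Per-site statistics assume one molecule length for the whole sample.
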