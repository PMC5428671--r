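---
title: "Niche overlap, null models and co-occurrence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche overlap, null models and co-occurrence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichenull)
```

## The problem

Spring outlets fed by karstic aquifers host two kinds of microcrustaceans:
obligate groundwater species (*stygobites*), which complete their life cycle
only in subterranean water and reach the springs by drift, and
*non-stygobites*, surface or interstitial freshwater species. How strongly
such species share space -- and whether a major hydrological disturbance
(e.g. an earthquake that raises aquifer discharge and flushes stygobites to
the outlets) changes that sharing -- can be quantified from species-by-site
abundance matrices collected in different years.

`nichenull` implements the full analysis chain for this question: a spatial
niche-overlap index, Monte Carlo null models for its assemblage mean, a
descriptive co-occurrence (segregation) statistic, and mixed-design
repeated-measures comparisons of overlap values across years. A synthetic
community generator with the same statistical structure makes every stage
testable without field data.

## Data model

The core object is a **community matrix**: species in rows, discrete
*resource states* in columns, non-negative abundances in cells. Here the
resource states are spring outlets ("natural sampling units"), and the number
of individuals of a species collected at a site proxies the amount of that
spatial resource the species uses. When a sampling design crosses sites with
temporal replicates (e.g. four bimonthly samples per site), the replicates
are summed into one column per site at ingestion (`pool_sep` in
`read_community_matrix()`, or `pool_replicates()`); each outlet, not each
visit, is the resource state. The unpooled site-by-period convention remains
available by simply not pooling, for sensitivity analysis -- the two
conventions can give different C-scores and null expectations, and the pooled
one is this package's reference.

Species with zero total abundance in a year are retained on read but excluded
(with a warning) from overlap and C-score computations for that year, where
their utilisation profile would be undefined. Abundances may be non-integer
so that normalised or simulated data flow through the same code path.

## Pianka's overlap index

For species $j$ and $k$ with utilisation proportions $p_{ij}$ over $n$
resource states,

$$O_{jk} = \frac{\sum_i^n p_{ij} p_{ik}}
  {\sqrt{\sum_i^n p_{ij}^2 \, \sum_i^n p_{ik}^2}},$$

a symmetric, $[0,1]$-bounded cosine similarity of the two utilisation
vectors: 0 for disjoint resource use, 1 for proportional profiles. The
asymmetric Levins index is deliberately out of scope: the symmetric,
standardised form is the appropriate descriptor when species autecology is
poorly known and general patterns are sought. Because the index is invariant
to rescaling a species' row, pooled counts, proportions, or
differently-normalised rows all give identical results; this invariance is
property-tested.

Three summaries are reported per assemblage (`niche_overlap()`): the full
pairwise matrix $O$; each species' mean pairwise overlap with all others,
$O_{sp}$; and the assemblage mean over all unordered pairs. Diagonal entries
are 1 by convention but never enter any average. Note one deliberate
asymmetry: $O_{sp}$ for a year averages over *all* of that year's pairs,
even partners that the cross-year filter later drops, whereas pair tables
keep only pairs whose members occur in every year.

## Null models: RA1-RA4

Whether an observed assemblage mean is unusual is judged against ensembles of
simulated null assemblages. Each algorithm transforms every species' row of
utilisation proportions independently:

| algorithm | niche breadth | zero states | row operation |
|-----------|---------------|-------------|----------------|
| RA1 | relaxed | not retained | every entry replaced by a uniform(0,1) draw |
| RA2 | relaxed | retained | nonzero entries replaced by uniform(0,1) draws |
| RA3 | retained | reshuffled | row values permuted over all states |
| RA4 | retained | retained | nonzero values permuted among nonzero positions |

RA3 -- retain each species' degree of specialisation, randomise *which*
states it uses -- is the standard algorithm for resource-overlap null models;
RA2 is its natural companion when the guild structure carried by the zeros
should be conserved but specialisation relaxed. RA1 and RA4 are provided for
completeness. Numerical choices worth noting:

* Uniform replacement draws live on the open interval $(0,1)$, so a nonzero
  entry can never become zero in RA1/RA2; RA2's zero pattern and RA3/RA4's
  value multisets are preserved exactly (structural invariants with
  property tests).
* RA1/RA2 rows are re-normalised to sum 1 after replacement. Pianka's index
  is row-scale-invariant, so this is provably inconsequential; it is done
  for tidiness of the returned matrices.
* The tail probability is reported as the raw proportion
  $p_{\ge} = \#\{\text{null means} \ge \text{observed}\}/\text{iterations}$,
  matching the reporting convention of the classical null-model software
  lineage. The $(\text{count}+1)/(\text{iterations}+1)$ convention is
  available via `pseudo_count = TRUE`.
* The reported `null_variance` is the population variance (divisor =
  iterations) of the null means: it describes the simulated ensemble, not an
  estimator of anything beyond it.
* A single seeded RNG stream drives the whole ensemble sequentially, so a
  fixed seed reproduces a result bit-exactly. The package does not
  parallelise the ensemble, so no per-iteration substream machinery is
  needed; `year_report()` derives one deterministic seed per test from its
  top-level seed.

Calibration is checked empirically: when the data are themselves an RA3 draw,
the observed mean is exchangeable with its null ensemble and $p_{\ge}$ is
uniform (Kolmogorov-Smirnov check in the test suite, 200 datasets of 20
species by 8 sites, 200 iterations each -- sizes chosen to make the check
sharp at desk scale). Directionally, communities built on disjoint site
blocks give $p_{\ge}$ near 1 (observed overlap below expectation:
segregation) and communities crowded onto a shared block give $p_{\ge}$ near
0 (aggregation).

## C-score

On the presence/absence view (`to_presence()`, threshold abundance > 0), the
Stone-Roberts score for a pair is $C_{jk} = (R_j - SS)(R_k - SS)$, with $R_j,
R_k$ the row totals and $SS$ the number of samples occupied by both. It runs
from 0 (maximal aggregation) to $R_j R_k$ (complete segregation). The
matrix-wide mean over all pairs (`c_score()`) is used *only as a descriptive
statistic* to compare randomness of co-occurrence across years -- higher
means more segregated. No checkerboard null model is attached, deliberately:
significance testing of matrix-wide C-scores is a methodologically disputed
exercise and outside this package's scope.

## Between-year comparisons

`build_pair_table()` assembles, for every species pair present in all years,
the pairwise value per year plus the ecological pair type (`ss`, `sn`, `nn`);
`build_species_table()` does the same per species for $O_{sp}$ with the
stygobite/non-stygobite specialisation. The filter is data-driven (presence
in every year), never a hard-coded species list.

`rm_anova()` fits the univariate mixed-design (split-plot) decomposition:
year is the within-subjects factor, pair type (or specialisation) the
between-subjects factor, subjects are pairs (or species). Sums of squares are
Type III via a sum-to-zero-coded model -- with unequal group sizes, as pair
types always have, the year test is on unweighted marginal means. The
implementation delegates to `car::Anova` on a multivariate linear model; the
test suite validates it against an independent brute-force projection oracle
(subject dummies plus sum-coded effects, residual-sum-of-squares
differences) to 1e-8 relative, on balanced and unbalanced designs.
Greenhouse-Geisser and Huynh-Feldt corrections are computed and attached as
attributes, but the uncorrected P values are the headline, and post hocs are
Bonferroni (raw P times the number of comparisons in the family, capped at
1), applied within each family -- years, and group levels -- separately.
Paired t-tests (`paired_t()`) compare two years within one pair type;
zero-variance difference vectors are reported as explicit degenerate cases
(t = 0, P = 1 when all differences vanish) rather than errors.

One known limitation is inherited from the design, not corrected: pairwise
values sharing a species are not independent, so the pair-level ANOVA's error
df are optimistic. This is documented rather than modelled (e.g. by
pair-level random effects), to keep the procedure identical to the standard
practice for these indices.

`year_report()` orchestrates everything -- per-year overlap (whole assemblage
and per category), null tests for the requested algorithms, C-scores, the
tables, both ANOVAs plus a pairwise C-score ANOVA, post hocs and paired
t-tests -- reproducibly from one seed.

## The synthetic generator

`generate_community()` draws, per species: a Dirichlet utilisation profile
over all sites with concentration `breadth` (small = specialist, large =
generalist); a second Dirichlet profile confined to the species' site block;
their mixture weighted by `segregation`; a negative-binomial total abundance
(mean `total_abundance`, size `dispersion`); and a multinomial allocation of
that total across sites. Defaults mirror the field system the package was
built around: 22 species of which 9 (~40%) stygobites, 8 sites, breadth 1,
mean abundance 70 per species and dispersion 1 (the yearly totals of roughly
1000-2750 individuals over 22 species, with between-sample standard errors
of the same order as the means, imply strong overdispersion -- a Poisson law
would be clearly too narrow). Blocks are contiguous site ranges assigned
round-robin by default; `blocks` accepts an explicit assignment (e.g.
`rep(1, n)` for a fully aggregated community) and `random_blocks` randomises
it. `generate_scenario()` repeats this per year over a shared roster, with
optional forced absences to exercise the all-years-present filter;
decreasing segregation across years emulates a disturbance-driven
redistribution.

What the generator does *not* emulate: temporal autocorrelation between
replicates, environmental covariates, and species-specific dispersal -- so
green tests demonstrate the statistical machinery is correct under the
assumed data-generating law, not that the law captures every feature of real
spring communities.

## Degenerate inputs and numerical notes

Matrices need at least 2 species and 2 resource states; category subsets need
2 species of that category. All-zero species rows are excluded with a
warning, never silently. Overlap values are accumulated in double precision
(at 22 species by 8 sites no compensated summation is warranted) and clamped
to $[0,1]$ against round-off; the brute-force oracle comparison in the tests
runs at 1e-12. Dirichlet draws with very small concentration guard against
numerical underflow by falling back to a one-hot profile.

## Interfaces

The package is function-first, in the tradition of community-ecology R
packages: readers (`read_community_matrix()`, `read_species_metadata()`),
the analysis verbs above, and `year_report()` as the one-call pipeline,
with plain data frames and small S3 result objects throughout. No shell
entry point is shipped -- `scripts/acceptance.R` in the source repository
shows the intended scripted use. Problem sizes in the shipped tests and the
acceptance script (20-22 species, 8 sites, 200-1000 null iterations,
200-replicate calibration runs) are the package's chosen desk-scale study
conditions; they complete in well under a minute each on one CPU.
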