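---
title: "Fuzzy expert-system scoring of farmed aquatic species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy expert-system scoring of farmed aquatic species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbscore)
```

## The model

`fcbscore` scores farmed aquatic species on three 1–100 indices of
potential contribution to food security (F), climate change mitigation
and adaptation (C), and biodiversity (B) goals, from nothing but a
species-by-trait table and a rulebook. The pipeline has four stages.

**Fuzzification.** Each trait has a family of four overlapping fuzzy
sets — *low*, *medium*, *high*, *very high* — described by
piecewise-linear membership functions: trapezoids for the two extreme
categories (a plateau at degree 1 with one linear shoulder) and
triangles for the interior ones. A crisp trait value receives a degree
of membership in `[0, 1]` for every category, and categories whose
degree does not strictly exceed the retention floor (default 0.2) are
dropped. Because neighbouring sets overlap, one value can be, say,
*medium* at 0.5 and *high* at 0.4 simultaneously — the overlap encodes
the uncertainty of assigning a discrete level of potential to a
continuous trait.

**Rule firing.** The rulebook maps trait categories to potential
categories per index ("if VBGF K is *very high* then food-security
potential is *very high*"). A rule fires only when its premise
membership strictly exceeds the firing threshold (default 0.2, the same
value as the retention floor; the two are independently configurable, so
with the shared default the second check is redundant but harmless). The
conclusion membership is `weight × premise` under the default product
combiner (`min(weight, premise)` is available as a configuration
switch). All rules carry weight 0.5 — a 50% level of belief in any one
heuristic — so a single rule can never push a conclusion set above 0.5.
The product combiner was chosen because it preserves gradation in the
premise (a 0.6 premise concludes 0.30, not 0.5) while respecting the
same cap; both operators agree at a fully satisfied premise.

**MYCIN accumulation.** Conclusions from different traits reaching the
same set combine with the certainty-factor recurrence
`AccMem ← AccMem + m (1 − AccMem)`, implemented through its closed form
`1 − ∏(1 − mᵢ)` (probabilistic OR). The closed form makes the three key
properties immediate: order invariance, monotonicity in every input, and
`AccMem < 1` whenever every contribution is below 1. With `k`
equal-weight (0.5) conclusions the accumulated membership is bounded by
`1 − 0.5ᵏ`.

**Defuzzification.** The four accumulated memberships collapse to a
crisp score as a membership-weighted average of fixed category index
values — low = 1, medium = 25, high = 75, very high = 100:
`FinInd = Σ AccMemₓ·Indₓ / Σ AccMemₓ`. The score is invariant to
uniform rescaling of the memberships and bounded by the index values of
the supported categories. An all-zero membership vector raises an
error identifying the species and index rather than returning a
sentinel: with the missing-data penalty in place it can only arise from
a rulebook that leaves an index uninformed, which is a defect worth
surfacing.

**Missing data.** A missing trait value is penalized by assigning the
species to the *low potential* set of every index the trait is linked
to, with full premise degree (so conclusion membership 0.5 under the
default weight). The penalty degree is configurable; 1.0 was chosen as
the strongest admissible low conclusion, which is what "penalty" should
mean, and it guarantees every declared trait contributes something to
every linked index.

## Membership-function geometry

Published breakpoints for every trait are not available as package
input, so the default recipe anchors each family to the observed trait
distribution: the *low* plateau ends at the 25th percentile, the *very
high* plateau begins at the 75th, the *medium* apex sits at the median,
and the *high* apex midway between median and upper quartile. All
shoulders have width `fuzziness × IQR` with `fuzziness = 0.5` by
default. Quantiles follow the linear-interpolation (type 7) convention.
With `fuzziness ≥ 0.5` the family provably covers the observed range
and every adjacent pair overlaps, for any non-degenerate sample; the
constructor verifies both invariants on a dense grid and fails loudly
otherwise (e.g. a zero IQR). Rulebooks may instead carry fully explicit
breakpoints per category, which override the recipe — the escape hatch
for users who do know the intended set boundaries.

Out-of-domain values are clamped to the family's domain with a warning
rather than rejected: real trait tables contain outliers, and clamping
keeps batch scoring deterministic. Degrees exactly equal to the 0.2
floor are dropped (the threshold must be *exceeded*).

## The default rulebook

The shipped rulebook is a reconstruction of the directional trait–goal
relationships the framework rests on, not a verbatim copy of any
published rule table (which is not packaged):

* food security: maximum size, VBGF growth coefficient K, absolute
  fecundity, macronutrient density, and the five environmental tolerance
  ranges (nitrate, phosphate, salinity, dissolved O₂, pH) all act
  positively — productive, nutritious, robust-to-rearing species;
* climate: the tolerance ranges act positively (resilience to shifting
  conditions), trophic level negatively (feed-efficiency proxy: high
  trophic level means fish-derived feed);
* biodiversity: fecundity and K negatively (escape/invasion risk),
  trophic level negatively, latitudinal and geographic range negatively
  (wide-ranging species overlap more wild populations).

Positive linkages map each trait category to the same potential
category; inverted linkages reverse the order, so a species with extreme
fecundity lands simultaneously in the *very high* food set and the *low*
biodiversity set. Direction inversion lives in the rulebook's category
mapping, never in the membership functions, which stay purely
descriptive of the trait distribution.

## Jackknife sensitivity analysis

`jackknife_single()` removes each trait in turn — with its rules *and*
its missing-data penalty; the trait ceases to exist rather than becoming
"missing" — and re-scores every species. `jackknife_multi()` draws a
configurable number of uniform random subsets (default 50 replicates)
of `k` traits for each removal count `k`, so each `k` gets its own
deviation distribution. Deviations are reported in index points and as
percent variation: deviation divided by the maximum baseline score of
that index across species (the dataset maximum, not the theoretical
100; a `denominator = "theoretical"` switch is provided). Indices that
no remaining trait informs are reported per species as undefined
rather than crashing the analysis. Multi-trait subsets are sampled
uniformly over traits, without stratification by index linkage.

## Rank statistics

Scores are ranked per index and overall (mean score), descending, with
midrank ties. Association between indices uses tie-corrected Kendall
tau-b, preferred over Pearson at these sample sizes; the p-value comes
from the exact null distribution of the Kendall statistic when
`n ≤ 10` and the data are untied (equivalent to full permutation
enumeration in that case) and from the tie-corrected normal
approximation otherwise. Group differences across taxa use
Kruskal–Wallis with Dunn's pairwise post-hoc z tests on the same joint
ranks, Holm-adjusted by default (none/Bonferroni/BH available). The
all-tied comparison is degenerate and returns H = 0, p = 1 by
convention.

The comparison of the ten best- (or worst-) ranked species against the
full set is implemented as a permutation test on the mean difference
(random k-subsets as the null), one-sided by construction. A rank-based
test of an extreme subset against its own parent population is
inherently a selection effect, and the procedure such comparisons
originally used is ambiguous; the permutation default is documented
rather than guessed at, and no published p-value is claimed to be
reproduced.

## The synthetic generator

`synthetic_config()` / `generate_table()` emulate the statistical
structure of a FishBase/SealifeBase-style extraction for the staple
farmed species: 54 species by default across finfish (27), crustaceans
(9), molluscs (11), and algae (7) — proportions like those of the
top-farmed species lists; per-taxon trait distributions (algae near
trophic level 1, molluscs near 2, finfish spanning roughly 2–5;
log-normal fecundity, size, and geographic range; wider tolerance
ranges and higher nutrient density for the extractive groups); and
missingness concentrated in the non-fish taxa (3% finfish vs 20%
algae). All location parameters are per-taxon offsets scaled by a
single `effect_size`, so `effect_size = 0` makes the taxa exchangeable
in location. What the generator does *not* emulate: trait–trait
correlation within species, phylogenetic structure, measurement error,
or non-random missingness within a taxon — so passing recovery tests
demonstrate that the pipeline detects the configured group structure,
not that real FishBase data would behave identically.

Two calibration-style properties are exercised at fixed seeds:

* *recovery*: under a strong configured taxa effect (`effect_size = 2`,
  108 species for power) the median F and B scores of algae and
  molluscs exceed those of finfish and crustaceans, and Kruskal–Wallis
  detects the difference. At the default `effect_size = 1` and 54
  species the mollusc-vs-finfish food-score contrast is within sampling
  noise — a genuinely marginal contrast, which is why the recovery
  check is defined at the strong-effect condition;
* *null calibration*: with `effect_size = 0`, a shared trophic-level
  spread, and a shared missingness rate (per-taxon missingness is a
  real signal under the penalty, not a spurious one), the
  Kruskal–Wallis rejection rate over 200 simulated tables stays within
  three Monte-Carlo standard errors of the nominal 0.05.

## Numerical and scale choices

Problem sizes in the test suite were chosen to keep the default run
complete and fast: 54-species tables for jackknife consistency checks,
10,000 random membership lists for the accumulation oracle, 2,000
replicates for the Kruskal–Wallis size check, 200 pipeline replicates
for null calibration, 300 random vectors at `n ≤ 8` against the
pair-counting tau oracle. Tolerances: 1e-12 for the algebraic oracles
(closed form vs recurrence, piecewise-linear evaluation), three
Monte-Carlo standard errors for rate checks. Seeds are fixed in tests;
user-facing stochastic functions (`jackknife_multi`,
`extreme_subset_test`, `generate_table`) take explicit seeds.

## Known limitations

* The default rulebook and quantile-based membership functions are a
  documented reconstruction; scores for real species under the
  originally published rule table and set boundaries are not claimed.
* Scores depend on the scored table itself whenever quantile recipes
  are used (the families are fitted to the observed distribution), so
  adding species can move other species' scores; fixed breakpoints
  avoid this.
* Only the discrete weighted-average defuzzifier is provided; centroid
  methods over continuous output sets are out of scope.
* No rule learning or weight optimization: weights are inputs.
* No retrieval from FishBase/SealifeBase or environmental layers; the
  synthetic generator is the stand-in data source.
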