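---
title: "Scale-dependent temporal beta diversity: methods and design"
author: "scalescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent temporal beta diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

When an assemblage is resurveyed decades later, how much it appears to
have changed depends on the spatial grain at which "the assemblage" is
defined. A single 100-m stream reach may hold an almost entirely
different set of fishes than it did forty years earlier, while the
drainage as a whole retains nearly the same species pool in nearly the
same relative abundances. `scalescan` quantifies this dependence
directly: it computes compositional change between two survey periods
at every spatial grain obtainable by pooling matched site pairs into
K spatial clusters, from K = N (each pair alone, the local scale) down
to K = 1 (the whole study region), and tests candidate discontinuities
in the change-versus-scale relationship against a bootstrap null built
from the local values. Discontinuities are of interest because a break
in the relationship suggests a boundary between domains of scale --
ranges of grain within which a different set of processes dominates
assemblage dynamics.

## The pipeline, stage by stage

**Input harmonization.** Counts are held in a site-by-species matrix
keyed by (site, period). Before any index is computed, a taxon map is
applied to reconcile identification practice between survey eras: the
shipped default merges the two *Campostoma* species and the two
*Fundulus* species (not distinguished in the earlier survey) and
reassigns *Notropis rubellus* to *N. suttkusi*. Merging always
conserves row totals; a rename that collides with an existing column
degrades to a merge, with a message, because species names must stay
unique.

**Site pairing.** Each later-period site is matched to its nearest
earlier-period site by river-network (fluvial) distance. A candidate
pair is retained only if the straight-line (haversine, Earth radius
6371.0088 km) separation is under 8 km and the two sites share the same
Strahler stream order -- so that a pair compares reaches of comparable
stream size that plausibly represent the same locality. Matching is
one-to-one by default: several resurveyed sites may be nearest to the
same historical site, and reusing it would pseudo-replicate its
assemblage. Conflicts are resolved on a single globally ascending
fluvial-distance queue with lexicographic tie-breaks, so the result is
deterministic and independent of input order; a `one_to_one = FALSE`
mode preserves the literal nearest-site reading. The pairing of the
original study cannot be reproduced exactly because its
conflict-resolution rule is not recorded; neither mode claims to.

**Temporal dissimilarity.** The primary index is the Morisita-Horn
dissimilarity, 1 − 2Σxy / ((d_x + d_y)XY) with X = Σx, Y = Σy,
d_x = Σx²/X², d_y = Σy²/Y². It depends only on relative abundances --
multiplying a survey by any positive constant changes nothing -- which
matters here because pooled clusters of different sizes and periods of
different sampling effort must be comparable. The presence/absence
counterpart (Jaccard) and the classic small-sample-corrected Morisita
index are available through the same interface to check robustness to
data resolution. Empty assemblages raise errors rather than NaN: a
silent NaN entering the scan would corrupt every downstream grain.
Values are clamped to [0, 1] against floating-point overshoot.

**Spatial hierarchy and the scan.** Pairs are clustered on their
fluvial distances with Ward's minimum-variance criterion (Lance-
Williams recurrence on squared dissimilarities). This is the
spatial-only limit of mixed geography/composition constrained
clustering: the compositional matrix gets zero weight, geography alone
defines the hierarchy, so plain Ward on the spatial matrix is the
algorithm. Only cluster memberships feed downstream -- merge heights
are reported in squared river-km and never interpreted -- so tree
topology, verified in the tests against a naive O(N³) agglomerator, is
the contract. Pair-to-pair fluvial distances inherited from approximate
matches can violate the triangle inequality; the hierarchy is built
regardless (with a warning), as generalized Ward admits arbitrary
dissimilarities. Cutting the one hierarchy at every K guarantees the
grains are nested. For each K, member pairs are pooled per period by
summing counts and the index is computed per cluster, giving K values
whose distribution (mean, quartiles) is reported in a boxplot-ready
table.

**The discontinuity test.** A candidate grain K is tested against the
hypothesis that its observed mean dissimilarity is an ordinary draw
from the local-scale values: B = 100,000 iterations each draw K values
with replacement from the N local dissimilarities and record the mean;
the p-value is the exact proportion of iteration means ≤ the observed
mean (one-sided "probability of sampling a mean at least this small",
no continuity correction; a two-sided option doubles the smaller
tail). Reports use α = 0.05. Which K to test is the analyst's choice,
made from the scan summary; an exploratory all-K mode exists but warns
that no multiplicity correction is applied, because none was applied in
the study design this follows. Bootstrap summary quartiles use the
type-7 (linear interpolation) convention.

**Diversity partition.** Global context comes from Hill-number
diversity: gamma is the effective species number of the pooled
assemblage, alpha the equal-weight mean within-site effective number,
and beta = gamma/alpha. The default order is q = 0 (richness), under
which alpha is the arithmetic mean site richness and gamma the integer
pooled richness; q is exposed because orders 1 and 2 weight dominance
differently. Equal site weights are the natural choice at q = 0 and
make beta range over [1, N]. Standard errors come from resampling
sites with replacement (B_div = 10,000), with plug-in point estimates.
Simpson's reciprocal diversity (the q = 2 Hill number of the pooled
assemblage) is reported per period with the same resampling scheme.
The identity n_shared + n_only_a = gamma(q = 0) of period a links the
species-persistence counts to the partition and is asserted
integer-exactly in the tests.

## The synthetic riverscape generator

Field data for a forty-year resurvey cannot be redistributed with a
package, so every stage is exercised against a seeded generator that
reproduces the statistical structure the analysis assumes.

**Network.** A dendritic tree: a mainstem with `n_tributaries = 15`
junctions, each fed by a tributary (confluence plus two order-1
headwater branches), edge lengths uniform(2, 20) river-km, Strahler
orders by the standard recursion. 33 sites sit two-to-three per
tributary (headwater, confluence, second headwater), spanning low to
mid orders. Fluvial distance is the unique tree-path length; a planar
embedding draws every edge at 0.7 x its river length (channels
meander), which by the triangle inequality caps straight-line distance
at fluvial distance; coordinates are scaled onto a pseudo lat/lon box
matching a ~113 x 48 km drainage so haversine-based pairing is
exercised realistically.

**Metacommunity.** A 50-species regional pool with lognormal(2.0, 1.2)
abundances gives the long right tail -- dominant cyprinids down to
near-singletons -- typical of stream-fish collections. Each species
occupies a contiguous river neighbourhood: presence probability decays
as exp(−0.015 · river-km) from a species-specific focal site. The rate
0.015 was chosen once so that observed site richness sits near 10 of
50 species and ranges span a few neighbouring tributaries, the profile
of a mid-sized warm-water drainage; it was fixed before the test
thresholds were frozen and is not revisited. Surveys are multinomial
draws of 150 individuals from the locally present species weighted by
regional abundance.

**Turnover.** Between periods, each species observed at a site is
extirpated with probability tau (default 0.5) and replaced by a
colonizer drawn from outside the standing assemblage, weighted by
regional abundance times local occupancy probability. The colonizer
inherits the observed abundance of the species it replaces -- it fills
the vacated niche -- so the site's abundance structure and expected
richness are stationary while identities turn over, and the regional
pool is preserved. This is exactly the contrast the analysis targets:
local change can approach complete replacement while pooled
composition drifts little. A site with no extirpation keeps its survey
unchanged, so tau = 0 reproduces the input bit-exactly. A third period
resurveys 8 sites one "year" later at tau2 = 0.15, exercising the
short-interval comparison path.

**Planted domain (tributary mode).** To validate domain detection, an
alternative turnover emulates within-tributary dispersal: each
tributary's pooled individuals are redistributed across its member
sites with random site shares, and the tributary total is rescaled by
a lognormal(0, 0.8) abundance trend. Site-level change is then large,
tributary-level change is near zero (the index is scale-invariant, so
the rescaling is invisible within a tributary), and coarser pools mix
tributaries whose relative weights shifted severalfold -- decadal
catch totals of small drainages commonly swing that much. The grain
minimizing pooled change therefore sits at the tributary count. The
trend sd and the redistribution scheme were designed to make the
planted boundary detectable by construction, not fitted to any test
outcome.

**What the generator does not emulate.** No mechanistic population
dynamics, no environmental covariates or habitat gradients beyond
distance decay, no detection-probability model, no gear or effort
differences between eras (the index's scale-invariance makes uniform
effort rescaling a no-op anyway), and no approximate site relocation:
synthetic resurveys reoccupy the same nodes, so all pairs are exact
matches and the 8-km/stream-order filters are exercised by dedicated
unit fixtures instead. Passing tests on synthetic data therefore show
the machinery is correct under the stated statistical structure, not
that any particular field system has these properties.

## Numerical and design choices

- **Domain locator statistic.** `find_domain_scale()` minimizes the
  per-K *mean* over interior K (2..N−1). Under strong homogenization
  the median ties at its floor across neighbouring K -- at one cluster
  fewer than the planted count, 13 of 14 clusters are still pure
  tributaries, so the median barely moves -- whereas the mean responds
  to every cluster and is uniquely minimized where all clusters sit at
  the homogenized scale. K = 1 is excluded because a single value has
  no distribution; K = N because it is the reference itself.
- **Ward implementation.** `stats::hclust(method = "ward.D")` on
  squared distances; cluster ids are renumbered 1..K by each cluster's
  smallest member label so assignments are stable across K and runs.
  Tie-breaking among equal merge costs follows the implementation's
  deterministic order; dendrograms under exact ties are not claimed to
  match any particular published tree.
- **Degenerate inputs.** Empty assemblages, all-zero rows, duplicate
  row keys, asymmetric or negative distance matrices, and out-of-range
  K all raise immediate, named errors. All-zero species columns are
  retained (the indices ignore them; retention keeps persistence
  bookkeeping simple).
- **Determinism.** Every stochastic stage (generator, both bootstraps)
  takes an explicit seed; the synthetic dataset is a pure function of
  its configuration, and identical configuration plus seed yields
  byte-identical summary JSON.
- **Problem sizes.** The shipped analyses and checks run the full
  default conditions -- 33 pairs, 50 species, all K from 1 to 33,
  B = 100,000 test iterations, B_div = 10,000 diversity resamples --
  and repeated-seed validation uses 50 riverscapes for planted-domain
  recovery and 100 for the local-versus-global contrast, sizes at
  which every property of interest is stable run-to-run.

## Known limitations

- Fluvial distances are inputs; the package does not route distances
  from hydrography, so real-data use requires a river-km matrix from
  GIS tooling.
- The discontinuity test conditions on the grain nominated by the
  analyst (or by the domain locator); nominating after inspecting the
  scan is an informal selection step, and the exploratory all-K mode
  makes the multiplicity explicit rather than correcting for it.
- The multiplicative partition uses equal site weights; abundance
  weighting at q ≠ 0 would change alpha and beta for strongly uneven
  site totals.
- One-to-one greedy matching is order-independent but not globally
  optimal (it is not a minimum-cost assignment); with dense candidate
  sets an optimal assignment could retain marginally more pairs.
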