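# scalescan

Scale-dependent temporal beta diversity for resurveyed assemblages.

## The problem

Estimates of how much an ecological community changed between two
surveys depend on the spatial grain at which the community is defined.
Individual stream reaches resurveyed after decades can show near-total
species replacement while the drainage as a whole keeps essentially the
same pool. `scalescan` measures that dependence on a continuous grain
axis and tests where it breaks. It is aimed at community ecologists with
site-by-species count data from two (or three) sampling periods on a
river network — and, since the machinery is index-agnostic over
assemblage count tables, at anyone comparing compositional change across
pooling scales.

The core quantities, for matched site pairs *i = 1..N* with abundance
vectors *x* (period 1) and *y* (period 2):

- **Temporal dissimilarity** (Morisita–Horn):
  `d(x, y) = 1 − 2Σxᵢyᵢ / ((dₓ + d_y) X Y)` with `X = Σxᵢ`, `Y = Σyᵢ`,
  `dₓ = Σxᵢ²/X²`, `d_y = Σyᵢ²/Y²`; Jaccard `1 − a/(a+b+c)` on
  presence/absence as the resolution check.
- **The scan**: a Ward hierarchy on pair-to-pair fluvial (river-km)
  distances is cut at every K from N down to 1; per cluster, member
  pairs are pooled per period and `d(pooled₁, pooled₂)` recorded — K
  values per grain K.
- **The discontinuity test**: for a nominated grain K, B = 100,000
  bootstrap iterations draw K values with replacement from the N local
  dissimilarities; `p = #{mean ≤ observed mean}/B`.
- **Diversity partition** (Hill numbers, order q = 0, equal weights):
  `gamma = alpha × beta`, with site-resampling standard errors
  (B = 10,000), plus species-persistence counts satisfying
  `n_shared + n_only_a = gamma_a` exactly.

A seeded generator of dendritic riverscape metacommunities (lognormal
regional pool, distance-decay occupancy, niche-filling identity
turnover, optional planted tributary-scale domain) makes every stage
testable offline.

## Worked example

The numbered drivers under `analysis/` run the full workflow on the
default synthetic drainage (33 paired sites, 50-species pool, turnover
0.5, one-year resurvey of 8 sites) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pair_sites.R
Rscript analysis/03_diversity_change.R
Rscript analysis/04_scale_scan.R
```

which prints:

```
Simulated 33 sites / 50 species, periods: T1 T2 T3
33 site pairs retained; 33 exact geographic matches
Local MH dissimilarity: mean 0.497 (range 0.011-0.993, n = 33)
One-year (T2 vs T3) mean: 0.153 (n = 8)
Species persistence: 49 shared, 1 only T1, 0 only T2
T1: alpha 9.79+-0.43, beta 5.11+-0.23, gamma 50.0+-0.79, Simpson 22.15
T2: alpha 9.24+-0.39, beta 5.30+-0.26, gamma 49.0+-1.43, Simpson 23.06
<scale_scan> morisita_horn dissimilarity over K = 1..33 (N = 33 pairs)
Local (K = 33) mean: 0.497; global (K = 1) value: 0.052
Candidate domain at K = 2: mean 0.100, p = 0.0443 (bootstrap median 0.496)
```

Reading this: individual reaches changed drastically over the long
interval (mean 0.50, some near 1.0) and far less over one "year"
(0.15), yet the pooled drainage barely moved (0.05) and the
species-level diversity partition is stable between periods — high
local turnover inside a persistent regional pool. Alpha ≈ 9.8 effective
species per site and gamma = 50 give beta ≈ 5 compositionally distinct
communities. Without a planted domain the pooled change declines
smoothly with grain, so the interior minimum lands at a small K; when
the generator plants within-tributary homogenization
(`synthetic_dataset(cfg, tributary_mode = TRUE)`), the minimum sits at
the tributary count instead.

The same stages are available programmatically:

```r
library(scalescan)
ds  <- synthetic_dataset(synthetic_config(seed = 1))
rep <- run_pipeline(ds$table, ds$sites, ds$fluvial,
                    pipeline_config(K_test = 15L, seed = 1L))
rep$summary$local_mean     # mean local temporal dissimilarity
rep$scan$summary           # boxplot-ready per-K table
rep$tests$K15$p_value      # bootstrap test at K = 15
```

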