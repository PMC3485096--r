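# firecomm

Pairwise community phylogenetics for fire-prone shrub assemblages.

`firecomm` asks how competition and habitat filtering shape which plant
species grow together, using species *pairs* rather than whole-community
indices. It was built for nested vegetation surveys of shrub genera with
two fire-response guilds — **reseeders** (killed by fire, regenerating
from seed) and **resprouters** (surviving fire vegetatively) — where the
prediction is that competitive sorting should be strongest among
reseeder pairs.

## What it computes

For every geographically overlapping species pair (ranges = minimum
convex polygons around occurrence records; non-overlapping pairs are
dropped):

- **Co-occurrence**: Schoener's index
  `C_ij = 1 − ½ Σ_k |p_ik − p_jk|` over plots `k`, where `p_ik` is
  species *i*'s proportional abundance — at the subplot (0.04 ha) scale
  and at the large-plot (4 ha) scale (mean of the 4 nested subplots).
- **Distances**: patristic distance on a dated phylogeny; differences in
  height, seed size and flowering-period length; flowering-overlap
  dissimilarity; and differences in *edaphic preference slopes* (OLS
  slope of log(n+1) abundance on each of 7 soil variables).
- **Association tests**: exact quantile regression of `C_ij` on each
  distance (default tau = 0.5), per guild subset and plot scale, with
  *species-level* permutation p-values and *species-level* bootstrap
  confidence intervals — randomizing species, not pairs, because pairs
  sharing a species are not independent. Positive slope = repulsion
  (distant pairs co-occur more); negative = attraction/filtering.
- **Phylogenetic signal**: Pagel's λ (ML over [0,1], boundary-mixture
  likelihood-ratio tests against λ=0 and λ=1) for continuous traits and
  soil preferences; the D statistic (shuffle and threshold-Brownian
  nulls) for regeneration mode; quantile regression against patristic
  distance for flowering overlap; and node-age–divergence plots from
  independent contrasts with a κ branch-length transformation tuned to
  decorrelate contrast size from its standard deviation, flagging nodes
  with |studentized residual| > 3.

A synthetic-data generator (`generate_synthetic_dataset()`) produces
complete surveys — Yule tree, conserved/labile traits, soil gradients,
Poisson counts, circular ranges, and an optional guild-specific
repulsion mechanism — so the entire pipeline is validated by simulation.

## Worked example

```r
library(firecomm)

sim <- generate_synthetic_dataset(sim_config(
  seed = 1,
  repulsion = list(guild = "reseeder", trait = "height",
                   delta = 0.5, rho = 0.9)   # height repulsion among reseeders
))
res <- run_analysis(sim$dataset, sim$tree, config = analysis_config(seed = 1))

subset(res$table1, scale_ha == 0.04 & predictor %in% c("phylo", "height"))
```

```
                 subset predictor n_pairs  df   slope   ci_low ci_high p_perm stars
                    all     phylo     352 350 0.00110 -0.00199 0.00341  0.305
                    all    height     352 350 0.05891  0.01053 0.09036  0.005    **
      reseeder_reseeder     phylo      97  95 0.00083 -0.00024 0.00205  0.070     †
      reseeder_reseeder    height      97  95 0.02062  0.00584 0.06867  0.015     *
  resprouter_resprouter     phylo      69  67 0.00072 -0.00148 0.00420  0.460
  resprouter_resprouter    height      69  67 0.00783 -0.05739 0.06443  0.690
```

The generator planted height repulsion among reseeders, and the analysis
recovers it: the reseeder height slope is significantly *positive*
(similar-height reseeders avoid each other), the resprouter cell is
null, and the phylogenetic-distance cell shows only the faint echo
expected when phylogeny acts through a conserved trait.

```r
res$table3[1:4, c("trait", "statistic", "estimate", "p_labile", "p_brownian")]
```

```
       trait statistic estimate p_labile p_brownian
      height    lambda     1.00  3.2e-14       1.00
        seed    lambda     1.00  1.1e-08       0.49
  flower_len    lambda     0.00  1.00       4.8e-15
  regen_mode         D     1.27  0.89       0.00
```

Height and seed size are recovered as conserved (λ ≈ 1, Brownian not
rejected), flowering-period length and all soil preferences as labile
(λ ≈ 0), and regeneration mode as phylogenetically random (D ≈ 1) —
exactly the signal structure the generator was told to produce.

`render_reports(res, "outdir")` writes the pair table, the three report
grids, per-trait contrast tables and a JSON run manifest;
`autoplot(res$contrasts[["height_m"]])` draws the node-age–divergence
diagnostic.

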