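---
title: "Methods: pairwise co-occurrence, quantile regression and phylogenetic signal"
author: "firecomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise co-occurrence, quantile regression and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecomm)
```

## The scientific problem

Communities of closely related plant species can assemble under two
opposing forces. Competition between ecologically similar (and therefore
often closely related) species pushes them apart — *phylogenetic or
phenotypic repulsion* — while shared habitat requirements pull species
with similar environmental responses together — *environmental
filtering*. Fire-prone shrublands add a twist: species that are killed by
fire and regenerate from seed (**reseeders**) go through repeated
population bottlenecks and local colonisation episodes, which should
intensify competitive sorting, while species that resprout vegetatively
(**resprouters**) persist in place and may be buffered from it.

`firecomm` implements a pairwise analysis of this problem for a nested
vegetation survey: 24 large (4 ha) plots, each containing four 0.04 ha
subplots in which individual plants are counted. Everything downstream
works on unordered species pairs rather than community-level indices,
because pair-level resolution is what lets guild-specific patterns
(reseeder pairs vs resprouter pairs vs mixed pairs) be separated.

## Co-occurrence

For species $i$ with proportional abundance $p_{ik}$ in plot $k$
(abundance divided by the species' total across plots), Schoener's index
is

$$C_{ij} = 1 - \tfrac12 \sum_k |p_{ik} - p_{jk}|,$$

1 for identical site-use profiles, 0 for disjoint ones
(`schoener_cij()`). It is computed at both spatial scales: subplot
counts directly, and large-plot abundances as the arithmetic mean of the
four nested subplot counts (`aggregate_large_plots()`). A large-plot
presence with no subplot individuals contributes abundance 0 by default
(`presence_floor` lets users assign a nominal value instead); the survey
protocol measures abundance only in subplots, so any other choice would
invent data.

Species pairs whose geographic ranges do not overlap are removed first
(`overlapping_pairs()`): allopatric species cannot co-occur for purely
historical reasons, and keeping them would manufacture spurious
repulsion. Ranges are minimum convex polygons around occurrence records,
held in planar coordinates — over a few-hundred-km region the distortion
from unprojected degrees cannot flip an overlap decision except for
boundary-touching slivers, which are already treated as non-overlap
(positive intersection area is required). Degenerate hulls (fewer than
three non-collinear records) are buffered by 0.01 degrees so that a
poorly collected species is not silently dropped.

## Pairwise distances

Each retained pair gets: patristic distance on a dated tree (Myr);
absolute differences in maximum height (m), seed length (mm) and
flowering-period length (months); a flowering-overlap dissimilarity
(shared months over the shorter season, subtracted from 1); and, per
soil variable, the absolute difference in *edaphic preference slopes* —
the OLS slope of $\log(n+1)$ abundance on the soil variable across all
96 subplots (`edaphic_preference_slopes()`). Zeros are kept in the
regression: excluding unoccupied plots would condition on the outcome.
Slopes carry the reciprocal units of their soil variable, so these
distances are not comparable *across* variables — only within a variable
across pairs, which is how they are used. Species missing from the tree
keep their trait and soil distances and are flagged with `NA` patristic
distance, mirroring surveys where the phylogeny covers only a subset of
the flora.

## Inference: exact quantile regression with species-level randomization

All distance–distance associations use quantile regression
(`quantile_fit()`), which is robust to the skewed, bounded distribution
of $C_{ij}$. The default `tau = 0.5` (median regression) is the most
defensible single choice; the analysis functions accept any `tau` set.
The fit is exact: the profiled objective in the slope is convex
piecewise linear, and the minimiser is found by bisection on its
subgradient sign (a compiled backend makes this fast; a pure-R reference
implementation is retained and tested equal, and both are checked
against the point-pair enumeration property of least absolute
deviations).

Pairs sharing a species are not independent, so ordinary standard errors
are badly anticonservative. Both inference devices therefore randomize
*species*, not pairs:

- **Permutation p-value** (`species_permutation_pvalue()`): the
  species-level attribute behind the predictor (trait value, soil slope,
  or tree tip label) is shuffled across species, all pairwise distances
  are rebuilt, and the regression is refitted;
  $p = (1 + \#\{|b_{perm}| \ge |b_{obs}|\})/(B+1)$, two-sided. Within a
  guild subset, permutation is over the species in that subset.
- **Bootstrap CI** (`species_bootstrap_ci()`): species are resampled
  with replacement, the pair table is rebuilt from the resample
  (self-pairs and geographically filtered pairs dropped), and the
  percentile interval of refitted slopes is reported.

Sign convention: a *positive* slope means more distant pairs co-occur
more — repulsion; a *negative* slope means similarity goes with
co-occurrence — attraction/filtering. Degrees of freedom are reported as
$n_{pairs} - 2$ per cell for comparability, though the permutation test,
not the df, carries the inference. No multiple-testing correction is
applied across the predictor-by-subset grid; each cell is reported as
its own test and flagged with conventional stars.

## Phylogenetic signal

**Pagel's lambda** (`pagel_lambda_ml()`): the trait is modelled as
multivariate normal with covariance $\sigma^2 C(\lambda)$, where
$C(\lambda)$ multiplies the shared-path entries of the Brownian
covariance by $\lambda$ and keeps tip variances. The mean and rate are
profiled analytically by GLS; $\lambda$ is maximised over $[0,1]$ by a
101-point grid scan plus bounded refinement (tolerance $10^{-6}$; the
grid guards against the flat, occasionally multimodal profiles of small
trees). Tests against $\lambda=0$ ("labile") and $\lambda=1$
("Brownian") are likelihood-ratio statistics referred to the boundary
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, since both nulls sit on
the boundary of the parameter space.

**D statistic** (`d_statistic()`): for a binary trait, the observed sum
of sister-clade differences in nodal estimates (Felsenstein averaging
pass applied to the 0/1 states) is scaled between the means of two
simulated nulls at the observed prevalence — prevalence-preserving
shuffles (D ≈ 1) and threshold-Brownian liabilities (D ≈ 0), 1000 draws
each by default. Thresholding at the empirical quantile keeps prevalence
exact, so the Brownian null is not confounded by prevalence drift.

**Flowering schedules** are pairwise data, so their signal is assessed
as a quantile regression of flowering-overlap dissimilarity on patristic
distance with the same species-permutation machinery
(`flowering_overlap_signal()`). All signal statistics accept a sample of
trees (`signal_across_trees()`) and report medians with 2.5/97.5
percentiles, the convention for Bayesian posterior tree samples.

**Node-age divergence** (`node_age_divergence()`): absolute standardized
contrasts are regressed through the origin on node age, and nodes with
externally studentized residuals beyond |3| are flagged as having
diverged more than expected from their age. Contrast standardization
divides by the square root of the summed (pruning-adjusted) branch
lengths; because labile traits are overstandardized at deep nodes,
branch lengths are first raised to a power $\kappa$ chosen to kill the
correlation between |standardized contrast| and its SD
(`optimize_kappa()`, grid 0–3 in steps of 0.01 with local refinement,
ties to the smallest $\kappa$). Node age is the mean node-to-tip path
length in the transformed tree (a transformed tree need not be
ultrametric; a max-path option is provided). Zero-length branches are
perturbed by $10^{-8}\times$ tree depth with a warning so contrast SDs
stay positive.

## The synthetic world

`generate_synthetic_dataset()` produces data with exactly the structure
the analysis assumes, so every stage can be validated by simulation:

- **Tree**: crown-conditioned Yule process; default birth rate 0.08/Myr
  puts the expected crown depth of a 39-tip tree near 40 Myr, the scale
  of the radiation the design emulates.
- **Traits**: log-height and log-seed evolve as Brownian motion
  ($\sigma^2 = 0.02$/Myr, $\lambda = 1$ by default — conserved); root
  heights near 1.5 m and seeds near 5 mm give realistic shrub ranges
  (floored at 0.2 m / 0.5 mm). Flowering seasons are random 2–6 month
  windows (labile). Regeneration mode is a fixed-prevalence binary trait
  (default 60% reseeders), random by default (labile) or
  Brownian-threshold.
- **Soil**: seven variables with a linear regional trend across the
  large-plot sequence plus subplot noise, at field-plausible scales
  (e.g. pH 5.5 ± 0.3). Gradients are linear so tests can compute
  expected slopes.
- **Abundance**: log intensity linear in the centred soil variables with
  i.i.d. per-species response slopes (labile edaphic preferences by
  construction), Poisson counts. Poisson is the simplest model
  satisfying the analysis's assumptions; an overdispersion knob is
  deliberately left out.
- **Repulsion**: within each subplot, each same-guild pair closer than
  `delta` in the chosen trait (height, or patristic distance) loses its
  rarer member with probability `rho` — ecological sorting of standing
  individuals, not evolutionary divergence.
- **Ranges**: circular ranges with uniform records; the default radius
  (1.0° ± 0.3° on a 3° study square) makes the geographic filter retain
  roughly 55–60% of pairs, the retention regime the analysis is designed
  for.

What the generator does *not* emulate: spatial autocorrelation beyond
the soil trend, overdispersed counts, observation error in traits,
non-circular ranges, and correlated edaphic preferences. Passing
recovery tests on this world therefore demonstrates correctness of the
machinery and qualitative detectability of guild-specific repulsion, not
field realism.

Two limitations worth stating plainly. First, the edaphic preference
slopes are *estimated from the same abundance table* that co-occurrence
is computed from. Under a pure-noise world this double use makes the
soil-preference association tests mildly anticonservative (rejection
rates up to ~0.15–0.20 at a nominal 0.05 in simulation): two species
whose abundance profiles are similar by chance score high on both
`C_ij` and preference similarity. Soil-cell p-values near the threshold
should therefore be read cautiously; an independent abundance split (or
external preference data) would remove the coupling but is outside the
survey design. Second, with preferences labile and height
conserved, phylogeny influences co-occurrence *only through height*.
The correlation between height distance and patristic distance on
~40-tip Yule trees is weak (≈0.2), so height repulsion induces only a
faint phylogenetic repulsion signal — detectable in a minority of
simulated worlds at these sample sizes. Direct phylogenetic repulsion
is available in the generator (`repulsion$trait = "phylo"`).

## Numerical and design choices

- Problem sizes in the package's simulation-based checks are desk-scale
  by design: 64-tip trees and 100 replicates for lambda recovery, 34-tip
  trees and 200 replicates for D calibration, 50-replicate end-to-end
  power runs with 99–199 permutations per cell. These sizes give Monte
  Carlo error well inside the tolerance bands asserted.
- Permutation counts: with `B_perm = 199` the smallest attainable p is
  0.005, so three-star significance (p ≤ 0.001) is reportable only with
  `B_perm >= 999`; the default grids cap at two stars.
- The boundary-mixture LRT for λ is *conservative* in finite samples:
  under a true λ = 0 world with 64 tips it rejects at roughly 1% for a
  nominal 5% level, because the ML estimate sticks to the boundary more
  than half the time. Interpret non-rejections of λ = 0 accordingly.
- The species bootstrap achieves nominal ~95% coverage when the
  residual dependence really is species-level (shared-species effects);
  when pair-level noise dominates, it over-covers (intervals are wider
  than necessary). It errs on the safe side.
- Grid cells with fewer than 10 pairs are skipped rather than fitted
  (quantile regression on a handful of dependent pairs is degenerate);
  the row remains with an explicit reason.
- Abundance tables store plots as rows and species as columns, with the
  nesting encoded in the plot id (`"L07_S3"`), so one file is
  self-describing.
- Null calibration of the whole pipeline is run with repulsion off *and*
  edaphic preference slopes set to zero: preferences are a real
  co-occurrence mechanism (filtering), so a world with active
  preferences is not a null world for the soil-distance cells.
- Flowering month sets are sets, not intervals: wrap-around seasons
  (Nov–Feb) are legal.
- Missing soil values are rejected at validation; imputation belongs
  upstream of this package.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_synthetic_dataset(sim_config(
  seed = 1,
  repulsion = list(guild = "reseeder", trait = "height",
                   delta = 0.5, rho = 0.9)
))
res <- run_analysis(sim$dataset, sim$tree,
                    config = analysis_config(seed = 1))
res$table1   # co-occurrence ~ phylogenetic/ecological distance, per guild
res$table3   # phylogenetic signal per trait and soil preference
autoplot(res$contrasts[["height_m"]])  # node-age divergence plot
render_reports(res, "firecomm-report")
```
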