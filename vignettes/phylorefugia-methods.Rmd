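---
title: "Methods: dispersion classification on grids and paired extinction simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersion classification on grids and paired extinction simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`phylorefugia` implements a community-phylogenetics workflow for gridded
presence–absence data — richness, mean pairwise distance (MPD), mean
nearest taxon distance (MNTD) and Faith's phylogenetic diversity (PD),
a regression-band classification of cells into under-, neutrally and
overdispersed, ecoregion aggregation, and cross-taxon overlap
statistics — together with a paired birth–death simulation that asks
whether *reduced extinction alone* is sufficient to produce
phylogenetic underdispersion. Because the empirical inputs such an
analysis consumes (continent-scale range maps, posterior tree sets,
ecoregion shapefiles) are large external downloads, the package ships a
synthetic-data generator that emulates their structure with known,
controllable signal, so every stage of the pipeline is testable from
code alone.

# Community metrics

All metrics are computed from first principles on rooted `phylo` trees
with branch lengths (time-like units):

* **MPD** of a community of $n \ge 2$ taxa is the arithmetic mean of the
  $n(n-1)/2$ distinct pairwise patristic distances, unweighted
  (presence–absence only).
* **MNTD** is the mean over members of the distance to the nearest
  co-occurring taxon.
* **Faith's PD** is the total branch length of the minimal spanning
  subtree of the community's tips. By default the spanning subtree is
  the union of tip-to-tip paths and is *not* connected down to the tree
  root; `include_root = TRUE` selects the root-inclusive variant. The
  unrooted default makes a singleton community carry PD = 0 and keeps
  the quantity self-contained; both variants are exposed because usage
  in the literature is split.

Communities with fewer than two members have undefined MPD/MNTD and are
recorded as missing, never as zero; downstream regressions simply drop
missing cells. No standardized effect sizes (NRI/NTI-style null models)
and no abundance weighting are provided: the dispersion measure used
here is built from the PD~richness relationship instead.

Pairwise distances come from an internal postorder sweep
(`cophenetic_distances()`); the implementation is checked in the test
suite against a naive path-walking oracle and against
`ape`/`picante`, which serve only as cross-checks, never as the
implementation.

When a set of $T$ posterior-like trees is supplied,
`summarize_over_trees()` records per cell the mean and the min–max
range of the metric across trees; classification consumes the mean
surface.

# Dispersion classification

`fit_pd_richness()` fits an ordinary least-squares line
$PD = \beta_0 + \beta_1 \cdot richness$ over cells where both surfaces
are defined. `classify_cells()` assigns category 0 (underdispersed)
below the lower limit of a 95% band around the line, 2 (overdispersed)
above the upper limit, and 1 otherwise; `ecoregion_scores()` averages
categories within ecoregions and rescales to $[-1, 1]$ (mean − 1), and
`combine_groups()` averages two taxon groups cell-wise and
ecoregion-wise.

The band is configurable, and the choice matters. The *mean-response
confidence band* shrinks like $\sigma/\sqrt{n}$: with $10^4$–$10^5$
cells it hugs the line so tightly that essentially every cell is
classified non-neutral, which makes three-class maps meaningless. The
default is therefore the *prediction band* for a new observation, which
has stable ≈5% off-band mass regardless of the number of cells (the
calibration test verifies 5% within three binomial standard errors at
$n = 10{,}000$). The mean-response band remains selectable
(`band = "confidence"`) for explicit comparisons. Both bands use the
standard normal-theory formulas from `stats::predict.lm`.

Groups are fitted and classified independently (each taxon group has
its own diversification history and PD scale) and only the categorical
results are combined.

# Cross-group statistics

`surface_association()` reports the OLS fit and Pearson correlation
over jointly non-missing cells. Schoener's
$D = 1 - \tfrac12\sum_i |p_{a,i} - p_{b,i}|$ and the Hellinger-based
$I = 1 - \tfrac12\sum_i (\sqrt{p_{a,i}} - \sqrt{p_{b,i}})^2$ operate on
surfaces first rescaled to $[0,1]$ and then to proportions summing to 1
over the jointly non-missing cells — both steps are explicit in
`surfaces_to_proportions()`. Significance uses a permutation null
(`overlap_null()`): surface `b`'s cell values are permuted across its
non-missing cells, destroying spatial co-structure while preserving the
value distribution; the observed statistic is compared with the null
distribution by a one-sample two-sided t-test, and empirical ranks are
reported alongside. The permutation definition is this package's own
documented choice of null; spatially structured nulls (torus shifts
etc.) are out of scope. Default 99 permutations, configurable.
`category_chisq()` forms the 3×3 cross-table of per-cell joint
categories (df = 4 when all margins are occupied) and applies Pearson's
chi-square without continuity correction; empty margins are dropped
with a warning.

# The paired extinction experiment

The theoretical module grows two communities that are identical in
every parameter except the survival probability of episodic mass
extinctions:

* Forward birth–death from a single lineage, speciation rate
  $\lambda = 1.75$ and background extinction $\mu = 0.1$ per lineage
  per time unit, active in all three epochs.
* Two instantaneous mass extinctions at fixed times shared by both
  arms; each extant lineage survives an event independently with
  probability $x$. The stable (refugium) arm uses
  $x_{stable} = 0.9 + 0.10\,x_{unstable}$, keeping its per-event
  survival in $[0.9, 1]$ and proportional to the unstable arm's.
* The simulation stops at the first point after the final event at
  which the extant count equals the richness target (10 or 100); the
  stop time is drawn uniformly within the waiting interval during which
  the count sits at the target, so terminal branches are strictly
  positive. Attempts that die out, or that overshoot the target after
  the final event (a state that cannot practically return to the target
  against the positive net diversification rate), restart on a fresh
  substream.
* Extinct lineages are pruned; the reconstructed tree of the extant
  community is ultrametric with exactly the target number of tips, and
  MPD and MNTD are computed on its full tip set.

Event times default to $t = 1.2, 2.4$ for a target of 100 and
$t = 0.5, 1.0$ for a target of 10 — chosen so the expected lineage
count entering each event is well below the target, i.e. the events act
on small radiating communities — and are config-exposed. 200 paired
replicates per scenario are compared by Welch t-tests oriented *stable
minus unstable*, so underdispersion of the refugium arm appears as
negative $t$.

Per-replicate and per-arm random substreams are derived from the root
seed by an integer hash, making experiments reproducible and the two
arms independent.

## Behaviour and a known limitation

Across the shipped survival ladder at richness 100, mean MPD of the
unstable arm exceeds the stable arm in every preset: heavier thinning
forces the unstable community to regrow over a longer total time, so
its reconstructed tree is older and pairwise distances are larger. The
effect strengthens with the survival gap (the 70%/7% preset separates
strongly, $t \approx -8$ at 200 replicates; 10%/1% sits near the
significance boundary) and collapses at low diversity (target 10), where
the distributions overlap too much to separate.

MNTD, in contrast, shows no reliable directional signal under this
conditioning: nearest-neighbour distances are set by the tempo of the
most recent radiation, which both arms share ($\lambda$ and $\mu$ are
identical), and the stop-at-attainment rule leaves almost no
post-attainment time during which background extinction could prune
tips and stretch pendant branches. An age-conditioned simulation (fix
the present, place events at fixed ages before it, and condition on the
tip count at the present) would stretch the unstable arm's branches —
pendant ones included — and is the natural mechanism by which both MPD
*and* MNTD separate; that conditioning (general sampling approach) is
deliberately out of scope in this version, and the corresponding MNTD
direction check in the acceptance suite documents the gap rather than
papering over it.

# The synthetic world

`gen_world()` builds two taxon groups over a shared planar grid
(default 20×20 cells of edge 0.1 — the same point-sampling geometry as
a 0.1° lattice, at desk scale). Geometry is deliberately planar:
nothing downstream uses spherical area, so no geodesy is implemented.

* **Trees.** Each group gets a reference birth–death tree (default
  pure-birth, 50 tips) from the same forward simulator as the
  theoretical module, and $T$ posterior-like trees (default 100)
  obtained by multiplying each branch by independent lognormal noise
  with median 1 (`jitter_sd` = 0.1). Jitter on a fixed topology, rather
  than topology resampling, is enough because the pipeline consumes
  only branch lengths per tree, and it keeps oracle checks tractable.
* **Ranges.** Species ranges are ellipses (center, semi-axes, rotation)
  rasterized by center-point containment — the simplest shape with
  controllable area and overlap. Range centers are sampled from a
  latent intensity field: a low floor (0.002) plus two Gaussian blobs
  (sd 0.3) whose centers avoid the refugium. The sharp field creates
  strong richness gradients (diverse cores, sparse margins), and
  because both groups sample the *same* shared field
  (`shared_field_weight` = 1 by default), their realized richness
  surfaces correlate positively — the generator's analogue of two
  co-distributed vertebrate classes. Setting the weight to 0 gives each
  group its own independent field and collapses the correlation.
* **The planted refugium.** An elliptical region (~12% of the domain)
  is designated the refugium. A focal clade — the most phylogenetically
  compact clade whose size is near the refugium's share of the domain —
  is preferentially centered inside it (probability
  `clustering_strength`, default 0.9), while other species are centered
  outside; refugial-clade ranges are sized to the refugium itself,
  mirroring lineages that persist and spread within a stable region.
  At strength 0 all centers are placed without regard to the refugium;
  at strength 1 every refugium-centered species belongs to the clade.
* **Ecoregions.** The grid is partitioned by a Voronoi tessellation of
  random seed cells; when a refugium is supplied its cells form one
  dedicated ecoregion and the remainder is tessellated around it.
  Aligning ecoregion boundaries with the refugium reflects that
  ecoregions are habitat units and a refugium is a habitat — and it is
  what makes ecoregion-level recovery of the planted signal a
  well-posed question.

All generators are pure functions of (parameters, seed): the same
configuration yields a byte-identical serialized world, and sub-seeds
for trees, fields, ranges and ecoregions are derived from the root seed.

What the generator does *not* emulate: real range-map error structure
(lacustrine artefacts, political-boundary clipping), spherical-area
effects, taxonomic placement uncertainty beyond branch-length jitter,
spatial autocorrelation of residuals, or island/mainland gridding
differences (the domain is a single rectangle). Passing the planted
signal therefore shows the *pipeline* recovers a known signal of this
kind; it does not validate any claim about real faunas.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as
the package's own study conditions: 200 paired replicates per
simulation scenario at richness targets 10 and 100; 100 seeded worlds
(20×20 grid, 50+50 species, 10 trees per group for the planted-signal
sweep, 100 trees by default elsewhere); 1000 random tree/community
instances (up to 30 tips) for oracle equivalence at a relative
tolerance of $10^{-12}$; classifier calibration at $10^4$ cells.

Degenerate inputs are handled explicitly rather than silently:
constant richness aborts the regression; constant surfaces normalize to
zero with a warning; all-missing surfaces are errors; zero-variance
permutation nulls are flagged rather than given a fabricated p-value;
communities below the metric's minimum size are missing values; empty
chi-square margins are dropped with a warning. Grid cells are indexed
row-major, 0-based, from the lower-left corner, and every tabular
output carries explicit cell-center coordinates so files are
self-describing; missing values in CSV output are empty fields, never
sentinels. Boundary points count as inside ranges (closed-boundary
point sampling), a convention that is documented and tested.
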