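# phylorefugia

Community phylogenetics on spatial presence–absence grids, and a paired
birth–death experiment on what extinction alone does to community
relatedness.

## The scientific problem

Communities with *low* phylogenetic diversity relative to their species
richness (underdispersed communities) are classically read as evidence
of environmental filtering. An alternative reading is biogeographic:
regions that act as climatic refugia suppress extinction, lineages
persist and keep diversifying in place, and close relatives accumulate —
producing the same underdispersed signature without any filtering.
Distinguishing these stories requires (i) mapping dispersion across a
landscape for multiple taxon groups and (ii) a theoretical test of
whether reduced extinction is, by itself, sufficient to create
underdispersion.

`phylorefugia` provides both halves as a tested, reusable pipeline for
researchers in community phylogenetics and macroecology:

* **Metrics** — first-principles MPD, MNTD and Faith's PD over sets of
  posterior trees on a sampling grid:
  MPD = (2/(n(n−1))) Σ<sub>i&lt;j</sub> d(i,j),
  MNTD = (1/n) Σ<sub>i</sub> min<sub>j≠i</sub> d(i,j),
  PD = total branch length of the community's minimal spanning subtree.
* **Dispersion** — OLS regression PD = β₀ + β₁·richness; cells below /
  within / above a 95% band are coded 0 / 1 / 2, averaged by ecoregion
  and rescaled to [−1, 1], and combinable across taxon groups.
* **Comparison** — Schoener's D and the Hellinger-based I overlap of two
  surfaces (with a permutation null), surface regressions/correlations,
  the 3×3 categorical chi-square (df = 4), Welch t-tests.
* **Simulation** — paired forward birth–death communities (λ = 1.75,
  μ = 0.1) grown through three epochs separated by two mass extinctions;
  the stable (refugium) arm survives each event with probability
  x<sub>stable</sub> = 0.9 + 0.10·x<sub>unstable</sub>; both arms are
  conditioned on the same extant richness and compared by Welch t-tests
  on MPD and MNTD over 200 replicates.
* **Synthetic data** — seeded generator for trees, elliptical species
  ranges on a latent richness field, ecoregion partitions, and a planted
  refugium where co-occurring species come from one compact clade — so
  the full pipeline is testable without any external downloads.

## Worked example

```r
library(phylorefugia)

world <- gen_world(world_config(seed = 42, n_trees = 25))
grp   <- world$groups$A

cm   <- rasterize_presence(grp$ranges, world$grid, group = "A")
rich <- richness(cm)
pd   <- summarize_over_trees(cm, grp$trees, metric = "pd")

fit <- fit_pd_richness(pd, rich)
fit
#> dispersion_fit: PD = -0.1924 + 2.079 * richness (n = 193, adj R^2 = 0.619, sigma = 6.365)

cl <- classify_cells(fit, pd, rich, band = "prediction")
table(category = cl$category, useNA = "ifany")
#> category
#>    0    1 <NA>
#>   16  177  207

rc <- refugium_contrast(world)
rc$cell_diff; rc$eco_diff
#> refugium vs elsewhere, mean category difference: -0.359 (cells), -0.360 (ecoregions)
```

193 of the 400 grid cells host at least one species and enter the
regression; 16 cells fall below the 95% prediction band (category 0,
underdispersed) and none above it. The planted refugium is recovered:
its cells average a dispersion category 0.36 lower than the rest of the
landscape, i.e. the refugium is where PD falls short of what richness
predicts. Cross-group structure behaves like the co-distributed faunas
it emulates:

```r
cmB <- rasterize_presence(world$groups$B$ranges, world$grid, group = "B")
surface_association(rich, richness(cmB))$correlation
#> 0.88
overlap_null(normalize_surface(rich), normalize_surface(richness(cmB)),
             n_null = 99, seed = 1)
#> overlap: D = 0.7917 (0/99 null >= obs), I = 0.9477 (0/99 null >= obs)
```

The theoretical experiment — does suppressing extinction alone create
underdispersion? — contrasts per-event survival 0.30 (unstable) with
0.93 (stable, via the mapping above) at richness 100:

```r
ex <- run_experiment(sim_scenario(0.3, richness_target = 100,
                                  reps = 200, seed = 1))
ex
#> sim_experiment 'u0.30-s0.93-n100': 200 paired replicates (n = 100 tips)
#>   MPD  stable 4.119 vs unstable 4.712: t = -8.28, df = 349.5, p = 2.68e-15
#>   MNTD stable 0.588 vs unstable 0.583: t = 0.69, df = 397.5, p = 0.492
```

The refugium arm ends up with clearly lower MPD than its high-extinction
twin (negative t, stable minus unstable): reduced extinction alone is
sufficient to produce a phylogenetically underdispersed community. MNTD
does not separate under this conditioning; the methods vignette
(`vignettes/phylorefugia-methods.Rmd`) discusses why, along with every
modelling choice and its alternatives.

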