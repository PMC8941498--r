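# Synthetic worlds: trees, posterior jitter, ecoregions, ranges, and
# whole-world generation.

test_that("gen_tree is ultrametric, sized, and deterministic", {
  t2 <- gen_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  d <- ape::node.depth.edgelength(t2)
  expect_equal(d[1], d[2], tolerance = 1e-9)  # equal root-to-tip paths
  a <- gen_tree(30, 1, 0.2, seed = 42)
  b <- gen_tree(30, 1, 0.2, seed = 42)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_false(identical(ape::write.tree(a),
                         ape::write.tree(gen_tree(30, 1, 0.2, seed = 43))))
  expect_true(ape::is.ultrametric(a, tol = 1e-6))
  expect_error(gen_tree(1), "n_tips")
  expect_error(gen_tree(10, 0.5, 0.7), "death")
})

test_that("posterior jitter preserves topology and mean branch lengths", {
  tree <- gen_tree(20, seed = 8)
  D <- cophenetic_distances(tree)
  full <- tree$tip.label
  # zero jitter: exact copies
  exact <- gen_posterior_set(tree, 5, 0, seed = 1)
  expect_length(exact, 5)
  for (tr in exact) expect_equal(mpd(full, cophenetic_distances(tr)),
                                 mpd(full, D))
  # T = 0 is a parameter error
  expect_error(gen_posterior_set(tree, 0, 0.1), "n_trees")
  # law of large numbers: per-branch mean within 5% of the original
  set100 <- gen_posterior_set(tree, 100, 0.1, seed = 2)
  lens <- sapply(set100, function(tr) tr$edge.length)
  rel <- rowMeans(lens) / tree$edge.length
  expect_true(all(abs(rel - 1) < 0.05))
  # same topology throughout
  expect_true(all(sapply(set100, function(tr) identical(tr$edge, tree$edge))))
})

test_that("ecoregion partitions cover every cell exactly once", {
  g <- grid_spec(0, 0, 1, 1, 0.1)
  e1 <- gen_ecoregions(g, 1, seed = 1)
  expect_equal(unique(e1$ecoregion), 1)
  en <- gen_ecoregions(g, g$n_cells, seed = 1)
  expect_equal(sort(unique(en$ecoregion)), seq_len(g$n_cells))
  ek <- gen_ecoregions(g, 7, seed = 5)
  expect_equal(sum(table(ek$ecoregion)), g$n_cells)
  expect_false(anyNA(ek$ecoregion))
  expect_identical(ek$ecoregion, gen_ecoregions(g, 7, seed = 5)$ecoregion)
  expect_error(gen_ecoregions(g, 0), "k")
  expect_error(gen_ecoregions(g, g$n_cells + 1), "k")
  # refugium carve-out: inside cells form one dedicated region
  ref <- ellipse_polygon(0.5, 0.5, 0.25, 0.2)
  er <- gen_ecoregions(g, 6, seed = 2, refugium = ref)
  ctr <- grid_centers(g)
  in_ref <- point_in_polygon(ctr$x, ctr$y, ref)
  expect_true(all(er$ecoregion[in_ref] == 6))
  expect_true(all(er$ecoregion[!in_ref] < 6))
})

test_that("range generation plants a clade signal that scales with strength", {
  g <- grid_spec(0, 0, 2, 2, 0.1)
  ref <- ellipse_polygon(0.6, 1.4, 0.45, 0.35, 0.4)
  tree <- gen_tree(40, seed = 31)
  # clustering 1: every refugium-centered species is in the focal clade,
  # and the clade is no more diverse than the tree at large
  r1 <- gen_ranges(tree, g, ref, clustering_strength = 1, seed = 7)
  ctrs <- attr(r1, "centers")
  expect_true(all(ctrs$in_clade[ctrs$in_refugium]))
  D <- cophenetic_distances(tree)
  expect_lte(mpd(attr(r1, "clade_tips"), D), mpd(tree$tip.label, D))
  # every polygon intersects the grid domain (centers lie inside it)
  for (poly in r1) {
    expect_true(max(poly$x) >= 0 && min(poly$x) <= 2 &&
                  max(poly$y) >= 0 && min(poly$y) <= 2)
  }
  # clustering 0: refugium-centered species are an unbiased draw from the
  # tree, so their MPD shows no systematic deficit across worlds
  diffs <- c()
  for (s in 1:40) {
    tr <- gen_tree(40, seed = 200 + s)
    rg <- gen_ranges(tr, g, ref, clustering_strength = 0, seed = 300 + s)
    cc <- attr(rg, "centers")
    Ds <- cophenetic_distances(tr)
    if (sum(cc$in_refugium) >= 2 && sum(!cc$in_refugium) >= 2) {
      diffs <- c(diffs,
                 mpd(cc$species[cc$in_refugium], Ds) -
                   mpd(cc$species[!cc$in_refugium], Ds))
    }
  }
  expect_gt(stats::t.test(diffs, mu = 0)$p.value, 0.001)
  expect_error(gen_ranges(tree, g, ref, clustering_strength = 2), "clustering")
})

test_that("worlds are deterministic and share grid and ecoregions", {
  cfg <- world_config(seed = 3, n_trees = 2, n_species = c(A = 15, B = 15))
  w1 <- gen_world(cfg)
  w2 <- gen_world(cfg)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  expect_identical(unclass(w1$grid), unclass(w1$grid))
  expect_equal(length(w1$groups$A$trees), 2)
  expect_equal(length(w1$groups$B$tree$tip.label), 15)
  # group trees and ranges are aligned
  expect_setequal(names(w1$groups$A$ranges), w1$groups$A$tree$tip.label)
})

test_that("shared latent field induces positive richness correlation", {
  rich_cor <- function(cfg) {
    w <- gen_world(cfg)
    cor(rowSums(rasterize_presence(w$groups$A$ranges, w$grid)$pa),
        rowSums(rasterize_presence(w$groups$B$ranges, w$grid)$pa))
  }
  cors1 <- sapply(1:15, function(s)
    rich_cor(world_config(seed = s, n_trees = 1)))
  expect_gte(sum(cors1 > 0.5), 13)
  # without the shared field (and without refugium coupling) the
  # correlation collapses towards zero
  cors0 <- sapply(1:15, function(s)
    rich_cor(world_config(seed = s, n_trees = 1, shared_field_weight = 0,
                          clustering_strength = 0)))
  expect_lt(mean(cors0), 0.35)
  expect_gt(mean(cors1) - mean(cors0), 0.3)
})

test_that("a generated world round-trips through its disk format", {
  w <- gen_world(world_config(seed = 5, n_trees = 2,
                              n_species = c(A = 10, B = 10)))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  tr <- read_newick(file.path(dir, "A", "reference.nwk"))
  expect_setequal(tr$tip.label, w$groups$A$tree$tip.label)
  rg <- read_ranges_geojson(file.path(dir, "A", "ranges.geojson"))
  expect_setequal(names(rg), names(w$groups$A$ranges))
  eco <- utils::read.csv(file.path(dir, "ecoregions.csv"))
  expect_equal(nrow(eco), w$grid$n_cells)
})
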