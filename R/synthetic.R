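#' Generate an ultrametric birth-death tree with a fixed tip count
#'
#' Forward-time birth-death simulation (no mass-extinction events)
#' conditioned on reaching `n_tips` extant lineages, pruned to the
#' reconstructed extant tree.  Deterministic given the seed.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> death_rate).
#' @param death_rate per-lineage extinction rate (>= 0).
#' @param seed integer seed.
#' @param tip_prefix label prefix; tips are renamed
#'   `sprintf("%s%03d", tip_prefix, 1:n_tips)`.
#' @return An ultrametric `phylo` object with `n_tips` tips.
#' @export
gen_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1,
                     tip_prefix = "sp") {
  if (!is_count(n_tips, min = 2)) stop("`n_tips` must be an integer >= 2")
  if (!is_scalar_num(birth_rate) || birth_rate <= 0) {
    stop("`birth_rate` must be positive")
  }
  if (!is_scalar_num(death_rate) || death_rate < 0 || birth_rate <= death_rate) {
    stop("require birth_rate > death_rate >= 0")
  }
  tree <- simulate_bd_mass_extinction(
    birth_rate, death_rate,
    epoch_schedule(numeric(0), numeric(0)),
    richness_target = n_tips, seed = seed
  )
  tree$tip.label <- sprintf("%s%03d", tip_prefix, seq_len(n_tips))
  tree
}

#' Emulate a posterior sample of trees by branch-length jitter
#'
#' Returns `T` trees with the input topology; every branch length is
#' multiplied by an independent lognormal factor with median 1 and log
#' scale `jitter_sd`, emulating branch-length uncertainty across a
#' posterior sample without resampling topology.  `jitter_sd = 0`
#' returns exact copies.
#'
#' @param tree a `phylo` object.
#' @param n_trees number of trees T (>= 1).
#' @param jitter_sd lognormal sigma of the multiplicative noise (>= 0).
#' @param seed integer seed.
#' @return A list of `phylo` objects of length `n_trees`.
#' @export
gen_posterior_set <- function(tree, n_trees = 100, jitter_sd = 0.1, seed = 1) {
  validate_tree(tree)
  if (!is_count(n_trees, min = 1)) stop("`n_trees` must be an integer >= 1")
  if (!is_scalar_num(jitter_sd) || jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  ne <- length(tree$edge.length)
  with_preserved_seed(seed, {
    lapply(seq_len(n_trees), function(k) {
      out <- tree
      if (jitter_sd > 0) {
        out$edge.length <- tree$edge.length * stats::rlnorm(ne, 0, jitter_sd)
      }
      out
    })
  })
}

#' Partition a grid into contiguous ecoregions
#'
#' Voronoi tessellation of `k` randomly chosen seed cells: every cell is
#' assigned to its nearest seed (Euclidean distance between cell
#' centers, ties broken by lowest seed index), yielding contiguous
#' regions.  Deterministic given the seed.
#'
#' When a `refugium` polygon is supplied, ecoregion boundaries are
#' aligned with it (ecoregions are habitat units and the refugium is a
#' habitat): cells whose centers fall inside the refugium form one
#' dedicated ecoregion (id `k`) and the remaining cells are
#' Voronoi-partitioned into `k - 1` regions seeded outside the
#' refugium.
#'
#' @param grid a [grid_spec()].
#' @param k number of ecoregions (1 <= k <= number of cells).
#' @param seed integer seed.
#' @param refugium optional polygon to carve out as its own ecoregion
#'   (requires k >= 2 and a refugium covering some but not all cell
#'   centers).
#' @return An [ecoregion_map()].
#' @export
gen_ecoregions <- function(grid, k, seed = 1, refugium = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is_count(k, min = 1) || k > grid$n_cells) {
    stop("`k` must be an integer in [1, number of cells]")
  }
  ctr <- grid_centers(grid)
  voronoi <- function(cells, n_regions) {
    # assign `cells` (indices) to their nearest of n_regions seed cells
    with_preserved_seed(seed, {
      seeds <- cells[sample.int(length(cells), n_regions)]
      d2 <- matrix(0, nrow = length(cells), ncol = n_regions)
      for (j in seq_len(n_regions)) {
        d2[, j] <- (ctr$x[cells] - ctr$x[seeds[j]])^2 +
          (ctr$y[cells] - ctr$y[seeds[j]])^2
      }
      max.col(-d2, ties.method = "first")
    })
  }
  if (is.null(refugium)) {
    return(ecoregion_map(grid, voronoi(seq_len(grid$n_cells), k)))
  }
  in_ref <- point_in_polygon(ctr$x, ctr$y, refugium)
  if (!any(in_ref) || all(in_ref)) {
    stop("refugium must cover some, but not all, cell centers")
  }
  if (k < 2) stop("k must be >= 2 when carving out a refugium ecoregion")
  ids <- integer(grid$n_cells)
  ids[in_ref] <- k
  ids[!in_ref] <- voronoi(which(!in_ref), k - 1L)
  ecoregion_map(grid, ids)
}

#' Construct an ecoregion map
#'
#' @param grid a [grid_spec()].
#' @param ecoregion integer/character ecoregion id per cell (row-major
#'   cell order); every cell must have exactly one id.
#' @param meta optional named vector mapping ecoregion id ->
#'   meta-region id.
#' @return A data frame of class `ecoregion_map` with columns `cell`,
#'   `x`, `y`, `ecoregion`.
#' @export
ecoregion_map <- function(grid, ecoregion, meta = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(ecoregion) != grid$n_cells || anyNA(ecoregion)) {
    stop("every grid cell needs exactly one ecoregion id")
  }
  out <- cbind(grid_centers(grid), ecoregion = ecoregion)
  structure(out, class = c("ecoregion_map", "data.frame"),
            grid = grid, meta = meta)
}

#' Write an ecoregion map as CSV
#'
#' @param ecoregions an [ecoregion_map()].
#' @param path output file.
#' @export
write_ecoregions_csv <- function(ecoregions, path) {
  stopifnot(inherits(ecoregions, "ecoregion_map"))
  utils::write.csv(as.data.frame(ecoregions), path, row.names = FALSE)
  invisible(path)
}

# Sample n cell indices proportional to `weights`, restricted to cells
# where `mask` is TRUE.
sample_cells <- function(n, weights, mask) {
  w <- weights * mask
  if (sum(w) <= 0) stop("no cells available with positive weight")
  sample.int(length(w), n, replace = TRUE, prob = w)
}

#' Generate elliptical species ranges with a planted refugium signal
#'
#' One elliptical range polygon per tip of `tree`.  A focal clade
#' (subtree whose size best matches the refugium's share of the domain)
#' is preferentially centered inside the refugium: with probability
#' `clustering_strength` a clade species' range center is drawn inside
#' the refugium and a non-clade species' center outside; with the
#' complementary probability centers are placed without regard to the
#' refugium.  `clustering_strength = 0` therefore places all centers at
#' random, and at 1 every range centered in the refugium belongs to the
#' focal clade, making refugium communities phylogenetically clustered.
#'
#' @param tree the group's reference tree (tip labels become species
#'   ids).
#' @param grid a [grid_spec()].
#' @param refugium a polygon inside the grid domain.
#' @param clustering_strength value in `[0, 1]`.
#' @param range_scale mean range diameter in grid units.
#' @param seed integer seed.
#' @param intensity optional per-cell positive weights (a latent
#'   richness field) biasing where range centers fall; uniform when
#'   omitted.
#' @param clade_fraction target share of tips in the focal clade;
#'   defaults to the refugium's area share of the domain (at least
#'   0.25).
#' @return A named list of polygons of class `range_set`, with
#'   attributes `centers` (data frame with `species`, `x`, `y`,
#'   `in_refugium`, `in_clade`) and `clade_tips`.
#' @export
gen_ranges <- function(tree, grid, refugium, clustering_strength = 0.9,
                       range_scale = 0.35, seed = 1, intensity = NULL,
                       clade_fraction = NULL) {
  validate_tree(tree)
  stopifnot(inherits(grid, "grid_spec"))
  if (!is_prob(clustering_strength)) {
    stop("`clustering_strength` must lie in [0, 1]")
  }
  if (!is_scalar_num(range_scale) || range_scale <= 0) {
    stop("`range_scale` must be positive")
  }
  if (polygon_area(refugium) <= 0) stop("degenerate refugium polygon")
  n_tips <- length(tree$tip.label)
  if (n_tips < 2) stop("tree must have at least 2 tips")
  ctr <- grid_centers(grid)
  in_ref <- point_in_polygon(ctr$x, ctr$y, refugium)
  if (!any(in_ref) || all(in_ref)) {
    stop("refugium must cover some, but not all, cell centers")
  }
  if (is.null(intensity)) intensity <- rep(1, grid$n_cells)
  stopifnot(length(intensity) == grid$n_cells, all(intensity >= 0))

  domain_area <- (grid$x_max - grid$x_min) * (grid$y_max - grid$y_min)
  if (is.null(clade_fraction)) {
    clade_fraction <- max(polygon_area(refugium) / domain_area, 0.25)
  }
  clade_tips <- pick_clade(tree, clade_fraction)

  res <- grid$resolution
  with_preserved_seed(seed, {
    centers <- data.frame(species = tree$tip.label,
                          x = NA_real_, y = NA_real_,
                          in_refugium = NA, in_clade = tree$tip.label %in% clade_tips)
    ranges <- vector("list", n_tips)
    names(ranges) <- tree$tip.label
    for (s in seq_len(n_tips)) {
      targeted <- stats::runif(1) < clustering_strength
      mask <- if (!targeted) rep(TRUE, grid$n_cells)
              else if (centers$in_clade[s]) in_ref else !in_ref
      # jitter within the chosen cell; keep the point's refugium
      # membership consistent with the targeted region
      for (try in 1:50) {
        cell <- sample_cells(1L, intensity, mask)
        px <- ctr$x[cell] + stats::runif(1, -res / 2, res / 2)
        py <- ctr$y[cell] + stats::runif(1, -res / 2, res / 2)
        p_in <- point_in_polygon(px, py, refugium)
        if (!targeted || p_in == centers$in_clade[s]) break
      }
      centers$x[s] <- px; centers$y[s] <- py
      centers$in_refugium[s] <- p_in
      if (targeted && centers$in_clade[s]) {
        # refugial-clade species persist and spread across the refugium:
        # size their ranges to the refugium itself
        rr <- sqrt(polygon_area(refugium) / pi)
        a <- rr * stats::runif(1, 0.6, 1.1)
        b <- rr * stats::runif(1, 0.6, 1.1)
      } else {
        a <- range_scale / 2 * stats::runif(1, 0.6, 1.4)
        b <- range_scale / 2 * stats::runif(1, 0.6, 1.4)
      }
      ang <- stats::runif(1, 0, pi)
      ranges[[s]] <- ellipse_polygon(px, py, a, b, ang)
    }
    structure(ranges, class = "range_set",
              centers = centers, clade_tips = clade_tips)
  })
}

# Internal: choose the focal refugium clade.  Among internal nodes
# whose tip count is within +/-40% of `fraction` of all tips, take the
# phylogenetically most compact one (lowest within-clade MPD), so the
# planted clade genuinely carries less diversity than a same-sized
# random draw; falls back to the node nearest the size target.
pick_clade <- function(tree, fraction) {
  ti <- tree_indices(tree)
  target <- max(2, round(fraction * ti$ntip))
  sizes <- numeric(ti$ntot)
  sizes[seq_len(ti$ntip)] <- 1
  for (v in rev(ti$bfs)) {
    ch <- ti$children[[v]]
    if (length(ch)) sizes[v] <- sum(sizes[ch])
  }
  internal <- (ti$ntip + 1L):ti$ntot
  internal <- internal[sizes[internal] < ti$ntip]  # exclude the root
  cand <- internal[sizes[internal] >= max(2, floor(0.6 * target)) &
                   sizes[internal] <= ceiling(1.4 * target)]
  tips_below <- function(node) {
    tips <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      ch <- ti$children[[v]]
      if (length(ch)) stack <- c(stack, ch) else tips <- c(tips, v)
    }
    tips
  }
  if (length(cand)) {
    D <- cophenetic_distances(tree)
    within_mpd <- vapply(cand, function(v) {
      tl <- tree$tip.label[tips_below(v)]
      mpd(tl, D)
    }, numeric(1))
    best <- cand[which.min(within_mpd)]
  } else {
    best <- internal[which.min(abs(sizes[internal] - target))]
  }
  tree$tip.label[tips_below(best)]
}

#' Configuration for a synthetic world
#'
#' Bundles the generator parameters of [gen_world()].  Defaults emulate
#' the structure of the empirical setting at desk scale: two taxon
#' groups on a shared 20 x 20 grid of 0.1-unit cells, 50 species and
#' 100 posterior-like trees per group, a shared latent richness field
#' (so the groups' richness surfaces correlate positively), an
#' elliptical refugium covering roughly an eighth of the domain, and
#' strong phylogenetic clustering of refugium species.
#'
#' @param grid a [grid_spec()].
#' @param n_species named vector, species per group.
#' @param n_trees posterior-like trees per group.
#' @param jitter_sd branch-length jitter of the posterior emulation.
#' @param birth_rate,death_rate rates for the groups' reference trees.
#' @param refugium refugium polygon.
#' @param clustering_strength see [gen_ranges()].
#' @param range_scale mean range diameter.
#' @param shared_field_weight weight in `[0, 1]` of the shared latent
#'   intensity field (1 = both groups share one field).
#' @param n_blobs,blob_sd Gaussian blobs composing each latent field.
#' @param k_ecoregions ecoregion count.
#' @param seed root seed; all sub-generators derive substreams from it.
#' @return A list of class `world_config`.
#' @export
world_config <- function(grid = grid_spec(0, 0, 2, 2, 0.1),
                         n_species = c(A = 50, B = 50),
                         n_trees = 100,
                         jitter_sd = 0.1,
                         birth_rate = 1, death_rate = 0,
                         refugium = ellipse_polygon(0.6, 1.4, 0.45, 0.35, 0.4),
                         clustering_strength = 0.9,
                         range_scale = 0.5,
                         shared_field_weight = 1,
                         n_blobs = 2, blob_sd = 0.3,
                         k_ecoregions = 15,
                         seed = 1) {
  stopifnot(inherits(grid, "grid_spec"), length(n_species) == 2,
            !is.null(names(n_species)),
            is_prob(shared_field_weight), is_prob(clustering_strength))
  structure(as.list(environment()), class = "world_config")
}

# Latent intensity field: a floor plus Gaussian blobs at random centers.
# The low floor concentrates species into the blobs, giving the strong
# richness gradients (diverse cores, near-empty margins) that make two
# groups sampling the same field visibly co-vary.  Blob centers can be
# kept away from an `avoid` polygon (the refugium): the field models
# richness hotspots of the unstable landscape, while refugium richness
# accumulates through in-situ diversification of the focal clade.
gen_intensity <- function(grid, n_blobs, blob_sd, seed, floor = 0.002,
                          avoid = NULL, avoid_buffer = 0.25) {
  ctr <- grid_centers(grid)
  with_preserved_seed(seed, {
    f <- rep(floor, grid$n_cells)
    for (b in seq_len(n_blobs)) {
      for (try in 1:200) {
        bx <- stats::runif(1, grid$x_min, grid$x_max)
        by <- stats::runif(1, grid$y_min, grid$y_max)
        if (is.null(avoid)) break
        d <- min(sqrt((avoid$x - bx)^2 + (avoid$y - by)^2))
        if (!point_in_polygon(bx, by, avoid) && d > avoid_buffer) break
      }
      f <- f + exp(-((ctr$x - bx)^2 + (ctr$y - by)^2) / (2 * blob_sd^2))
    }
    f
  })
}

#' Generate a complete synthetic world
#'
#' Two taxon groups ("A" emulating mammals, "B" emulating birds) over a
#' shared grid and ecoregion partition.  Each group receives a
#' reference birth-death tree, a set of jittered posterior-like trees,
#' and elliptical ranges placed by a latent intensity field that is a
#' mixture of a shared and a group-specific field
#' (`shared_field_weight` controls the mixture), so realized per-cell
#' richness of the two groups is positively correlated.  Species of a
#' focal clade are concentrated in the refugium (see [gen_ranges()]),
#' planting a phylogenetic-underdispersion signal there.  All
#' randomness derives from the config seed; the same config yields a
#' byte-identical world.
#'
#' @param config a [world_config()].
#' @return A list of class `synthetic_world`: `grid`, `refugium`,
#'   `ecoregions`, `groups` (each with `name`, `tree`, `trees`,
#'   `ranges`), `config`.
#' @export
gen_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  shared <- gen_intensity(cfg$grid, cfg$n_blobs, cfg$blob_sd,
                          derive_seed(cfg$seed, 101), avoid = cfg$refugium)
  groups <- list()
  for (gi in seq_along(cfg$n_species)) {
    gname <- names(cfg$n_species)[gi]
    own <- gen_intensity(cfg$grid, cfg$n_blobs, cfg$blob_sd,
                         derive_seed(cfg$seed, 200 + gi), avoid = cfg$refugium)
    intensity <- cfg$shared_field_weight * shared +
      (1 - cfg$shared_field_weight) * own
    tree <- gen_tree(cfg$n_species[[gi]], cfg$birth_rate, cfg$death_rate,
                     seed = derive_seed(cfg$seed, 300 + gi),
                     tip_prefix = paste0(tolower(gname), "_sp"))
    trees <- gen_posterior_set(tree, cfg$n_trees, cfg$jitter_sd,
                               seed = derive_seed(cfg$seed, 400 + gi))
    ranges <- gen_ranges(tree, cfg$grid, cfg$refugium,
                         clustering_strength = cfg$clustering_strength,
                         range_scale = cfg$range_scale,
                         seed = derive_seed(cfg$seed, 500 + gi),
                         intensity = intensity)
    groups[[gname]] <- list(name = gname, tree = tree, trees = trees,
                            ranges = ranges)
  }
  eco <- gen_ecoregions(cfg$grid, cfg$k_ecoregions,
                        seed = derive_seed(cfg$seed, 600),
                        refugium = cfg$refugium)
  structure(list(grid = cfg$grid, refugium = cfg$refugium,
                 ecoregions = eco, groups = groups, config = cfg),
            class = "synthetic_world")
}

#' Write a synthetic world to disk
#'
#' Trees as Newick (one file per tree plus the reference tree), ranges
#' as GeoJSON, ecoregions as CSV, and a JSON manifest.
#'
#' @param world a [gen_world()] result.
#' @param dir output directory.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = world$config$seed,
                   grid = unclass(world$grid), groups = list())
  for (g in world$groups) {
    gdir <- file.path(dir, g$name)
    dir.create(file.path(gdir, "trees"), showWarnings = FALSE, recursive = TRUE)
    write_newick(g$tree, file.path(gdir, "reference.nwk"))
    for (k in seq_along(g$trees)) {
      write_newick(g$trees[[k]],
                   file.path(gdir, "trees", sprintf("tree_%03d.nwk", k)))
    }
    write_ranges_geojson(g$ranges, file.path(gdir, "ranges.geojson"))
    manifest$groups[[g$name]] <- list(
      n_species = length(g$tree$tip.label),
      n_trees = length(g$trees),
      reference_tree = file.path(g$name, "reference.nwk"),
      ranges = file.path(g$name, "ranges.geojson"))
  }
  write_ecoregions_csv(world$ecoregions, file.path(dir, "ecoregions.csv"))
  rpoly <- world$refugium
  jsonlite::write_json(list(x = rpoly$x, y = rpoly$y),
                       file.path(dir, "refugium.json"), digits = NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Dispersion contrast between refugium and non-refugium areas
#'
#' Runs the full classification pipeline for one group of a synthetic
#' world -- rasterize ranges, compute richness and the across-trees
#' mean PD surface, fit the PD~richness regression, classify cells --
#' and contrasts the planted refugium with the rest of the domain at
#' both the cell and the ecoregion level.  Negative differences mean
#' the refugium is the more underdispersed (lower category) area, the
#' planted signal.
#'
#' @param world a [gen_world()] result.
#' @param group group name (default the first group).
#' @param band classification band type (see [classify_cells()]).
#' @return A list with `cell_diff` (mean refugium-cell category minus
#'   mean non-refugium category), `eco_diff` (same contrast on
#'   ecoregion mean categories, refugial = majority of cells inside the
#'   refugium), the `classification` and the `fit`.
#' @export
refugium_contrast <- function(world, group = names(world$groups)[1],
                              band = "prediction") {
  stopifnot(inherits(world, "synthetic_world"))
  g <- world$groups[[group]]
  if (is.null(g)) stop("unknown group: ", group)
  cm <- rasterize_presence(g$ranges, world$grid, group = group)
  rich <- richness(cm)
  pd_surf <- summarize_over_trees(cm, g$trees, metric = "pd")
  fit <- fit_pd_richness(pd_surf, rich)
  cl <- classify_cells(fit, pd_surf, rich, band = band)
  ctr <- grid_centers(world$grid)
  in_ref <- point_in_polygon(ctr$x, ctr$y, world$refugium)
  cat_in <- cl$category[in_ref]
  cat_out <- cl$category[!in_ref]
  cell_diff <- mean(cat_in, na.rm = TRUE) - mean(cat_out, na.rm = TRUE)
  eco_frac <- tapply(in_ref, world$ecoregions$ecoregion, mean)
  sc <- ecoregion_scores(cl, world$ecoregions)
  refugial <- eco_frac[as.character(sc$ecoregion)] > 0.5
  if (!any(refugial)) {
    # no ecoregion is majority-refugium: fall back to those with the
    # largest refugium share so the contrast is always defined
    refugial <- eco_frac[as.character(sc$ecoregion)] >=
      max(eco_frac[eco_frac > 0])
  }
  eco_diff <- mean(sc$mean_category[refugial], na.rm = TRUE) -
    mean(sc$mean_category[!refugial], na.rm = TRUE)
  list(cell_diff = cell_diff, eco_diff = eco_diff,
       classification = cl, fit = fit)
}
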