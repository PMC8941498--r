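# First-principles community metrics against hand values, brute-force
# path-walking oracles, and the established implementations in ape and
# picante.

test_that("newick round trip preserves topology, labels and lengths", {
  tr <- read_newick("(A:1,B:1):0;", text = TRUE)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(cophenetic_distances(tr)["A", "B"], 2)

  for (s in 1:20) {
    tree <- gen_tree(sample(5:40, 1), 1, 0.2, seed = s)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tree, path)
    back <- read_newick(path)
    back_D <- cophenetic_distances(back)
    D <- cophenetic_distances(tree)[rownames(back_D), colnames(back_D)]
    expect_equal(back_D, D, tolerance = 1e-8)
  }
})

test_that("malformed or invalid newick input is rejected with a reason", {
  expect_error(read_newick("((A:1,B:1):1;", text = TRUE), "unclosed")
  expect_error(read_newick("(A:1,B:1)):0;", text = TRUE), "position")
  expect_error(read_newick("(A:1,A:1);", text = TRUE), "duplicate")
  expect_error(read_newick("(A,B);", text = TRUE), "branch length")
})

test_that("cophenetic distances match hand values and independent oracles", {
  tr <- read_newick("((A:1,B:1):1,C:2):0;", text = TRUE)
  D <- cophenetic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))

  for (s in 1:15) {
    tree <- gen_tree(20, 1, 0.3, seed = 100 + s)
    D <- cophenetic_distances(tree)
    # naive path-walking oracle
    Do <- oracle_cophenetic(tree)
    expect_equal(D, Do[rownames(D), colnames(D)], tolerance = 1e-12)
    # established implementation
    Da <- as.matrix(stats::cophenetic(tree))
    expect_equal(D, Da[rownames(D), colnames(D)], tolerance = 1e-10)
  }
})

test_that("mpd, mntd and pd reproduce hand-computable examples", {
  tr <- read_newick("((A:1,B:1):1,C:2):0;", text = TRUE)
  D <- cophenetic_distances(tr)
  expect_equal(mpd(c("A", "B"), D), 2)
  expect_equal(mpd(c("A", "B", "C"), D), 10 / 3)
  expect_equal(mntd(c("A", "B", "C"), D), 8 / 3)
  expect_equal(mntd(c("A", "B"), D), mpd(c("A", "B"), D))
  expect_equal(faith_pd(c("A", "B"), tr), 2)            # the A-B path
  expect_equal(faith_pd(c("A", "B", "C"), tr), sum(tr$edge.length))
  expect_equal(faith_pd("A", tr), 0)                    # singleton, unrooted PD
  expect_equal(faith_pd("A", tr, include_root = TRUE), 2)
  # undefined metrics are missing, not zero
  expect_true(is.na(mpd("A", D)))
  expect_true(is.na(mntd("A", D)))
  expect_true(is.na(faith_pd(character(0), tr)))
  expect_error(mpd(c("A", "Z"), D), "Z")
})

test_that("metrics agree with brute-force oracles on random instances", {
  # the exhaustive equivalence suite: random trees up to 30 tips
  n_instances <- 300
  for (s in seq_len(n_instances)) {
    inst <- random_instance(s)
    D <- cophenetic_distances(inst$tree)
    expect_equal(mpd(inst$community, D), oracle_mpd(inst$community, D),
                 tolerance = 1e-12)
    expect_equal(mntd(inst$community, D), oracle_mntd(inst$community, D),
                 tolerance = 1e-12)
    expect_equal(faith_pd(inst$community, inst$tree),
                 oracle_pd(inst$community, inst$tree), tolerance = 1e-12)
    expect_equal(faith_pd(inst$community, inst$tree, include_root = TRUE),
                 oracle_pd(inst$community, inst$tree, include_root = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with picante on a community matrix", {
  tree <- gen_tree(25, 1, 0.2, seed = 77)
  set.seed(77)
  samp <- matrix(rbinom(10 * 25, 1, 0.4), nrow = 10,
                 dimnames = list(NULL, tree$tip.label))
  samp[rowSums(samp) < 2, 1:2] <- 1   # keep every community testable
  D <- cophenetic_distances(tree)
  got_mpd <- apply(samp, 1, function(r) mpd(colnames(samp)[r > 0], D))
  got_mntd <- apply(samp, 1, function(r) mntd(colnames(samp)[r > 0], D))
  got_pd <- apply(samp, 1, function(r) faith_pd(colnames(samp)[r > 0], tree))
  expect_equal(unname(got_mpd), picante::mpd(samp, D), tolerance = 1e-10)
  expect_equal(unname(got_mntd), picante::mntd(samp, D), tolerance = 1e-10)
  ppd <- picante::pd(samp, tree, include.root = FALSE)$PD
  expect_equal(unname(got_pd), ppd, tolerance = 1e-10)
})

test_that("metric inequalities, monotonicity and linear scaling hold", {
  for (s in 1:100) {
    inst <- random_instance(500 + s)
    tree <- inst$tree
    D <- cophenetic_distances(tree)
    comm <- inst$community
    m1 <- mpd(comm, D); m2 <- mntd(comm, D)
    expect_gte(m1, 0); expect_gte(m2, 0)
    expect_lte(m2, m1 + 1e-12)
    # PD monotone under adding a taxon
    extra <- setdiff(tree$tip.label, comm)
    if (length(extra)) {
      expect_gte(faith_pd(c(comm, extra[1]), tree) + 1e-12,
                 faith_pd(comm, tree))
    }
    # linear scaling of branch lengths scales all three metrics
    tree2 <- tree
    tree2$edge.length <- tree$edge.length * 3
    D2 <- cophenetic_distances(tree2)
    expect_equal(mpd(comm, D2), 3 * m1, tolerance = 1e-12)
    expect_equal(mntd(comm, D2), 3 * m2, tolerance = 1e-12)
    expect_equal(faith_pd(comm, tree2), 3 * faith_pd(comm, tree),
                 tolerance = 1e-12)
  }
})

test_that("summarize_over_trees averages per cell across trees", {
  tree <- gen_tree(12, seed = 5)
  g <- grid_spec(0, 0, 1, 1, 0.5)  # 4 cells
  set.seed(5)
  pa <- matrix(rbinom(4 * 12, 1, 0.6), nrow = 4,
               dimnames = list(NULL, tree$tip.label))
  pa[1, ] <- 0            # empty cell stays missing
  cm <- community_matrix(g, pa)

  # single tree: mean = min = max
  s1 <- summarize_over_trees(cm, list(tree), "mpd")
  expect_equal(s1$value, s1$vmin)
  expect_equal(s1$value, s1$vmax)
  expect_true(is.na(s1$value[1]))

  # two trees scaled x1 and x2: mean is 1.5x the x1 value for all metrics
  tree2 <- tree; tree2$edge.length <- 2 * tree$edge.length
  for (metric in c("mpd", "mntd", "pd")) {
    s12 <- summarize_over_trees(cm, list(tree, tree2), metric)
    base <- summarize_over_trees(cm, list(tree), metric)
    expect_equal(s12$value, 1.5 * base$value, tolerance = 1e-12)
  }

  # jittered posterior set: mean within [min, max] everywhere
  trees <- gen_posterior_set(tree, 25, 0.2, seed = 9)
  sj <- summarize_over_trees(cm, trees, "pd")
  ok <- !is.na(sj$value)
  expect_true(all(sj$value[ok] >= sj$vmin[ok] - 1e-12))
  expect_true(all(sj$value[ok] <= sj$vmax[ok] + 1e-12))

  # species missing from a tree is an error naming the labels
  tree3 <- ape::drop.tip(tree, "sp001")
  expect_error(summarize_over_trees(cm, list(tree3), "mpd"), "sp001")
})
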