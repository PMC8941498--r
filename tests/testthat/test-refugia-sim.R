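# Paired birth-death simulation with episodic mass extinctions.

test_that("stable_survival maps unstable survival into [0.9, 1]", {
  expect_equal(stable_survival(0.2), 0.92)
  expect_equal(stable_survival(0.9), 0.99)   # 10% vs 1% per-event extinction
  expect_equal(stable_survival(0.3), 0.93)   # 70% vs 7%
  expect_equal(stable_survival(1), 1)
  expect_equal(stable_survival(0), 0.9)
  expect_error(stable_survival(1.2), "probability")
  expect_error(stable_survival(-0.1), "probability")
})

test_that("epoch schedules are validated", {
  s <- epoch_schedule(c(1.2, 2.4), 0.5)
  expect_equal(s$epochs, 3)
  expect_equal(s$survival, c(0.5, 0.5))
  expect_error(epoch_schedule(c(2, 1), 0.5), "increasing")
  expect_error(epoch_schedule(c(1, 2), 1.5), "probabilities")
})

test_that("reconstructed trees honor the conditioning contract", {
  sched <- epoch_schedule(c(0.5, 1.0), 0.6)
  for (s in 1:10) {
    tr <- simulate_bd_mass_extinction(1.75, 0.1, sched, 20, seed = s)
    expect_equal(length(tr$tip.label), 20)
    expect_true(all(tr$edge.length > 0))
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  }
  # two-taxon boundary: MPD = MNTD
  tr2 <- simulate_bd_mass_extinction(1.75, 0.1, sched, 2, seed = 3)
  expect_equal(length(tr2$tip.label), 2)
  D <- cophenetic_distances(tr2)
  expect_equal(mpd(tr2$tip.label, D), mntd(tr2$tip.label, D))
  # determinism
  a <- simulate_bd_mass_extinction(1.75, 0.1, sched, 15, seed = 11)
  b <- simulate_bd_mass_extinction(1.75, 0.1, sched, 15, seed = 11)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_error(simulate_bd_mass_extinction(0.5, 0.6, sched, 10), "lambda > mu")
  expect_warning(
    try(simulate_bd_mass_extinction(1.75, 0.1, epoch_schedule(0.5, 0),
                                    5, seed = 1, max_restarts = 2),
        silent = TRUE),
    "survival 0")
})

test_that("survival-1 events are no-ops for the MPD distribution", {
  sched1 <- epoch_schedule(c(0.5, 1.0), 1)
  sched0 <- epoch_schedule(numeric(0), numeric(0))
  mpd_of <- function(tr) mpd(tr$tip.label, cophenetic_distances(tr))
  with_events <- vapply(1:60, function(s)
    mpd_of(simulate_bd_mass_extinction(1.75, 0.1, sched1, 20, seed = s)),
    numeric(1))
  without <- vapply(1:60, function(s)
    mpd_of(simulate_bd_mass_extinction(1.75, 0.1, sched0, 20, seed = 1000 + s)),
    numeric(1))
  # same data-generating process: a two-sample test should not separate them
  expect_gt(welch_t(with_events, without)$p, 0.001)
})

test_that("pure-birth attainment times match the Yule waiting-time oracle", {
  # depth from the first split to attainment of n tips is a sum of
  # exponential waiting times with rates k*lambda, k = 2..n-1
  n <- 30; lambda <- 1
  set.seed(123)
  oracle <- replicate(1e5, sum(rexp(n - 2, (2:(n - 1)) * lambda)))
  depth_of <- function(tr) max(ape::node.depth.edgelength(tr))
  # subtract the uniform stop-time extension beyond the last speciation:
  # its expectation is E[U * Exp(n(lambda))] = 1/(2 n lambda)
  depths <- vapply(1:300, function(s) depth_of(gen_tree(n, lambda, 0, seed = s)),
                   numeric(1))
  expected <- mean(oracle) + 1 / (2 * n * lambda)
  se <- sd(oracle) / sqrt(300)  # replicate-count dominates the error
  expect_lt(abs(mean(depths) - expected), 3 * sqrt(var(depths) / 300 + var(oracle) / 1e5))
})

test_that("paired replicates are deterministic and hit the target richness", {
  sc <- sim_scenario(0.3, richness_target = 25, reps = 5, seed = 9)
  r1 <- simulate_pair(sc, 2, keep_trees = TRUE)
  r2 <- simulate_pair(sc, 2, keep_trees = TRUE)
  expect_equal(r1$stable$mpd, r2$stable$mpd)
  expect_equal(r1$unstable$mntd, r2$unstable$mntd)
  expect_equal(length(r1$stable$tree$tip.label), 25)
  expect_equal(length(r1$unstable$tree$tip.label), 25)
  # arms differ (independent substreams)
  expect_false(identical(r1$stable$mpd, r1$unstable$mpd))
})

test_that("a null scenario (equal survival) yields an unremarkable t", {
  sc <- sim_scenario(0.6, x_stable = 0.6, richness_target = 30, reps = 60,
                     seed = 17)
  ex <- run_experiment(sc)
  expect_lt(abs(ex$t_mpd$t), 3.5)
  expect_equal(nrow(ex$replicates), 120)
  expect_equal(sum(ex$histograms$mpd$stable), 60)
  expect_equal(sum(ex$histograms$mpd$unstable), 60)
})

test_that("shipped presets cover the survival ladder consistently", {
  pres <- preset_scenarios()
  expect_length(pres, 10)  # 5 survival pairs x 2 richness levels
  pairs <- unique(t(sapply(pres, function(s) c(s$x_unstable, s$x_stable))))
  expect_true(any(pairs[, 1] == 0.3 & pairs[, 2] == 0.93))
  expect_true(any(pairs[, 1] == 0.2 & pairs[, 2] == 0.92))
  for (s in pres) {
    expect_gte(s$x_stable, s$x_unstable)
    expect_equal(s$reps, 200)
  }
  # Eq.-1-derived presets are exactly consistent with stable_survival
  eq1 <- pres[sapply(pres, function(s) s$x_unstable %in% c(0.9, 0.3) &
                                       s$x_stable > 0.9)]
  for (s in eq1) expect_equal(s$x_stable, stable_survival(s$x_unstable))
})

test_that("experiment outputs serialize to disk", {
  sc <- sim_scenario(0.5, richness_target = 10, reps = 4, seed = 2)
  ex <- run_experiment(sc)
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_true(file.exists(file.path(dir, "replicates.csv")))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$scenario$richness_target, 10)
  expect_equal(summ$t_mpd$t, ex$t_mpd$t, tolerance = 1e-9)
})
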