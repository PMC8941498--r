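#' Survival probability of the stable (refugium) arm
#'
#' Maps the unstable arm's per-event mass-extinction survival
#' probability onto the stable arm's: `x_stable = 0.9 + 0.10 *
#' x_unstable`, so the refugium community always survives each episodic
#' event with probability between 0.9 and 1 while remaining
#' proportional to the unstable arm's survival.
#'
#' @param x_unstable survival probability in `[0, 1]`.
#' @return Stable-arm survival probability in `[0.9, 1]`.
#' @examples
#' stable_survival(0.2)  # 0.92
#' stable_survival(0.9)  # 0.99: 10% vs 1% per-event extinction
#' @export
stable_survival <- function(x_unstable) {
  if (!is_prob(x_unstable)) stop("`x_unstable` must be a probability in [0, 1]")
  0.9 + 0.10 * x_unstable
}

#' Mass-extinction schedule
#'
#' Three diversification epochs separated by two instantaneous mass
#' extinctions at fixed absolute times shared by both arms of a paired
#' simulation; each extant lineage independently survives an event with
#' probability `survival`.
#'
#' @param event_times strictly increasing numeric vector of event times
#'   (length = epochs - 1; default two events, three epochs).
#' @param survival per-event survival probability in `[0, 1]` (scalar,
#'   or one value per event).
#' @return A list of class `epoch_schedule`.
#' @export
epoch_schedule <- function(event_times, survival) {
  stopifnot(is.numeric(event_times))
  if (length(event_times) && any(diff(event_times) <= 0)) {
    stop("`event_times` must be strictly increasing")
  }
  if (length(event_times) && any(event_times <= 0)) {
    stop("`event_times` must be positive")
  }
  survival <- rep_len(survival, length(event_times))
  if (!all(vapply(survival, is_prob, logical(1)))) {
    stop("`survival` values must be probabilities in [0, 1]")
  }
  structure(list(event_times = as.numeric(event_times),
                 survival = as.numeric(survival),
                 epochs = length(event_times) + 1L),
            class = "epoch_schedule")
}

# Default event times: chosen so the expected lineage count entering
# each event under the net rate (lambda - mu) is well below the richness
# target, letting the events act on small radiating communities.
default_event_times <- function(richness_target) {
  if (richness_target >= 50) c(1.2, 2.4) else c(0.5, 1.0)
}

#' Simulate a reconstructed birth-death tree through mass extinctions
#'
#' Forward-time birth-death process from a single lineage: speciation
#' at rate `lambda` and extinction at rate `mu` per lineage throughout
#' all epochs; at each scheduled event time every extant lineage
#' independently survives with the event's survival probability.  The
#' simulation stops at the first moment after the final event at which
#' the extant lineage count equals `richness_target`; extinct lineages
#' are then pruned, yielding the ultrametric reconstructed tree of the
#' extant community.  Attempts that die out (or that can no longer
#' attain the target, e.g. overshoot with `mu = 0`) restart on a fresh
#' random substream, up to `max_restarts`.
#'
#' @param lambda per-lineage speciation rate (> mu).
#' @param mu per-lineage background extinction rate (>= 0), active in
#'   every epoch.
#' @param schedule an [epoch_schedule()]; use
#'   `epoch_schedule(numeric(0), numeric(0))` for a plain birth-death
#'   run without events.
#' @param richness_target number of extant tips to condition on (>= 2).
#' @param seed integer seed (deterministic output for fixed inputs).
#' @param max_restarts maximum rejected attempts before failing.
#' @return A `phylo` object with exactly `richness_target` tips, with
#'   attributes `restarts` (rejected attempts) and `stop_time` (total
#'   simulated time from the origin).
#' @export
simulate_bd_mass_extinction <- function(lambda, mu, schedule,
                                        richness_target, seed = 1,
                                        max_restarts = 1000) {
  stopifnot(is_scalar_num(lambda), is_scalar_num(mu))
  if (mu < 0 || lambda <= mu) stop("require lambda > mu >= 0")
  if (!is_count(richness_target, min = 2)) {
    stop("`richness_target` must be an integer >= 2")
  }
  stopifnot(inherits(schedule, "epoch_schedule"))
  if (length(schedule$survival) && any(schedule$survival == 0)) {
    warning("an event has survival 0: every attempt is guaranteed to fail")
  }
  with_preserved_seed(seed, {
    restarts <- 0L
    repeat {
      res <- bd_attempt(lambda, mu, schedule, richness_target)
      if (!is.null(res)) break
      restarts <- restarts + 1L
      if (restarts > max_restarts) {
        stop(sprintf("replicate failed: %d restarts exhausted (lambda=%g, mu=%g, survival=%s, target=%d)",
                     max_restarts, lambda, mu,
                     paste(schedule$survival, collapse = "/"), richness_target))
      }
    }
    tree <- build_reconstructed_tree(res)
    attr(tree, "restarts") <- restarts
    attr(tree, "stop_time") <- res$stop_time
    tree
  })
}

# One forward simulation attempt; NULL on rejection.
bd_attempt <- function(lambda, mu, schedule, target,
                       max_events = 1e6) {
  ev_times <- schedule$event_times
  ev_surv <- schedule$survival
  n_ev <- length(ev_times)
  cap <- max(64L, 8L * target)
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  dead <- logical(cap)          # went extinct before the stop time
  n_lin <- 1L
  parent[1] <- 0L; t_start[1] <- 0
  alive <- c(1L)
  t <- 0
  next_ev <- 1L
  total_rate <- lambda + mu
  p_spec <- lambda / total_rate
  events <- 0L
  grow <- function() {
    newcap <- cap * 2L
    length(parent) <<- newcap; length(t_start) <<- newcap
    length(t_end) <<- newcap; length(dead) <<- newcap
    dead[(cap + 1L):newcap] <<- FALSE
    cap <<- newcap
  }
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    past_final <- next_ev > n_ev
    if (past_final) {
      if (n_alive == target) {
        # The count first sits at the target over the waiting interval to
        # the next birth/death event; sample the stop time uniformly
        # within it so terminal branch lengths are strictly positive.
        t <- t + stats::runif(1) * stats::rexp(1, n_alive * total_rate)
        break
      }
      # Overshoot past the final event cannot realistically return to the
      # target against the positive net diversification rate; reject.
      if (n_alive > target) return(NULL)
    }
    events <- events + 1L
    if (events > max_events) return(NULL)
    dt <- stats::rexp(1, n_alive * total_rate)
    if (!past_final && t + dt >= ev_times[next_ev]) {
      t <- ev_times[next_ev]
      surv <- stats::runif(n_alive) < ev_surv[next_ev]
      victims <- alive[!surv]
      if (length(victims)) {
        t_end[victims] <- t
        dead[victims] <- TRUE
        alive <- alive[surv]
      }
      next_ev <- next_ev + 1L
      next
    }
    t <- t + dt
    i <- alive[sample.int(n_alive, 1L)]
    if (stats::runif(1) < p_spec) {
      # lineage i ends, two daughters start
      if (n_lin + 2L > cap) grow()
      t_end[i] <- t
      c1 <- n_lin + 1L; c2 <- n_lin + 2L
      parent[c1] <- i; parent[c2] <- i
      t_start[c1] <- t; t_start[c2] <- t
      n_lin <- n_lin + 2L
      alive <- c(alive[alive != i], c1, c2)
    } else {
      t_end[i] <- t
      dead[i] <- TRUE
      alive <- alive[alive != i]
    }
  }
  t_end[alive] <- t
  list(parent = parent[seq_len(n_lin)],
       t_start = t_start[seq_len(n_lin)],
       t_end = t_end[seq_len(n_lin)],
       dead = dead[seq_len(n_lin)],
       extant = alive,
       stop_time = t)
}

# Assemble the complete genealogy as Newick, parse it, and prune
# extinct lineages to obtain the reconstructed extant tree.
build_reconstructed_tree <- function(res) {
  n_lin <- length(res$parent)
  children <- vector("list", n_lin)
  for (i in seq_len(n_lin)) {
    p <- res$parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  lens <- res$t_end - res$t_start
  nw <- function(i) {
    ch <- children[[i]]
    if (is.null(ch)) {
      lab <- if (res$dead[i]) paste0("x", i) else paste0("t", i)
      sprintf("%s:%.12g", lab, lens[i])
    } else {
      sprintf("(%s,%s):%.12g", nw(ch[1]), nw(ch[2]), lens[i])
    }
  }
  full <- ape::read.tree(text = paste0(nw(1L), ";"))
  extinct <- grep("^x", full$tip.label, value = TRUE)
  tree <- if (length(extinct)) ape::drop.tip(full, extinct) else full
  tree
}

#' Simulation scenario for the paired refugium experiment
#'
#' Bundles the parameters of a paired stable/unstable birth-death
#' comparison: both arms share `lambda`, `mu`, the event times and the
#' richness target, and differ only in per-event survival.
#'
#' @param x_unstable per-event survival of the unstable (non-refugium)
#'   arm.
#' @param x_stable per-event survival of the stable (refugium) arm;
#'   defaults to [stable_survival()] of `x_unstable`.
#' @param lambda,mu per-lineage speciation and background extinction
#'   rates (defaults 1.75 and 0.1 per lineage per time unit).
#' @param richness_target extant richness both communities are grown to
#'   (10 or 100 in the shipped presets).
#' @param reps number of paired replicates (default 200).
#' @param event_times times of the two mass extinctions; defaults
#'   depend on the richness target (see [epoch_schedule()]).
#' @param seed root seed; per-replicate, per-arm substreams are derived
#'   deterministically from it.
#' @param max_restarts per-replicate rejection budget.
#' @param name optional scenario label.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(x_unstable, x_stable = stable_survival(x_unstable),
                         lambda = 1.75, mu = 0.1, richness_target = 100,
                         reps = 200, event_times = NULL, seed = 1,
                         max_restarts = 1000, name = NULL) {
  if (!is_prob(x_unstable) || !is_prob(x_stable)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  stopifnot(is_scalar_num(lambda), is_scalar_num(mu))
  if (mu < 0 || lambda <= mu) stop("require lambda > mu >= 0")
  if (!is_count(richness_target, min = 2)) stop("invalid `richness_target`")
  if (!is_count(reps, min = 2)) stop("`reps` must be >= 2")
  if (is.null(event_times)) event_times <- default_event_times(richness_target)
  if (is.null(name)) {
    name <- sprintf("u%.2f-s%.2f-n%d", x_unstable, x_stable, richness_target)
  }
  structure(list(
    name = name,
    lambda = lambda, mu = mu,
    x_unstable = x_unstable, x_stable = x_stable,
    richness_target = as.integer(richness_target),
    reps = as.integer(reps),
    event_times = event_times,
    seed = as.integer(seed),
    max_restarts = max_restarts
  ), class = "sim_scenario")
}

#' Simulate one paired stable/unstable replicate
#'
#' Runs the mass-extinction birth-death simulator twice with identical
#' rates, event times and richness target -- survival `x_stable` for
#' the stable arm, `x_unstable` for the unstable arm -- on independent
#' seeded substreams, and records each reconstructed community's MPD
#' and MNTD over its full tip set.
#'
#' @param scenario a [sim_scenario()].
#' @param rep_index replicate number (determines the substream).
#' @param keep_trees retain the reconstructed trees in the result.
#' @return A list of class `sim_replicate` with per-arm `mpd`, `mntd`,
#'   `restarts` (and `tree` when `keep_trees = TRUE`).
#' @export
simulate_pair <- function(scenario, rep_index, keep_trees = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"), is_count(rep_index))
  run_arm <- function(x, arm_id) {
    sched <- epoch_schedule(scenario$event_times, x)
    tree <- simulate_bd_mass_extinction(
      scenario$lambda, scenario$mu, sched, scenario$richness_target,
      seed = derive_seed(scenario$seed, rep_index, arm_id),
      max_restarts = scenario$max_restarts
    )
    D <- cophenetic_distances(tree)
    tips <- tree$tip.label
    out <- list(mpd = mpd(tips, D), mntd = mntd(tips, D),
                restarts = attr(tree, "restarts"),
                stop_time = attr(tree, "stop_time"))
    if (keep_trees) out$tree <- tree
    out
  }
  structure(list(
    rep = rep_index,
    stable = run_arm(scenario$x_stable, 1L),
    unstable = run_arm(scenario$x_unstable, 2L)
  ), class = "sim_replicate")
}

#' Run a full paired simulation experiment
#'
#' Simulates `reps` paired replicates, then compares the stable and
#' unstable arms' MPD and MNTD distributions with Welch t-tests
#' (oriented stable minus unstable, so a community with lower diversity
#' in the stable arm yields a negative t).  Replicates whose rejection
#' budget is exhausted are recorded as failures; the experiment aborts
#' if more than 10% of replicates fail.
#'
#' @param scenario a [sim_scenario()].
#' @param n_bins bins for the summary histograms.
#' @return A list of class `sim_experiment`: `replicates` (data frame
#'   `rep`, `arm`, `mpd`, `mntd`, `restarts`), `t_mpd`, `t_mntd` (Welch
#'   test results), `histograms`, `n_failed`, and the scenario.
#' @export
run_experiment <- function(scenario, n_bins = 30) {
  stopifnot(inherits(scenario, "sim_scenario"))
  rows <- vector("list", scenario$reps * 2L)
  n_failed <- 0L
  for (r in seq_len(scenario$reps)) {
    rep_r <- tryCatch(simulate_pair(scenario, r), error = function(e) NULL)
    if (is.null(rep_r)) {
      n_failed <- n_failed + 1L
      if (n_failed > 0.1 * scenario$reps) {
        stop(sprintf("experiment aborted: %d of %d replicates failed (scenario %s)",
                     n_failed, scenario$reps, scenario$name))
      }
      next
    }
    rows[[2L * r - 1L]] <- data.frame(
      rep = r, arm = "stable", mpd = rep_r$stable$mpd,
      mntd = rep_r$stable$mntd, restarts = rep_r$stable$restarts)
    rows[[2L * r]] <- data.frame(
      rep = r, arm = "unstable", mpd = rep_r$unstable$mpd,
      mntd = rep_r$unstable$mntd, restarts = rep_r$unstable$restarts)
  }
  replicates <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  st <- replicates[replicates$arm == "stable", ]
  un <- replicates[replicates$arm == "unstable", ]
  hist_table <- function(metric) {
    v <- replicates[[metric]]
    breaks <- seq(min(v), max(v), length.out = n_bins + 1)
    data.frame(
      bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
      stable = graphics::hist(st[[metric]], breaks = breaks, plot = FALSE)$counts,
      unstable = graphics::hist(un[[metric]], breaks = breaks, plot = FALSE)$counts
    )
  }
  structure(list(
    scenario = scenario,
    replicates = replicates,
    t_mpd = welch_t(st$mpd, un$mpd),
    t_mntd = welch_t(st$mntd, un$mntd),
    histograms = list(mpd = hist_table("mpd"), mntd = hist_table("mntd")),
    n_failed = n_failed
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment '%s': %d paired replicates (n = %d tips)\n",
              x$scenario$name, x$scenario$reps, x$scenario$richness_target))
  cat(sprintf("  MPD  stable %.3f vs unstable %.3f: t = %.2f, df = %.1f, p = %.3g\n",
              x$t_mpd$mean_x, x$t_mpd$mean_y, x$t_mpd$t, x$t_mpd$df, x$t_mpd$p))
  cat(sprintf("  MNTD stable %.3f vs unstable %.3f: t = %.2f, df = %.1f, p = %.3g\n",
              x$t_mntd$mean_x, x$t_mntd$mean_y, x$t_mntd$t, x$t_mntd$df, x$t_mntd$p))
  invisible(x)
}

#' Shipped simulation presets
#'
#' The survival-probability ladder of the paired experiment: highly
#' disparate survival (0.2 vs 0.92), similar moderate survival (0.7 vs
#' 0.75), similar low survival (0.3 vs 0.35), and the two
#' extinction-percentage contrasts 10%/1% (0.9 vs 0.99) and 70%/7%
#' (0.3 vs 0.93), the latter pair derived from [stable_survival()].
#' Each preset is provided at richness 10 and 100 with 200 replicates.
#'
#' @param richness_targets richness levels to expand the ladder over.
#' @param reps replicates per scenario.
#' @param seed root seed applied to every scenario.
#' @return A named list of [sim_scenario()] objects.
#' @export
preset_scenarios <- function(richness_targets = c(10, 100), reps = 200,
                             seed = 1) {
  ladder <- list(
    c(0.2, 0.92),
    c(0.7, 0.75),
    c(0.3, 0.35),
    c(0.9, stable_survival(0.9)),   # 10% vs 1% per-event extinction
    c(0.3, stable_survival(0.3))    # 70% vs 7% per-event extinction
  )
  out <- list()
  for (n in richness_targets) {
    for (xs in ladder) {
      sc <- sim_scenario(x_unstable = xs[1], x_stable = xs[2],
                         richness_target = n, reps = reps, seed = seed)
      out[[sc$name]] <- sc
    }
  }
  out
}

#' Write experiment outputs
#'
#' Per-replicate table and histograms as CSV, summary statistics as
#' JSON.
#'
#' @param experiment a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$replicates,
                   file.path(dir, "replicates.csv"), row.names = FALSE)
  utils::write.csv(experiment$histograms$mpd,
                   file.path(dir, "hist_mpd.csv"), row.names = FALSE)
  utils::write.csv(experiment$histograms$mntd,
                   file.path(dir, "hist_mntd.csv"), row.names = FALSE)
  sc <- experiment$scenario
  jsonlite::write_json(list(
    scenario = sc[c("name", "lambda", "mu", "x_unstable", "x_stable",
                    "richness_target", "reps", "event_times", "seed")],
    t_mpd = experiment$t_mpd,
    t_mntd = experiment$t_mntd,
    n_failed = experiment$n_failed
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
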