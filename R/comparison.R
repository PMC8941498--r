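#' Association between two metric surfaces
#'
#' OLS fit of `b ~ a` and Pearson correlation over the jointly
#' non-missing cells.
#'
#' @param a,b [metric_surface()] objects on the same grid.
#' @return A list with `slope`, `intercept`, `adj_r_squared`,
#'   `correlation`, `n`.
#' @export
surface_association <- function(a, b) {
  stopifnot(inherits(a, "metric_surface"), inherits(b, "metric_surface"))
  if (nrow(a) != nrow(b) || any(a$cell != b$cell)) {
    stop("surfaces are not on the same grid")
  }
  ok <- !is.na(a$value) & !is.na(b$value)
  if (sum(ok) < 3L) stop("need at least 3 jointly non-missing cells")
  av <- a$value[ok]; bv <- b$value[ok]
  if (stats::var(av) == 0 || stats::var(bv) == 0) {
    stop("degenerate variance in one of the surfaces")
  }
  fit <- stats::lm(bv ~ av)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r_squared = sm$adj.r.squared,
       correlation = stats::cor(av, bv),
       n = sum(ok))
}

# Turn two surfaces into aligned probability vectors: each is first
# rescaled to [0, 1] over the jointly non-missing cells and then to sum
# 1, mirroring how raster overlap statistics scale their inputs.
surfaces_to_proportions <- function(a, b) {
  stopifnot(inherits(a, "metric_surface"), inherits(b, "metric_surface"))
  if (nrow(a) != nrow(b) || any(a$cell != b$cell)) {
    stop("surfaces are not on the same grid")
  }
  ok <- !is.na(a$value) & !is.na(b$value)
  if (sum(ok) < 2L) stop("need at least 2 jointly non-missing cells")
  rescale01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) v - rng[1] else (v - rng[1]) / diff(rng)
  }
  pa <- rescale01(a$value[ok]); pb <- rescale01(b$value[ok])
  if (sum(pa) == 0 || sum(pb) == 0) {
    stop("surface is constant/all-zero after rescaling; overlap undefined")
  }
  list(pa = pa / sum(pa), pb = pb / sum(pb), ok = ok)
}

# Overlap statistics on probability vectors (already summing to 1).
schoener_d_p <- function(pa, pb) 1 - 0.5 * sum(abs(pa - pb))
hellinger_i_p <- function(pa, pb) 1 - 0.5 * sum((sqrt(pa) - sqrt(pb))^2)

#' Schoener's D overlap between two surfaces
#'
#' D = 1 - 1/2 * sum_i |p_a,i - p_b,i|, where each surface is rescaled
#' to `[0, 1]` and then to proportions (sum 1) over the jointly
#' non-missing cells.  D is symmetric and lies in `[0, 1]`, equalling 1
#' iff the two proportion surfaces are identical and 0 iff their
#' supports are disjoint.
#'
#' @param a,b [metric_surface()] objects on the same grid.
#' @return Overlap value in `[0, 1]`.
#' @export
schoener_d <- function(a, b) {
  p <- surfaces_to_proportions(a, b)
  schoener_d_p(p$pa, p$pb)
}

#' Hellinger-based I overlap between two surfaces
#'
#' I = 1 - 1/2 * sum_i (sqrt(p_a,i) - sqrt(p_b,i))^2, i.e. one minus
#' half the squared Hellinger distance between the proportion surfaces;
#' scaling as in [schoener_d()].
#'
#' @inheritParams schoener_d
#' @return Overlap value in `[0, 1]`.
#' @export
hellinger_i <- function(a, b) {
  p <- surfaces_to_proportions(a, b)
  hellinger_i_p(p$pa, p$pb)
}

#' Permutation null for the overlap statistics
#'
#' Holds surface `a` fixed and permutes the cell values of surface `b`
#' across its non-missing cells `n_null` times, recomputing D and I for
#' each permutation; spatial co-structure is destroyed while each
#' surface's value distribution is preserved.  The observed statistics
#' are compared with the null distributions by one-sample two-sided
#' t-tests (null values against the observed value).
#'
#' @inheritParams schoener_d
#' @param n_null number of permutations (default 99).
#' @param seed integer seed; the null lists are reproducible given the
#'   seed.
#' @return An object of class `overlap_result`: observed `D` and `I`,
#'   vectors `null_D`, `null_I`, per-statistic `t`, `df`, `p` (a
#'   degenerate zero-variance null reports `p = NA` with
#'   `degenerate = TRUE`), and empirical ranks.
#' @export
overlap_null <- function(a, b, n_null = 99, seed = 1) {
  if (!is_count(n_null, min = 2)) stop("`n_null` must be a count >= 2")
  p <- surfaces_to_proportions(a, b)
  obs_d <- schoener_d_p(p$pa, p$pb)
  obs_i <- hellinger_i_p(p$pa, p$pb)
  bvals <- b$value[p$ok]
  null_d <- numeric(n_null)
  null_i <- numeric(n_null)
  with_preserved_seed(seed, {
    for (k in seq_len(n_null)) {
      bp <- b
      bp$value[p$ok] <- sample(bvals)
      pk <- surfaces_to_proportions(a, bp)
      null_d[k] <- schoener_d_p(pk$pa, pk$pb)
      null_i[k] <- hellinger_i_p(pk$pa, pk$pb)
    }
  })
  one_sample <- function(null, obs) {
    if (stats::sd(null) == 0) {
      return(list(t = if (all(null == obs)) 0 else NA_real_,
                  df = n_null - 1L, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(null, mu = obs)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
  }
  structure(list(
    D = obs_d, I = obs_i,
    null_D = null_d, null_I = null_i,
    test_D = one_sample(null_d, obs_d),
    test_I = one_sample(null_i, obs_i),
    rank_D = sum(null_d >= obs_d),  # permutations at least as extreme
    rank_I = sum(null_i >= obs_i),
    n_null = n_null, seed = seed
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: D = %.4f (%d/%d null >= obs), I = %.4f (%d/%d null >= obs)\n",
              x$D, x$rank_D, x$n_null, x$I, x$rank_I, x$n_null))
  invisible(x)
}

#' Chi-square comparison of two groups' dispersion categories
#'
#' Pearson chi-square (no continuity correction) on the 3x3 contingency
#' table of per-cell joint categories (group A category x group B
#' category) over jointly classified cells.  Empty rows/columns are
#' dropped with a warning; the full table has df = 4.
#'
#' @param class_a,class_b [classify_cells()] results on the same grid.
#' @return A list of class `crosstab`: `table` (3x3 counts),
#'   `statistic`, `df`, `p`.
#' @export
category_chisq <- function(class_a, class_b) {
  stopifnot(inherits(class_a, "dispersion_classification"),
            inherits(class_b, "dispersion_classification"))
  if (nrow(class_a) != nrow(class_b) || any(class_a$cell != class_b$cell)) {
    stop("classifications are not on the same grid")
  }
  ok <- !is.na(class_a$category) & !is.na(class_b$category)
  if (!any(ok)) stop("no jointly classified cells")
  tab <- table(factor(class_a$category[ok], levels = 0:2),
               factor(class_b$category[ok], levels = 0:2),
               dnn = c("A", "B"))
  full <- tab
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping empty category rows/columns from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("contingency table degenerate after dropping empty margins")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = full,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value),
            class = "crosstab")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom
#' (the default behaviour of `t.test`); reported as `x` minus `y`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return A list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both samples have zero variance; t undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}
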