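#' Regress phylogenetic diversity on species richness
#'
#' Ordinary least-squares fit PD = b0 + b1 * richness over all cells
#' where both surfaces are non-missing.  The fit anchors the dispersion
#' classification: cells far below the band are underdispersed (less
#' phylogenetic diversity than their richness predicts), cells far above
#' are overdispersed.
#'
#' @param pd_surface a [metric_surface()] of (across-tree mean) PD.
#' @param richness_surface a richness [metric_surface()].
#' @param level confidence level for the classification band
#'   (default 0.95).
#' @return An object of class `dispersion_fit` with fields `slope`,
#'   `intercept`, `sigma` (residual standard error), `adj_r_squared`,
#'   `n`, `level` and the underlying `lm` fit in `model`.
#' @export
fit_pd_richness <- function(pd_surface, richness_surface, level = 0.95) {
  stopifnot(inherits(pd_surface, "metric_surface"),
            inherits(richness_surface, "metric_surface"))
  if (nrow(pd_surface) != nrow(richness_surface) ||
      any(pd_surface$cell != richness_surface$cell)) {
    stop("surfaces are not on the same grid")
  }
  stopifnot(is_prob(level), level > 0, level < 1)
  dat <- data.frame(cell = pd_surface$cell,
                    pd = pd_surface$value,
                    richness = richness_surface$value)
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 3L) stop("need at least 3 cells with both PD and richness")
  if (stats::var(dat$richness) == 0) {
    stop("richness has zero variance; the regression is degenerate")
  }
  fit <- stats::lm(pd ~ richness, data = dat)
  sm <- summary(fit)
  structure(list(
    model = fit,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sigma = sm$sigma,
    adj_r_squared = sm$adj.r.squared,
    n = nrow(dat),
    level = level
  ), class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("dispersion_fit: PD = %.4g + %.4g * richness (n = %d, adj R^2 = %.3f, sigma = %.4g)\n",
              x$intercept, x$slope, x$n, x$adj_r_squared, x$sigma))
  invisible(x)
}

#' Classify cells as under-, neutrally or overdispersed
#'
#' Each cell with both PD and richness is compared with a `level`
#' (default 95%) band around the fitted PD~richness line at the cell's
#' richness: category 0 (underdispersed) below the lower limit, 2
#' (overdispersed) above the upper limit, 1 otherwise.  Cells missing
#' either metric are unclassified (`NA` category).
#'
#' The default band is the prediction interval for a new observation;
#' with very many cells the mean-response confidence band shrinks
#' towards the line and would label nearly every cell non-neutral.  Both
#' are available via `band`.
#'
#' @param fit a [fit_pd_richness()] result.
#' @param pd_surface,richness_surface the surfaces to classify (usually
#'   those used to fit).
#' @param band `"prediction"` (default) or `"confidence"` (mean
#'   response).
#' @return A data frame of class `dispersion_classification` with
#'   columns `cell`, `x`, `y`, `category` (0/1/2 or `NA`).
#' @export
classify_cells <- function(fit, pd_surface, richness_surface,
                           band = c("prediction", "confidence")) {
  band <- match.arg(band)
  stopifnot(inherits(fit, "dispersion_fit"),
            inherits(pd_surface, "metric_surface"),
            inherits(richness_surface, "metric_surface"))
  if (nrow(pd_surface) != nrow(richness_surface) ||
      any(pd_surface$cell != richness_surface$cell)) {
    stop("surfaces are not on the same grid")
  }
  category <- rep(NA_integer_, nrow(pd_surface))
  ok <- !is.na(pd_surface$value) & !is.na(richness_surface$value)
  if (any(ok)) {
    pr <- stats::predict(fit$model,
                         newdata = data.frame(richness = richness_surface$value[ok]),
                         interval = band, level = fit$level)
    pd <- pd_surface$value[ok]
    cat_ok <- ifelse(pd < pr[, "lwr"], 0L, ifelse(pd > pr[, "upr"], 2L, 1L))
    category[ok] <- cat_ok
  }
  out <- cbind(grid_centers(attr(pd_surface, "grid")), category = category)
  structure(out,
            class = c("dispersion_classification", "data.frame"),
            grid = attr(pd_surface, "grid"),
            band = band, level = fit$level,
            group = attr(pd_surface, "group"))
}

#' Average dispersion categories by ecoregion
#'
#' For each ecoregion: the mean 0/1/2 category over its classified
#' cells, the classified-cell count, and the rescaled score
#' `mean - 1` in `[-1, 1]` (-1 most underdispersed, +1 most
#' overdispersed).  Ecoregions with no classified cells get a missing
#' score.
#'
#' @param classification a [classify_cells()] result.
#' @param ecoregions an [ecoregion_map()] on the same grid.
#' @return A data frame with columns `ecoregion`, `n_cells`,
#'   `mean_category`, `rescaled_score`.
#' @export
ecoregion_scores <- function(classification, ecoregions) {
  stopifnot(inherits(classification, "dispersion_classification"),
            inherits(ecoregions, "ecoregion_map"))
  if (nrow(classification) != nrow(ecoregions) ||
      any(classification$cell != ecoregions$cell)) {
    stop("classification and ecoregions are not on the same grid")
  }
  eco_ids <- sort(unique(ecoregions$ecoregion))
  out <- data.frame(ecoregion = eco_ids,
                    n_cells = 0L,
                    mean_category = NA_real_,
                    rescaled_score = NA_real_)
  for (i in seq_along(eco_ids)) {
    cat_i <- classification$category[ecoregions$ecoregion == eco_ids[i]]
    cat_i <- cat_i[!is.na(cat_i)]
    out$n_cells[i] <- length(cat_i)
    if (length(cat_i)) {
      out$mean_category[i] <- mean(cat_i)
      out$rescaled_score[i] <- mean(cat_i) - 1
    }
  }
  out
}

#' Combine the dispersion classifications of two taxon groups
#'
#' Per cell, the combined value is the mean of the two groups' 0/1/2
#' categories (range \code{[0, 2]}; 0 = most underdispersed in both
#' groups); cells unclassified in either group are excluded.  When an
#' ecoregion map is supplied, per-ecoregion combined scores are the mean
#' of the two groups' rescaled scores.
#'
#' @param class_a,class_b [classify_cells()] results on the same grid.
#' @param ecoregions optional [ecoregion_map()] for ecoregion-level
#'   combination.
#' @return A list of class `combined_dispersion` with `cells` (data
#'   frame `cell`, `x`, `y`, `combined`) and, if requested, `ecoregions`
#'   (data frame `ecoregion`, `combined_rescaled`).
#' @export
combine_groups <- function(class_a, class_b, ecoregions = NULL) {
  stopifnot(inherits(class_a, "dispersion_classification"),
            inherits(class_b, "dispersion_classification"))
  ga <- attr(class_a, "grid"); gb <- attr(class_b, "grid")
  if (!identical(unclass(ga), unclass(gb))) stop("grids differ between groups")
  combined <- (class_a$category + class_b$category) / 2
  cells <- cbind(grid_centers(ga), combined = combined)
  eco <- NULL
  if (!is.null(ecoregions)) {
    sa <- ecoregion_scores(class_a, ecoregions)
    sb <- ecoregion_scores(class_b, ecoregions)
    eco <- data.frame(ecoregion = sa$ecoregion,
                      combined_rescaled = (sa$rescaled_score + sb$rescaled_score) / 2)
  }
  structure(list(cells = cells, ecoregions = eco),
            class = "combined_dispersion")
}
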