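#' Construct a presence-absence community matrix
#'
#' @param grid a [grid_spec()].
#' @param pa binary matrix, cells x species, with species column names;
#'   row count must equal the grid's cell count.
#' @param group optional taxon-group name carried through to surfaces.
#' @return An object of class `community_matrix`.
#' @export
community_matrix <- function(grid, pa, group = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(pa))
  if (nrow(pa) != grid$n_cells) {
    stop(sprintf("matrix has %d rows but the grid has %d cells",
                 nrow(pa), grid$n_cells))
  }
  if (is.null(colnames(pa)) || anyDuplicated(colnames(pa))) {
    stop("species column names must be present and unique")
  }
  if (!all(pa %in% c(0, 1))) stop("matrix entries must be 0 or 1")
  storage.mode(pa) <- "double"
  structure(list(grid = grid, pa = pa, species = colnames(pa), group = group),
            class = "community_matrix")
}

#' Rasterize species ranges onto a grid
#'
#' A species is recorded present in a cell iff the cell's center point
#' lies inside or on the boundary of the species' range polygon
#' (point-sampling semantics; partial overlap of the cell square does
#' not count).
#'
#' @param ranges a named list of polygons (`range_set`); names are
#'   species ids.
#' @param grid a [grid_spec()].
#' @param group optional group name stored on the result.
#' @return A [community_matrix()] with one column per species.
#' @export
rasterize_presence <- function(ranges, grid, group = "") {
  stopifnot(inherits(grid, "grid_spec"), length(ranges) >= 1)
  if (is.null(names(ranges)) || anyDuplicated(names(ranges))) {
    stop("ranges must be a named list with unique species ids")
  }
  ctr <- grid_centers(grid)
  pa <- matrix(0, nrow = grid$n_cells, ncol = length(ranges),
               dimnames = list(NULL, names(ranges)))
  for (s in seq_along(ranges)) {
    poly <- ranges[[s]]
    if (polygon_area(poly) <= 1e-12) {
      warning(sprintf("range polygon for '%s' has zero area; species absent everywhere",
                      names(ranges)[s]))
      next
    }
    pa[, s] <- as.numeric(point_in_polygon(ctr$x, ctr$y, poly))
  }
  community_matrix(grid, pa, group = group)
}

#' Species richness surface
#'
#' Alpha diversity: the number of species present at each sampling
#' point (per-cell row sum of the presence-absence matrix).
#'
#' @param matrix a [community_matrix()].
#' @return A [metric_surface()] with metric `"richness"`.
#' @export
richness <- function(matrix) {
  stopifnot(inherits(matrix, "community_matrix"))
  metric_surface(matrix$grid, value = rowSums(matrix$pa),
                 metric = "richness", group = matrix$group)
}

#' Construct a per-cell metric surface
#'
#' @param grid a [grid_spec()].
#' @param value per-cell values in row-major cell order (`NA` = missing).
#' @param vmin,vmax optional per-cell across-tree range.
#' @param metric,group,n_trees metadata carried in attributes.
#' @return A data frame of class `metric_surface` with columns `cell`,
#'   `x`, `y`, `value` and optionally `vmin`, `vmax`.
#' @export
metric_surface <- function(grid, value, vmin = NULL, vmax = NULL,
                           metric = "", group = "", n_trees = NA_integer_) {
  stopifnot(inherits(grid, "grid_spec"), length(value) == grid$n_cells)
  if (any(is.infinite(value), na.rm = TRUE)) {
    stop("surface values must be finite or missing")
  }
  out <- cbind(grid_centers(grid), value = as.numeric(value))
  if (!is.null(vmin)) out$vmin <- as.numeric(vmin)
  if (!is.null(vmax)) out$vmax <- as.numeric(vmax)
  structure(out,
            class = c("metric_surface", "data.frame"),
            grid = grid, metric = metric, group = group,
            n_trees = n_trees)
}

#' Rescale a surface to the unit interval
#'
#' v' = (v - min) / (max - min) over non-missing cells.  A constant
#' surface maps to all zeros with a warning; missing cells stay missing.
#'
#' @param surface a [metric_surface()].
#' @return The rescaled surface (metric name suffixed `_norm`).
#' @export
normalize_surface <- function(surface) {
  stopifnot(inherits(surface, "metric_surface"))
  v <- surface$value
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot normalize an all-missing surface")
  rng <- range(v[ok])
  if (diff(rng) == 0) {
    warning("constant surface: normalized to all zeros")
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - rng[1]) / (rng[2] - rng[1])
  }
  metric_surface(attr(surface, "grid"), v,
                 metric = paste0(sub("_norm$", "", attr(surface, "metric")), "_norm"),
                 group = attr(surface, "group"),
                 n_trees = attr(surface, "n_trees"))
}

#' Write a metric surface as CSV
#'
#' Columns `cell`, `x`, `y`, `value` (and `vmin`, `vmax` when present);
#' missing values are written as empty fields, never sentinel numbers.
#'
#' @param surface a [metric_surface()].
#' @param path output file.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "metric_surface"))
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a community matrix as CSV
#'
#' Rows are cells (with explicit `cell`, `x`, `y` columns), columns are
#' species.
#'
#' @param matrix a [community_matrix()].
#' @param path output file.
#' @export
write_community_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "community_matrix"))
  df <- cbind(grid_centers(matrix$grid), as.data.frame(matrix$pa))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
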