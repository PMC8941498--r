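#' Construct a simple planar polygon
#'
#' Polygons are closed rings of vertices in grid coordinates; the first
#' vertex is not repeated.  Used for species ranges and for the refugium
#' region of synthetic worlds.
#'
#' @param x,y numeric vertex coordinates (length >= 3).
#' @param check_simple verify the ring is non-self-intersecting
#'   (O(n^2) segment test; default TRUE).
#' @return A list with fields `x`, `y` of class `refugia_polygon`.
#' @export
make_polygon <- function(x, y, check_simple = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("a polygon needs at least 3 vertices")
  if (anyNA(x) || anyNA(y)) stop("polygon vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
    if (length(x) < 3L) stop("a polygon needs at least 3 distinct vertices")
  }
  poly <- structure(list(x = x, y = y), class = "refugia_polygon")
  if (polygon_area(poly) <= 0) stop("polygon has zero area")
  if (check_simple && !polygon_is_simple(poly)) {
    stop("polygon is self-intersecting; only simple polygons are supported")
  }
  poly
}

#' Polygon area by the shoelace formula
#'
#' @param poly a polygon from [make_polygon()] or [ellipse_polygon()].
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  j <- c(seq_along(x)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Segment-intersection check for ring simplicity; adjacent segments
# (sharing an endpoint) are skipped.
polygon_is_simple <- function(poly) {
  x <- poly$x; y <- poly$y; n <- length(x)
  j <- c(seq_len(n)[-1], 1L)
  seg <- cbind(x, y, x[j], y[j])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (a in seq_len(n - 2L)) {
    for (b in seq((a + 2L), n)) {
      if (a == 1L && b == n) next  # adjacent around the ring
      o1 <- orient(seg[a, 1], seg[a, 2], seg[a, 3], seg[a, 4], seg[b, 1], seg[b, 2])
      o2 <- orient(seg[a, 1], seg[a, 2], seg[a, 3], seg[a, 4], seg[b, 3], seg[b, 4])
      o3 <- orient(seg[b, 1], seg[b, 2], seg[b, 3], seg[b, 4], seg[a, 1], seg[a, 2])
      o4 <- orient(seg[b, 1], seg[b, 2], seg[b, 3], seg[b, 4], seg[a, 3], seg[a, 4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Even-odd (ray casting) containment, vectorized over query points.
#' Points lying on an edge or vertex are counted inside, matching the
#' package's closed-boundary sampling convention.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly a polygon.
#' @param eps absolute tolerance for the on-boundary test, scaled to the
#'   polygon's bounding box.
#' @return Logical vector, TRUE where the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  stopifnot(length(px) == length(py))
  x <- poly$x; y <- poly$y; n <- length(x)
  scale <- max(diff(range(x)), diff(range(y)), 1)
  tol <- eps * scale
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  jprev <- n
  for (k in seq_len(n)) {
    x1 <- x[jprev]; y1 <- y[jprev]; x2 <- x[k]; y2 <- y[k]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    within <- px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    on_edge <- on_edge | (abs(cross) <= tol * max(seg_len, 1) & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    jprev <- k
  }
  inside | on_edge
}

#' Polygon approximation of an ellipse
#'
#' @param cx,cy center; `a`, `b` semi-axis lengths; `angle` rotation in
#'   radians; `n_vertices` ring resolution.
#' @return A `refugia_polygon`.
#' @export
ellipse_polygon <- function(cx, cy, a, b, angle = 0, n_vertices = 40) {
  stopifnot(a > 0, b > 0, is_count(n_vertices, min = 8))
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ex <- a * cos(th); ey <- b * sin(th)
  poly <- structure(list(
    x = cx + ex * cos(angle) - ey * sin(angle),
    y = cy + ex * sin(angle) + ey * cos(angle)
  ), class = "refugia_polygon")
  attr(poly, "ellipse") <- c(cx = cx, cy = cy, a = a, b = b, angle = angle)
  poly
}

# Analytic containment for ellipse-backed polygons (used by tests as an
# oracle and by generators for speed when available).
in_ellipse <- function(px, py, ellipse) {
  e <- ellipse
  dx <- px - e[["cx"]]; dy <- py - e[["cy"]]
  u <- dx * cos(e[["angle"]]) + dy * sin(e[["angle"]])
  v <- -dx * sin(e[["angle"]]) + dy * cos(e[["angle"]])
  (u / e[["a"]])^2 + (v / e[["b"]])^2 <= 1
}

#' Write a set of species range polygons as GeoJSON
#'
#' Ranges are serialized as a `FeatureCollection` of `Polygon` features
#' carrying a `species_id` property, in planar grid coordinates.
#'
#' @param ranges a named list of polygons (a `range_set`).
#' @param path output file.
#' @export
write_ranges_geojson <- function(ranges, path) {
  feats <- lapply(names(ranges), function(sp) {
    poly <- ranges[[sp]]
    ring <- cbind(c(poly$x, poly$x[1]), c(poly$y, poly$y[1]))
    list(
      type = "Feature",
      properties = list(species_id = sp),
      geometry = list(type = "Polygon",
                      coordinates = list(ring))
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read species range polygons from GeoJSON
#'
#' @param path a GeoJSON `FeatureCollection` written by
#'   [write_ranges_geojson()] (or any collection of `Polygon` features
#'   with a `species_id` property).
#' @return A named list of polygons of class `range_set`.
#' @export
read_ranges_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  out <- list()
  for (f in obj$features) {
    sp <- f$properties$species_id
    if (is.null(sp)) stop("feature without a species_id property")
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    out[[sp]] <- make_polygon(xs, ys, check_simple = FALSE)
  }
  structure(out, class = "range_set")
}
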