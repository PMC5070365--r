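# Thiessen (Voronoi) tessellation of a rectangular extent.
#
# Each seed's polygon is the bounding rectangle clipped against the
# perpendicular-bisector half-plane of every other seed
# (Sutherland-Hodgman).  Seeds are visited in order of distance with an
# early exit: once half the distance to the next seed exceeds the
# circumradius of the current polygon no further seed can cut it, which
# keeps the construction near-linear in practice.

#' Thiessen (Voronoi) polygons of district centroids
#'
#' Partitions the extent so that every location inside a polygon is closer
#' to its seed than to any other seed; used to paint district-level
#' accessibility results as a gap-free map layer.
#'
#' @param points Data frame `id`, `x`, `y` of distinct seed points.
#' @param extent Bounding rectangle `c(xmin, ymin, xmax, ymax)` containing
#'   all seeds.
#' @return Object of class `thiessen_tessellation`: named list `polygons`
#'   (one x/y data frame per seed, unclosed ring, counter-clockwise) and
#'   the `seeds` table.
#' @export
#' @examples
#' th <- thiessen_polygons(
#'   data.frame(id = c("a", "b"), x = c(1, 3), y = c(1, 1)),
#'   extent = c(0, 0, 4, 2))
#' polygon_area(th$polygons[["a"]])  # bisector splits the box: 4
thiessen_polygons <- function(points, extent) {
  stopifnot(nrow(points) >= 1, length(extent) == 4)
  if (anyDuplicated(points[, c("x", "y")])) {
    stop("duplicate centroids", call. = FALSE)
  }
  if (any(points$x < extent[1] | points$x > extent[3] |
            points$y < extent[2] | points$y > extent[4])) {
    stop("extent must contain all seeds", call. = FALSE)
  }
  rect <- data.frame(
    x = c(extent[1], extent[3], extent[3], extent[1]),
    y = c(extent[2], extent[2], extent[4], extent[4]))

  n <- nrow(points)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    sx <- points$x[i]; sy <- points$y[i]
    d2 <- (points$x - sx)^2 + (points$y - sy)^2
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- rect
    for (j in ord) {
      dj <- sqrt(d2[j])
      r2max <- max((poly$x - sx)^2 + (poly$y - sy)^2)
      if ((dj / 2)^2 > r2max) break  # bisector cannot reach the polygon
      poly <- .clip_halfplane(poly, sx, sy, points$x[j], points$y[j])
      if (nrow(poly) < 3L) break
    }
    polys[[i]] <- poly
  }
  names(polys) <- points$id
  structure(list(polygons = polys, seeds = points, extent = extent),
            class = "thiessen_tessellation")
}

# keep the side of the perpendicular bisector containing (sx, sy)
.clip_halfplane <- function(poly, sx, sy, ox, oy) {
  mx <- (sx + ox) / 2
  my <- (sy + oy) / 2
  nx <- ox - sx
  ny <- oy - sy
  val <- (poly$x - mx) * nx + (poly$y - my) * ny  # <= 0 is the seed side
  n <- nrow(poly)
  out_x <- numeric(0)
  out_y <- numeric(0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    in1 <- val[k] <= 0
    in2 <- val[k2] <= 0
    if (in1) {
      out_x <- c(out_x, poly$x[k])
      out_y <- c(out_y, poly$y[k])
    }
    if (xor(in1, in2)) {
      t <- val[k] / (val[k] - val[k2])
      out_x <- c(out_x, poly$x[k] + t * (poly$x[k2] - poly$x[k]))
      out_y <- c(out_y, poly$y[k] + t * (poly$y[k2] - poly$y[k]))
    }
  }
  data.frame(x = out_x, y = out_y)
}

#' Polygon area (shoelace formula)
#'
#' @param poly Data frame or matrix with x/y columns (unclosed ring).
#' @return Absolute area.
#' @export
polygon_area <- function(poly) {
  x <- poly[[1]]
  y <- poly[[2]]
  n <- length(x)
  if (n < 3L) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Test points for polygon containment (ray casting)
#'
#' @param px,py Point coordinates (vectors).
#' @param poly Data frame with x/y columns (unclosed ring).
#' @return Logical vector; boundary points may fall either way.
#' @export
points_in_polygon <- function(px, py, poly) {
  x <- poly[[1]]
  y <- poly[[2]]
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (y[i] > py) != (y[j] > py)
    xi <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
    hit <- cross & (px < xi)
    inside[hit] <- !inside[hit]
    j <- i
  }
  inside
}
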