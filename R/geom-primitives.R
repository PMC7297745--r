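# Planar geometry primitives: point-in-polygon, segment intersection and
# minimum distances between points and simple polygon rings. Rings are
# n x 2 numeric matrices of vertices in order, not closed (the first vertex
# is not repeated at the end); closure is implied.

# squared distance from point (px, py) to segment (ax, ay)-(bx, by); vectorised
# over segments
point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  list(ax = ring[, 1], ay = ring[, 2], bx = ring[j, 1], by = ring[j, 2])
}

# minimum distance from a point to the boundary of a ring
point_ring_boundary_dist <- function(px, py, ring) {
  e <- ring_edges(ring)
  sqrt(min(point_seg_dist2(px, py, e$ax, e$ay, e$bx, e$by)))
}

#' Point-in-polygon test
#'
#' Ray-casting test for a point against a simple polygon ring. Points lying
#' exactly on the boundary count as inside, matching the inclusive contact
#' and confinement conventions used throughout the package.
#'
#' @param px,py point coordinates (metres).
#' @param ring n x 2 matrix of polygon vertices in order (not closed).
#' @return `TRUE` if the point is inside or on the boundary.
#' @export
point_in_polygon <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  # boundary check first (ray casting is unreliable exactly on edges)
  e <- ring_edges(ring)
  if (min(point_seg_dist2(px, py, e$ax, e$ay, e$bx, e$by)) <= 1e-24) {
    return(TRUE)
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

orient2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

on_segment_collinear <- function(ax, ay, bx, by, px, py) {
  min(ax, bx) - 1e-12 <= px && px <= max(ax, bx) + 1e-12 &&
    min(ay, by) - 1e-12 <= py && py <= max(ay, by) + 1e-12
}

# do segments a1-a2 and b1-b2 intersect (touching counts)?
segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- orient2(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- orient2(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- orient2(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- orient2(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  (d1 == 0 && on_segment_collinear(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])) ||
    (d2 == 0 && on_segment_collinear(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])) ||
    (d3 == 0 && on_segment_collinear(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])) ||
    (d4 == 0 && on_segment_collinear(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2]))
}

rings_intersect <- function(a, b) {
  ea <- ring_edges(a)
  eb <- ring_edges(b)
  for (i in seq_along(ea$ax)) {
    for (j in seq_along(eb$ax)) {
      if (segments_intersect(c(ea$ax[i], ea$ay[i]), c(ea$bx[i], ea$by[i]),
                             c(eb$ax[j], eb$ay[j]), c(eb$bx[j], eb$by[j]))) {
        return(TRUE)
      }
    }
  }
  # no edge crossing: containment is the only remaining overlap
  point_in_polygon(a[1, 1], a[1, 2], b) || point_in_polygon(b[1, 1], b[1, 2], a)
}

# minimum distance between two disjoint ring boundaries. For simple polygons
# whose boundaries do not cross, the minimum is attained at a vertex of one
# ring against an edge of the other, so a vertex-to-edge sweep both ways is
# exact.
ring_ring_dist <- function(a, b) {
  ea <- ring_edges(a)
  eb <- ring_edges(b)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    best <- min(best, min(point_seg_dist2(a[i, 1], a[i, 2],
                                          eb$ax, eb$ay, eb$bx, eb$by)))
  }
  for (j in seq_len(nrow(b))) {
    best <- min(best, min(point_seg_dist2(b[j, 1], b[j, 2],
                                          ea$ax, ea$ay, ea$bx, ea$by)))
  }
  sqrt(best)
}

validate_ring <- function(ring, what = "ring") {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2 || anyNA(ring)) {
    stop_config("%s must be a numeric n x 2 matrix without NAs", what)
  }
  # drop an explicitly closed last vertex
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop_config("%s must have at least 3 vertices", what)
  ring
}

# simplicity check: no two non-adjacent edges may intersect
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  for (e1 in seq_len(n - 1)) {
    for (e2 in (e1 + 1):n) {
      adjacent <- (j[e1] == e2) || (j[e2] == e1)
      if (adjacent) next
      if (segments_intersect(ring[e1, ], ring[j[e1], ],
                             ring[e2, ], ring[j[e2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

ring_area <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  abs(sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2])) / 2
}

ring_edge_lengths <- function(ring) {
  e <- ring_edges(ring)
  sqrt((e$bx - e$ax)^2 + (e$by - e$ay)^2)
}

#' Minimum distance between two planar geometries
#'
#' Computes the minimum Euclidean distance between two geometries, each a
#' point (numeric length-2 vector) or a simple polygon ring (n x 2 matrix).
#' The distance is 0 when the geometries intersect or one contains the
#' other, which is the polygon-intersection contact definition at a spatial
#' threshold of zero.
#'
#' @param g1,g2 point (length-2 numeric) or polygon ring (n x 2 matrix).
#' @return minimum distance in the input units (metres).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' geometry_distance(c(0.5, 0.5), sq)       # containment: 0
#' geometry_distance(sq, sq + cbind(2, 0))  # gap of 1 m
#' @export
geometry_distance <- function(g1, g2) {
  p1 <- is.numeric(g1) && is.null(dim(g1)) && length(g1) == 2
  p2 <- is.numeric(g2) && is.null(dim(g2)) && length(g2) == 2
  if (p1 && p2) {
    return(euclid(g1[1], g1[2], g2[1], g2[2]))
  }
  if (p1 || p2) {
    pt <- if (p1) g1 else g2
    ring <- validate_ring(if (p1) g2 else g1, "polygon")
    if (point_in_polygon(pt[1], pt[2], ring)) return(0)
    return(point_ring_boundary_dist(pt[1], pt[2], ring))
  }
  a <- validate_ring(g1, "polygon 1")
  b <- validate_ring(g2, "polygon 2")
  if (rings_intersect(a, b)) return(0)
  ring_ring_dist(a, b)
}
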