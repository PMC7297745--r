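# Independent oracles and fixture builders used across the suite. These
# deliberately take different computational routes from the package code
# they check.

unit_square <- function(dx = 0, dy = 0) {
  cbind(c(0, 1, 1, 0) + dx, c(0, 0, 1, 1) + dy)
}

# random simple convex polygon: convex hull of random points
random_convex_polygon <- function(n_points = 10, center = c(0, 0),
                                  scale = 1) {
  pts <- cbind(stats::runif(n_points, -scale, scale) + center[1],
               stats::runif(n_points, -scale, scale) + center[2])
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}

# --- brute-force polygon distance oracle (segment-segment route) -----------

oracle_seg_seg_dist <- function(p1, p2, p3, p4) {
  # closed form: zero if the segments cross, else the minimum of the four
  # endpoint-to-segment distances
  d <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * ab - p)^2))
  }
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
    (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
  d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
  if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(0)
  min(d(p1, p3, p4), d(p2, p3, p4), d(p3, p1, p2), d(p4, p1, p2))
}

# point strictly inside a CONVEX ring: all cross products share a sign
oracle_point_in_convex <- function(p, ring) {
  n <- nrow(ring)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (ring[j, 1] - ring[i, 1]) * (p[2] - ring[i, 2]) -
      (ring[j, 2] - ring[i, 2]) * (p[1] - ring[i, 1])
    if (cr > 0) s <- s + 1 else if (cr < 0) s <- s - 1
  }
  abs(s) == n
}

oracle_polygon_dist <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (oracle_point_in_convex(a[1, ], b) || oracle_point_in_convex(b[1, ], a)) {
    return(0)
  }
  best <- Inf
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      best <- min(best, oracle_seg_seg_dist(a[i, ], a[i2, ],
                                            b[j, ], b[j2, ]))
      if (best == 0) return(0)
    }
  }
  best
}

# --- Rice / Rayleigh closed forms ------------------------------------------

rayleigh_mean <- function(s) s * sqrt(pi / 2)
rayleigh_sd <- function(s) s * sqrt(2 - pi / 2)
rayleigh_quantile <- function(s, q) s * sqrt(-2 * log(1 - q))

rice_pdf <- function(x, nu, s) {
  # exp-scaled Bessel keeps the product finite for large arguments
  (x / s^2) * exp(-(x - nu)^2 / (2 * s^2)) * besselI(x * nu / s^2, 0,
                                                     expon.scaled = TRUE)
}

rice_mean_quadrature <- function(nu, s) {
  stats::integrate(function(x) x * rice_pdf(x, nu, s), 0, nu + 20 * s,
                   rel.tol = 1e-10)$value
}

rice_sd_quadrature <- function(nu, s) {
  m <- rice_mean_quadrature(nu, s)
  m2 <- stats::integrate(function(x) x^2 * rice_pdf(x, nu, s), 0,
                         nu + 20 * s, rel.tol = 1e-10)$value
  sqrt(m2 - m^2)
}

# --- misc -------------------------------------------------------------------

# independent shoelace/edge-length computations (not the package's own)
ring_edge_lengths_test <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  sqrt(rowSums((ring[j, , drop = FALSE] - ring)^2))
}

ring_area_test <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  abs(sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2])) / 2
}

rotate_ring <- function(ring, phi_deg, about = c(0, 0)) {
  a <- phi_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(ring, 2, about) %*% t(R), 2, about, `+`)
}

calf_model <- function() {
  read_planar_model(system.file("extdata", "calf.json",
                                package = "polycontact"))
}

straight_track <- function(id = "a", n = 5, step = 1, interval = 10,
                           y = 0) {
  fix_table(data.frame(id = id, time = (seq_len(n) - 1) * interval,
                       x = (seq_len(n) - 1) * step, y = y,
                       stringsAsFactors = FALSE))
}
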