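# Pairwise distances per timestep, contact detection under a spatial
# threshold, and extraction of maximal contact bouts.

# build a per-time lookup of geometries: list(time -> list(id -> list(part -> ring)))
series_geoms <- function(series) {
  recs <- split_polygon_records(series)
  out <- list()
  for (r in recs) {
    tkey <- as.character(r$time)
    if (is.null(out[[tkey]])) out[[tkey]] <- list()
    if (is.null(out[[tkey]][[r$id]])) out[[tkey]][[r$id]] <- list()
    out[[tkey]][[r$id]][[r$part]] <- r$ring
  }
  out
}

parse_pairing <- function(pairing) {
  if (identical(pairing, "fullBody") || identical(pairing, "point")) {
    return(list(kind = pairing))
  }
  m <- strsplit(pairing, "[:.]")[[1]]
  if (length(m) != 2) {
    stop_config("pairing must be 'fullBody', 'point' or 'partA:partB'")
  }
  list(kind = "parts", a = m[1], b = m[2])
}

#' Pairwise distances between individuals at every timestep
#'
#' Computes, for each time point and each unordered pair of *distinct*
#' individuals, the minimum distance between the requested geometries.
#' Self-pairs (any two parts of the same individual) never form records.
#'
#' Pairings:
#' * `"point"` — `x` is a [fix_table()]; point-to-point distance (planar
#'   Euclidean, or great-circle for geographic tables).
#' * `"fullBody"` — `x` is a polygon series; the minimum distance over all
#'   part combinations of the two individuals (0 as soon as any two polygons
#'   intersect).
#' * `"partA:partB"` (e.g. `"head:head"`, `"head:posterior"`) — distances
#'   for the named part pair. For unequal parts both ordered combinations
#'   (`a`'s partA vs `b`'s partB, and `b`'s partA vs `a`'s partB) are
#'   reported as separate records.
#'
#' Individuals missing a geometry at a timestep simply contribute no record
#' there (missingness is preserved, not read as distance 0).
#'
#' @param x a `polygon_series` or a [fix_table()].
#' @param pairing pairing specification (see above).
#' @return a `distance_table` data frame: `time`, `id_a`, `part_a`, `id_b`,
#'   `part_b`, `distance`, with `id_a < id_b`.
#' @export
pairwise_distances <- function(x, pairing = "fullBody") {
  p <- parse_pairing(pairing)
  rows <- list()
  add <- function(time, ia, pa, ib, pb, d) {
    rows[[length(rows) + 1]] <<- data.frame(
      time = time, id_a = ia, part_a = pa, id_b = ib, part_b = pb,
      distance = d, stringsAsFactors = FALSE)
  }
  if (p$kind == "point") {
    if (!inherits(x, "fix_table")) {
      stop_config("pairing 'point' requires a fix_table")
    }
    gc <- !is_planar(x)
    ids <- sort(unique(x$id))
    by_id <- lapply(stats::setNames(ids, ids),
                    function(i) x[x$id == i, , drop = FALSE])
    n <- length(ids)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- by_id[[ids[i]]]; b <- by_id[[ids[j]]]
          common <- intersect(a$time, b$time)
          if (length(common) == 0) next
          ai <- match(common, a$time); bi <- match(common, b$time)
          d <- if (gc) {
            haversine_m(a$x[ai], a$y[ai], b$x[bi], b$y[bi])
          } else {
            euclid(a$x[ai], a$y[ai], b$x[bi], b$y[bi])
          }
          rows[[length(rows) + 1]] <- data.frame(
            time = common, id_a = ids[i], part_a = "point", id_b = ids[j],
            part_b = "point", distance = d, stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    if (!inherits(x, "polygon_series")) {
      stop_config("pairing '%s' requires a polygon series", pairing)
    }
    if (p$kind == "parts") {
      have <- unique(x$part)
      miss <- setdiff(c(p$a, p$b), have)
      if (length(miss) > 0) {
        stop_config("part(s) not in series: %s", paste(miss, collapse = ", "))
      }
    }
    geoms <- series_geoms(x)
    for (tkey in names(geoms)) {
      byid <- geoms[[tkey]]
      ids <- sort(names(byid))
      n <- length(ids)
      if (n < 2) next
      time <- as.integer(tkey)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          ga <- byid[[ids[i]]]; gb <- byid[[ids[j]]]
          if (p$kind == "fullBody") {
            d <- Inf
            for (ra in ga) for (rb in gb) {
              d <- min(d, geometry_distance(ra, rb))
              if (d == 0) break
            }
            add(time, ids[i], "fullBody", ids[j], "fullBody", d)
          } else if (p$a == p$b) {
            if (!is.null(ga[[p$a]]) && !is.null(gb[[p$b]])) {
              add(time, ids[i], p$a, ids[j], p$b,
                  geometry_distance(ga[[p$a]], gb[[p$b]]))
            }
          } else {
            if (!is.null(ga[[p$a]]) && !is.null(gb[[p$b]])) {
              add(time, ids[i], p$a, ids[j], p$b,
                  geometry_distance(ga[[p$a]], gb[[p$b]]))
            }
            if (!is.null(gb[[p$a]]) && !is.null(ga[[p$b]])) {
              add(time, ids[j], p$a, ids[i], p$b,
                  geometry_distance(gb[[p$a]], ga[[p$b]]))
            }
          }
        }
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(time = integer(0), id_a = character(0), part_a = character(0),
               id_b = character(0), part_b = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(out$time, out$id_a, out$id_b, out$part_a, out$part_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Directed observer-to-point distances for visual fields
#'
#' For every timestep and ordered pair (observer i, target j != i) computes
#' the distance from j's point location to i's visual-field polygon; 0 means
#' j is inside i's field. This relation is deliberately not symmetrised.
#'
#' @param polygons visual-field `polygon_series` (one part).
#' @param positions planar [fix_table()] of point locations on the same
#'   grid.
#' @return a directed `distance_table` with `id_a` the observer
#'   (`part_a = "visual"`) and `id_b` the observed point
#'   (`part_b = "point"`).
#' @export
visual_distances <- function(polygons, positions) {
  assert_planar(positions, "visual_distances")
  geoms <- series_geoms(polygons)
  rows <- list()
  pos_by_time <- split(seq_len(nrow(positions)), positions$time)
  for (tkey in names(geoms)) {
    pts <- pos_by_time[[tkey]]
    if (is.null(pts)) next
    byid <- geoms[[tkey]]
    time <- as.integer(tkey)
    for (obs in sort(names(byid))) {
      ring <- byid[[obs]][[1]]
      for (k in pts) {
        if (positions$id[k] == obs) next
        d <- geometry_distance(c(positions$x[k], positions$y[k]), ring)
        rows[[length(rows) + 1]] <- data.frame(
          time = time, id_a = obs, part_a = "visual",
          id_b = positions$id[k], part_b = "point", distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(time = integer(0), id_a = character(0), part_a = character(0),
               id_b = character(0), part_b = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(out$time, out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "directed") <- TRUE
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Flag contacts under a spatial threshold
#'
#' A contact occurs when the distance is less than or equal to `spth`
#' (inclusive), so `spth = 0` is the polygon-intersection definition.
#'
#' @param dist a `distance_table`.
#' @param spth spatial threshold, metres (>= 0).
#' @return the table with a logical `contact` column added.
#' @export
detect_contacts <- function(dist, spth) {
  if (!is.numeric(spth) || spth < 0) stop_config("spth must be >= 0")
  dist$contact <- dist$distance <= spth
  dist
}

#' Extract maximal contact bouts
#'
#' Collapses per-timestep contact flags into maximal bouts per dyad (and
#' part pair). Under the default `max_gap = 0` a bout is a run of strictly
#' consecutive grid timesteps in contact; timesteps that are missing from
#' the table or not in contact break bouts. With `max_gap > 0`, runs
#' separated by at most that many non-contact/missing timesteps are merged
#' (the bout's `n_timesteps` still counts only in-contact timesteps).
#'
#' @param flags output of [detect_contacts()].
#' @param grid a [grid_spec()] describing the timestep grid, or `NULL` to
#'   infer interval and window from the data.
#' @param max_gap number of tolerated gap timesteps inside a bout
#'   (default 0).
#' @return a `contact_bouts` data frame: `id_a`, `part_a`, `id_b`, `part_b`,
#'   `directed`, `start_time`, `end_time`, `n_timesteps`.
#' @export
extract_bouts <- function(flags, grid = NULL, max_gap = 0L) {
  if (!is_count(max_gap, min = 0L)) stop_config("max_gap must be >= 0")
  directed <- isTRUE(attr(flags, "directed"))
  if (nrow(flags) == 0) {
    return(empty_bouts(directed))
  }
  if (is.null(grid)) {
    ut <- unique(flags$time)
    grid <- if (length(ut) < 2) {
      # a single observed timestep: any interval yields the same bouts
      grid_spec(1L, min(ut), min(ut) + 1L)
    } else {
      infer_grid(flags$time)
    }
  }
  interval <- grid$interval
  key <- paste(flags$id_a, flags$part_a, flags$id_b, flags$part_b, sep = "\r")
  rows <- list()
  for (idx in split(seq_len(nrow(flags)), key)) {
    times <- sort(flags$time[idx][flags$contact[idx]])
    if (length(times) == 0) next
    # split contact times into bouts wherever the gap exceeds max_gap slots
    gap_slots <- diff(times) / interval - 1
    brk <- c(0, cumsum(gap_slots > max_gap))
    for (g in split(times, brk)) {
      rows[[length(rows) + 1]] <- data.frame(
        id_a = flags$id_a[idx[1]], part_a = flags$part_a[idx[1]],
        id_b = flags$id_b[idx[1]], part_b = flags$part_b[idx[1]],
        directed = directed,
        start_time = g[1], end_time = g[length(g)],
        n_timesteps = length(g), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_bouts(directed))
  out <- do.call(rbind, rows)
  out <- out[order(out$id_a, out$id_b, out$part_a, out$part_b,
                   out$start_time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "interval") <- interval
  class(out) <- c("contact_bouts", "data.frame")
  out
}

empty_bouts <- function(directed = FALSE) {
  out <- data.frame(id_a = character(0), part_a = character(0),
                    id_b = character(0), part_b = character(0),
                    directed = logical(0), start_time = integer(0),
                    end_time = integer(0), n_timesteps = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_bouts", "data.frame")
  out
}
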