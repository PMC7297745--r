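# Cleaning filters and temporal regularisation. Each filter returns the
# retained fixes together with a report so that row accounting is explicit:
# rows_removed + rows_kept always equals the input row count.

#' Confinement filter
#'
#' Retains fixes that fall inside or on a confinement boundary (e.g. a pen
#' fence); points exactly on the boundary are kept.
#'
#' @param fixes planar [fix_table()].
#' @param boundary polygon ring (n x 2 matrix, n >= 3) in the same planar
#'   frame.
#' @return list with elements `fixes` (filtered table, order preserved) and
#'   `report` (a filter report).
#' @export
filter_confine <- function(fixes, boundary) {
  assert_planar(fixes, "filter_confine")
  boundary <- validate_ring(boundary, "boundary")
  keep <- vapply(seq_len(nrow(fixes)),
                 function(i) point_in_polygon(fixes$x[i], fixes$y[i], boundary),
                 logical(1))
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coordinates") <- coord_system(fixes)
  class(out) <- class(fixes)
  list(fixes = out,
       report = new_filter_report("confine", sum(!keep), sum(keep)))
}

#' Duplicate filter
#'
#' Keeps at most one record per (individual, time); the first occurrence in
#' file order wins, including when coordinates disagree.
#'
#' @param fixes a [fix_table()].
#' @return list of `fixes` and `report`. Applying the filter twice is a
#'   no-op.
#' @export
filter_duplicates <- function(fixes) {
  keep <- !duplicated(paste(fixes$id, fixes$time, sep = "\r"))
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coordinates") <- coord_system(fixes)
  class(out) <- class(fixes)
  list(fixes = out, report = new_filter_report("dup", sum(!keep), sum(keep)))
}

#' Speed (metres-per-second) filter
#'
#' Removes fixes implying impossible movement speeds. A single forward pass
#' per individual drops any fix whose implied speed from the last *retained*
#' fix exceeds `max_mps`; the first fix of each individual is always
#' retained. Anchoring to the last retained fix prevents one bad fix from
#' cascading into the deletion of everything after it.
#'
#' @param fixes planar [fix_table()], time-sorted per individual.
#' @param max_mps maximum plausible speed, metres/second (> 0; `Inf` is the
#'   identity).
#' @return list of `fixes` and `report`.
#' @export
filter_speed <- function(fixes, max_mps) {
  assert_planar(fixes, "filter_speed")
  if (!is.numeric(max_mps) || length(max_mps) != 1 || is.na(max_mps) ||
      max_mps <= 0) {
    stop_config("max_mps must be > 0")
  }
  keep <- logical(nrow(fixes))
  for (idx in split(seq_len(nrow(fixes)), fixes$id)) {
    ax <- fixes$x[idx[1]]; ay <- fixes$y[idx[1]]; at <- fixes$time[idx[1]]
    keep[idx[1]] <- TRUE
    for (k in idx[-1]) {
      dt <- fixes$time[k] - at
      d <- euclid(ax, ay, fixes$x[k], fixes$y[k])
      if (dt > 0 && d / dt <= max_mps) {
        keep[k] <- TRUE
        ax <- fixes$x[k]; ay <- fixes$y[k]; at <- fixes$time[k]
      }
    }
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coordinates") <- coord_system(fixes)
  class(out) <- class(fixes)
  list(fixes = out, report = new_filter_report("mps", sum(!keep), sum(keep)))
}

#' Aggregate fixes onto a fixed time grid
#'
#' Produces one record per individual per grid slot `[start + k * interval,
#' start + (k+1) * interval)`, the coordinate being the arithmetic mean of
#' the raw fixes falling in the slot — the interval-average smoothing used
#' to standardise jittered 1-10 s RTLS feeds to a uniform fix interval.
#' Slots with no data are filled by carrying the last known location forward
#' for at most `max_fill_gap` consecutive slots (default 0: left absent).
#'
#' @param fixes planar [fix_table()] (cleaned).
#' @param grid a [grid_spec()].
#' @return planar [fix_table()] whose times are exactly the slot starts,
#'   at most one record per individual per slot.
#' @export
aggregate_time <- function(fixes, grid) {
  assert_planar(fixes, "aggregate_time")
  stopifnot(inherits(grid, "grid_spec"))
  inwin <- fixes$time >= grid$start & fixes$time < grid$end
  if (!any(inwin)) stop_config("no fixes inside the grid window")
  f <- fixes[inwin, , drop = FALSE]
  slots <- grid_times(grid)
  nslot <- length(slots)
  slot_of <- (f$time - grid$start) %/% grid$interval + 1L
  pieces <- lapply(split(seq_len(nrow(f)), f$id), function(idx) {
    sx <- tapply(f$x[idx], slot_of[idx], mean)
    sy <- tapply(f$y[idx], slot_of[idx], mean)
    got <- as.integer(names(sx))
    x <- rep(NA_real_, nslot); y <- rep(NA_real_, nslot)
    x[got] <- as.numeric(sx); y[got] <- as.numeric(sy)
    if (grid$max_fill_gap > 0) {
      gap <- 0L
      for (k in seq_len(nslot)[-1]) {
        if (is.na(x[k])) {
          gap <- gap + 1L
          if (gap <= grid$max_fill_gap && !is.na(x[k - 1])) {
            x[k] <- x[k - 1]; y[k] <- y[k - 1]
          }
        } else {
          gap <- 0L
        }
      }
    }
    ok <- !is.na(x)
    data.frame(id = f$id[idx[1]], time = slots[ok], x = x[ok], y = y[ok],
               stringsAsFactors = FALSE)
  })
  fix_table(do.call(rbind, pieces), coordinates = "planar")
}
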