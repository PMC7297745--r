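#' Construct a fix table
#'
#' A fix table holds time-stamped positions ("fixes") for one or more tracked
#' individuals as reported by a real-time location system (RTLS). It is a
#' plain data frame with columns `id` (character), `time` (integer seconds
#' since epoch), `x` and `y` (metres for planar tables, degrees
#' longitude/latitude for geographic ones), sorted by `(id, time)`, carrying
#' the coordinate system as an attribute.
#'
#' @param x data frame with columns `id`, `time`, `x`, `y`.
#' @param coordinates `"planar"` (metres) or `"geographic"`
#'   (longitude/latitude degrees).
#' @return a `fix_table` data frame.
#' @export
fix_table <- function(x, coordinates = c("planar", "geographic")) {
  coordinates <- match.arg(coordinates)
  need <- c("id", "time", "x", "y")
  if (!all(need %in% names(x))) {
    stop_config("fix table needs columns: %s",
                paste(setdiff(need, names(x)), collapse = ", "))
  }
  out <- data.frame(
    id = as.character(x$id),
    time = as.integer(round(as.numeric(x$time))),
    x = as.numeric(x$x),
    y = as.numeric(x$y),
    stringsAsFactors = FALSE
  )
  if (coordinates == "geographic" && any(abs(out$y) > 90, na.rm = TRUE)) {
    stop_config("geographic fixes need |latitude| <= 90")
  }
  out <- out[order(out$id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coordinates") <- coordinates
  class(out) <- c("fix_table", "data.frame")
  out
}

#' Coordinate system of a fix table
#' @param x a `fix_table`.
#' @return `"planar"` or `"geographic"`.
#' @export
coord_system <- function(x) attr(x, "coordinates") %||% "planar"

is_planar <- function(x) identical(coord_system(x), "planar")

assert_planar <- function(x, op) {
  if (!is_planar(x)) stop_config("%s requires planar (projected) coordinates", op)
  invisible(x)
}

new_filter_report <- function(rule, removed, kept) {
  structure(list(rule = rule, rows_removed = as.integer(removed),
                 rows_kept = as.integer(kept)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter %s>: removed %d, kept %d rows\n",
              x$rule, x$rows_removed, x$rows_kept))
  invisible(x)
}

#' Fixed time grid specification
#'
#' Describes the regular grid of timesteps onto which fixes are aggregated:
#' slots start at `start + k * interval` and cover `[slot, slot + interval)`
#' for `k = 0, ..., (end - start)/interval - 1`.
#'
#' @param interval fix interval in seconds (> 0).
#' @param start,end window in epoch seconds; `interval` must divide
#'   `end - start`.
#' @param max_fill_gap maximum number of consecutive empty slots filled by
#'   carrying the last known location forward (default 0: no fill).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(interval, start, end, max_fill_gap = 0L) {
  if (!is_count(interval)) stop_config("interval must be a positive integer")
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop_config("grid end must be after start")
  if ((end - start) %% interval != 0) {
    stop_config("interval must divide end - start")
  }
  if (!is_count(max_fill_gap, min = 0L)) {
    stop_config("max_fill_gap must be a non-negative integer")
  }
  structure(list(interval = as.integer(interval), start = start, end = end,
                 max_fill_gap = as.integer(max_fill_gap)),
            class = "grid_spec")
}

grid_times <- function(grid) {
  seq(grid$start, grid$end - grid$interval, by = grid$interval)
}

# infer a grid from the times present in a table (used when the caller has
# already aggregated to a fixed interval)
infer_grid <- function(times) {
  ut <- sort(unique(as.integer(times)))
  if (length(ut) < 2) stop_config("cannot infer a grid from fewer than 2 times")
  interval <- min(diff(ut))
  grid_spec(interval, ut[1], ut[length(ut)] + interval)
}
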