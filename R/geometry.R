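# Heading estimation and the point-to-polygon transformation: every fix is
# replaced by rigid template polygons translated to the fix and rotated from
# the template's forward direction to the individual's current heading.

#' Construct a planar model
#'
#' A planar model is the rigid template from which empirical polygons are
#' instantiated: a reference point (where the tracking device sits on the
#' body), a forward direction, and one or more named polygon parts given as
#' vertex rings in the template's own coordinate frame (metres).
#'
#' @param reference_point length-2 numeric, template coordinates of the
#'   tracked device (ear tag, collar).
#' @param forward_direction_deg the direction the modelled animal faces in
#'   the template frame, degrees counter-clockwise from the +x axis.
#' @param parts named list of vertex rings (n x 2 matrices, n >= 3, simple).
#' @return a `planar_model`.
#' @seealso [read_planar_model()] for the JSON file format and the bundled
#'   calf and visual-field models.
#' @export
planar_model <- function(reference_point, forward_direction_deg, parts) {
  if (length(reference_point) != 2 || !all(is.finite(reference_point))) {
    stop_config("reference_point must be a finite (x, y) pair")
  }
  if (!is.finite(forward_direction_deg)) {
    stop_config("forward_direction_deg must be finite")
  }
  if (!is.list(parts) || length(parts) == 0 || is.null(names(parts)) ||
      any(!nzchar(names(parts)))) {
    stop_config("parts must be a non-empty named list of vertex rings")
  }
  part_names <- names(parts)
  parts <- lapply(part_names, function(nm) {
    ring <- validate_ring(parts[[nm]], sprintf("part '%s'", nm))
    if (!ring_is_simple(ring)) {
      stop_config("part '%s' is self-intersecting", nm)
    }
    ring
  })
  names(parts) <- part_names
  structure(list(reference_point = as.numeric(reference_point),
                 forward_direction_deg = norm_deg(forward_direction_deg),
                 parts = parts),
            class = "planar_model")
}

#' @export
print.planar_model <- function(x, ...) {
  cat(sprintf("<planar_model> forward %.1f deg, reference (%.3f, %.3f)\n",
              x$forward_direction_deg, x$reference_point[1],
              x$reference_point[2]))
  for (nm in names(x$parts)) {
    cat(sprintf("  part %-10s %d vertices, area %.4f m^2\n", nm,
                nrow(x$parts[[nm]]), ring_area(x$parts[[nm]])))
  }
  invisible(x)
}

#' Estimate headings from consecutive relocations
#'
#' For each individual the function maintains an anchor: the last position at
#' which the polygon pose was updated. A fix closer than
#' `immobility_threshold` to the anchor leaves the pose (position used for
#' polygon placement and heading) unchanged, discounting jitter such as head
#' shaking; a fix at or beyond the threshold sets the heading to the angle of
#' the anchor-to-fix vector (degrees CCW from +x) and moves the anchor to the
#' fix. The heading is undefined (`NA`) before the first qualifying
#' relocation, so polygons cannot be oriented at the first time point.
#'
#' @param track planar [fix_table()] on a fixed time grid.
#' @param immobility_threshold metres (>= 0). At 0, every observed movement,
#'   however small, updates the pose.
#' @return data frame with columns `id`, `time`, `x_raw`, `y_raw` (reported
#'   fix), `x`, `y` (pose position, i.e. the anchor) and `heading` (degrees,
#'   `NA` while undefined), class `heading_states`.
#' @export
estimate_heading <- function(track, immobility_threshold = 0) {
  assert_planar(track, "estimate_heading")
  if (!is.numeric(immobility_threshold) || immobility_threshold < 0) {
    stop_config("immobility_threshold must be >= 0")
  }
  pieces <- lapply(split(seq_len(nrow(track)), track$id), function(idx) {
    xs <- track$x[idx]; ys <- track$y[idx]
    n <- length(idx)
    px <- numeric(n); py <- numeric(n); hd <- rep(NA_real_, n)
    ax <- xs[1]; ay <- ys[1]; h <- NA_real_
    for (k in seq_len(n)) {
      d <- euclid(ax, ay, xs[k], ys[k])
      if (d > 0 && d >= immobility_threshold) {
        h <- vector_angle_deg(xs[k] - ax, ys[k] - ay)
        ax <- xs[k]; ay <- ys[k]
      }
      px[k] <- ax; py[k] <- ay; hd[k] <- h
    }
    data.frame(id = track$id[idx], time = track$time[idx],
               x_raw = xs, y_raw = ys, x = px, y = py, heading = hd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("heading_states", "data.frame")
  out
}

#' Translate fixes to an offset point on the body
#'
#' Moves each pose position a fixed distance away at a fixed angle relative
#' to the individual's current heading (e.g. from an ear tag to the centre of
#' the head), preserving the angular orientation of movements. Records with
#' undefined heading are omitted.
#'
#' @param states [estimate_heading()] output (or a compatible data frame with
#'   columns `id`, `time`, `x`, `y`, `heading` if headings come from an
#'   external sensor).
#' @param distance offset distance, metres.
#' @param angle offset angle in degrees relative to the heading (0 = straight
#'   ahead, 90 = to the animal's left).
#' @return planar [fix_table()] of translated points.
#' @export
reposition_reference_point <- function(states, distance, angle = 0) {
  ok <- !is.na(states$heading)
  a <- deg2rad(states$heading[ok] + angle)
  fix_table(data.frame(
    id = states$id[ok],
    time = states$time[ok],
    x = states$x[ok] + distance * cos(a),
    y = states$y[ok] + distance * sin(a),
    stringsAsFactors = FALSE
  ), coordinates = "planar")
}

# template geometry relative to the reference point: per part, per vertex,
# the radial distance and absolute template angle
template_polar <- function(model) {
  lapply(model$parts, function(ring) {
    dx <- ring[, 1] - model$reference_point[1]
    dy <- ring[, 2] - model$reference_point[2]
    list(dist = sqrt(dx^2 + dy^2), theta = vector_angle_deg(dx, dy))
  })
}

#' Derive oriented polygons from heading states
#'
#' Instantiates the planar model at every pose with a defined heading. For
#' each template vertex the radial distance from the reference point is
#' preserved and the vertex is placed on the bearing
#' `(theta_l + heading - forward) mod 360` from the pose position, where
#' `theta_l` is the vertex's template angle and `forward` the template's
#' forward direction. When the heading equals the template forward
#' direction this reduces to a pure translation. During immobility spans the
#' pose is frozen, so the previous polygon is re-emitted unchanged. Records
#' before the first relocation (undefined heading) are skipped and counted
#' in the attached `skip_report`.
#'
#' @param states [estimate_heading()] output, or any data frame with columns
#'   `id`, `time`, `x`, `y`, `heading` (external headings are welcome).
#' @param model a [planar_model()].
#' @return a `polygon_series` data frame in long form: columns `id`, `time`,
#'   `part`, `vertex`, `x`, `y`, `heading`.
#' @export
derive_polygons <- function(states, model) {
  if (!inherits(model, "planar_model")) stop_config("model must be a planar_model")
  polar <- template_polar(model)
  ok <- !is.na(states$heading)
  skipped <- sum(!ok)
  st <- states[ok, , drop = FALSE]
  if (nrow(st) == 0) {
    out <- data.frame(id = character(0), time = integer(0),
                      part = character(0), vertex = integer(0),
                      x = numeric(0), y = numeric(0), heading = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "skip_report") <- new_filter_report("undefined_heading",
                                                  skipped, 0L)
    class(out) <- c("polygon_series", "data.frame")
    return(out)
  }
  parts <- names(model$parts)
  blocks <- vector("list", length(parts))
  for (pi in seq_along(parts)) {
    p <- polar[[pi]]
    L <- length(p$dist)
    nrec <- nrow(st)
    # bearings: outer over records x vertices
    bearing <- deg2rad(outer(st$heading - model$forward_direction_deg,
                             p$theta, `+`))
    vx <- st$x + t(t(cos(bearing)) * p$dist)
    vy <- st$y + t(t(sin(bearing)) * p$dist)
    blocks[[pi]] <- data.frame(
      id = rep(st$id, times = L),
      time = rep(st$time, times = L),
      part = parts[pi],
      vertex = rep(seq_len(L), each = nrec),
      x = as.vector(vx),
      y = as.vector(vy),
      heading = rep(st$heading, times = L),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$id, out$time, out$part, out$vertex), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skip_report") <- new_filter_report("undefined_heading", skipped,
                                                nrow(st) * length(parts))
  class(out) <- c("polygon_series", "data.frame")
  out
}

#' Build a triangular visual-field model
#'
#' Constructs the inverted-triangle visual field used for line-of-sight
#' contact: apex at the reference point (the collar), opening forward with
#' the given apex angle, extending `height` metres ahead. The base half-width
#' is `height * tan(apex_angle / 2)`; base interior angles are
#' `(180 - apex_angle) / 2` each.
#'
#' @param height viewing distance, metres (> 0).
#' @param apex_angle total angular width of the field, degrees in (0, 180).
#' @return a [planar_model()] with a single part `"visual"`; the template
#'   forward direction is +y, the apex sits at the origin.
#' @examples
#' vf <- build_visual_field_model(100, 120)  # base half-width 100 * tan(60)
#' @export
build_visual_field_model <- function(height, apex_angle) {
  if (!is.numeric(height) || height <= 0) stop_config("height must be > 0")
  if (!is.numeric(apex_angle) || apex_angle <= 0 || apex_angle >= 180) {
    stop_config("apex_angle must lie in (0, 180) degrees")
  }
  half <- height * tan(deg2rad(apex_angle / 2))
  planar_model(
    reference_point = c(0, 0),
    forward_direction_deg = 90,
    parts = list(visual = cbind(c(0, half, -half), c(0, height, height)))
  )
}

# ---- polygon series helpers -------------------------------------------------

#' Split a polygon series into per-record rings
#'
#' @param series a `polygon_series` (long form).
#' @return list of records, each with `id`, `time`, `part`, `heading` and
#'   the vertex `ring` as an n x 2 matrix.
#' @export
split_polygon_records <- function(series) {
  key <- paste(series$id, series$time, series$part, sep = "\r")
  idx <- split(seq_len(nrow(series)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    i <- i[order(series$vertex[i])]
    list(id = series$id[i[1]], time = series$time[i[1]],
         part = series$part[i[1]], heading = series$heading[i[1]],
         ring = cbind(series$x[i], series$y[i]))
  })
}

bind_polygon_records <- function(recs) {
  blocks <- lapply(recs, function(r) {
    L <- nrow(r$ring)
    data.frame(id = r$id, time = r$time, part = r$part, vertex = seq_len(L),
               x = r$ring[, 1], y = r$ring[, 2], heading = r$heading,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$id, out$time, out$part, out$vertex), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("polygon_series", "data.frame")
  out
}
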