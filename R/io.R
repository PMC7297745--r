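# Reading and writing trajectory tables, polygons, planar models and
# networks. All files are plain text: CSV for tables, WKT-CSV or GeoJSON for
# polygons, JSON for planar models.

EARTH_RADIUS_M <- 6371000

#' Column mapping for Movebank-style CSV exports
#'
#' @return named character vector mapping the internal field names
#'   (`id`, `time`, `x`, `y`) to Movebank column headers.
#' @export
movebank_column_map <- function() {
  c(id = "individual-local-identifier", time = "timestamp",
    x = "location-long", y = "location-lat")
}

parse_epoch_seconds <- function(v) {
  if (is.numeric(v)) return(round(v))
  v <- as.character(v)
  num <- suppressWarnings(as.numeric(v))
  # a fully numeric column (NAs aside) is already epoch seconds
  if (all(!is.na(num) | is.na(v) | !nzchar(v))) return(round(num))
  out <- rep(NA_real_, length(v))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                "%Y/%m/%d %H:%M:%OS")) {
    idx <- which(is.na(out))
    if (length(idx) == 0) break
    out[idx] <- as.numeric(strptime(v[idx], format = fmt, tz = "UTC"))
  }
  round(out)
}

#' Read a trajectory CSV into a fix table
#'
#' Reads a comma-separated trajectory file (header required, UTF-8) and maps
#' its columns onto the internal fields `id`, `time`, `x`, `y`. Timestamps
#' may be epoch seconds or UTC date-times (`YYYY-mm-dd HH:MM:SS`, with or
#' without a `T`). Rows whose coordinates or timestamps do not parse are
#' dropped and counted in the attached parse report.
#'
#' @param path CSV file path.
#' @param column_map named character vector with entries `id`, `time`, `x`,
#'   `y` naming the file's columns; defaults to those exact names. Use
#'   [movebank_column_map()] for Movebank exports.
#' @param coordinates `"planar"`, `"geographic"`, or `NULL` to infer
#'   (geographic when the mapped x column name contains "lon"/"long").
#' @return a [fix_table()] sorted by `(id, time)`, with attribute
#'   `parse_report` giving the number of dropped rows.
#' @export
read_fixes <- function(path, column_map = NULL, coordinates = NULL) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  column_map <- column_map %||% c(id = "id", time = "time", x = "x", y = "y")
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(column_map[c("id", "time", "x", "y")]), names(raw))
  if (length(missing) > 0) {
    stop_config("mapped column(s) absent from %s: %s", path,
                paste(missing, collapse = ", "))
  }
  if (is.null(coordinates)) {
    coordinates <- if (grepl("lon", column_map[["x"]], ignore.case = TRUE)) {
      "geographic"
    } else {
      "planar"
    }
  }
  df <- data.frame(
    id = as.character(raw[[column_map[["id"]]]]),
    time = parse_epoch_seconds(raw[[column_map[["time"]]]]),
    x = suppressWarnings(as.numeric(raw[[column_map[["x"]]]])),
    y = suppressWarnings(as.numeric(raw[[column_map[["y"]]]])),
    stringsAsFactors = FALSE
  )
  ok <- stats::complete.cases(df)
  dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop_config("no parseable fixes in %s", path)
  out <- fix_table(df, coordinates = coordinates)
  attr(out, "parse_report") <- new_filter_report("parse", dropped, nrow(out))
  out
}

#' Write a fix table to CSV
#'
#' @param fixes a [fix_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  df <- as.data.frame(fixes)
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Azimuthal equidistant projection specification
#'
#' @param center_lon,center_lat projection centre in degrees.
#' @return a `projection_spec` list with `method = "azimuthal_equidistant"`.
#' @export
projection_spec <- function(center_lon, center_lat) {
  if (!is.finite(center_lon) || !is.finite(center_lat) ||
      abs(center_lat) > 90) {
    stop_config("projection centre must be finite with |lat| <= 90")
  }
  structure(list(center_lon = center_lon, center_lat = center_lat,
                 method = "azimuthal_equidistant"),
            class = "projection_spec")
}

#' Project geographic fixes onto a plane
#'
#' Applies a spherical azimuthal equidistant projection (earth radius
#' 6,371,000 m), so planar distances from the projection centre equal
#' great-circle distances from the centre. By default the centre is the
#' arithmetic mean of all longitudes and latitudes in the table.
#'
#' @param fixes geographic [fix_table()].
#' @param spec a [projection_spec()], or `"centroid"` to centre on the data
#'   centroid.
#' @return planar [fix_table()] with metres east/north of the centre, the
#'   spec stored in attribute `projection`, and records at the centre's
#'   antipode dropped (counted in attribute `parse_report`).
#' @export
project_to_plane <- function(fixes, spec = "centroid") {
  if (coord_system(fixes) != "geographic") {
    stop_config("project_to_plane requires geographic coordinates")
  }
  if (identical(spec, "centroid")) {
    spec <- projection_spec(mean(fixes$x), mean(fixes$y))
  }
  lam0 <- deg2rad(spec$center_lon)
  phi0 <- deg2rad(spec$center_lat)
  lam <- deg2rad(fixes$x)
  phi <- deg2rad(fixes$y)
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  ok <- c_ang < pi - 1e-6  # antipode of the centre is undefined
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  px <- EARTH_RADIUS_M * k * cos(phi) * sin(lam - lam0)
  py <- EARTH_RADIUS_M * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  out <- fix_table(
    data.frame(id = fixes$id[ok], time = fixes$time[ok],
               x = px[ok], y = py[ok], stringsAsFactors = FALSE),
    coordinates = "planar"
  )
  attr(out, "projection") <- spec
  attr(out, "parse_report") <-
    new_filter_report("projection", sum(!ok), nrow(out))
  out
}

# great-circle distance on the package's reference sphere, used for
# point-based distances on geographic tables
haversine_m <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

fmt_coord <- function(x) sprintf("%.17g", x)

#' Write an oriented polygon series
#'
#' Writes one feature per (individual, time, part) either as WKT-CSV
#' (columns `id,time,part,heading,wkt`; rings closed by repeating the first
#' vertex) or as a GeoJSON FeatureCollection with properties `id`, `time`,
#' `part`, `heading`.
#'
#' @param series a polygon series from [derive_polygons()].
#' @param path output file.
#' @param format `"wkt"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(series, path, format = c("wkt", "geojson")) {
  format <- match.arg(format)
  recs <- split_polygon_records(series)
  if (length(recs) == 0) stop_config("polygon series is empty")
  if (format == "wkt") {
    rows <- vapply(recs, function(r) {
      ring <- rbind(r$ring, r$ring[1, , drop = FALSE])
      wkt <- sprintf("POLYGON((%s))",
                     paste(fmt_coord(ring[, 1]), fmt_coord(ring[, 2]),
                           collapse = ", "))
      sprintf("%s,%d,%s,%s,\"%s\"", r$id, r$time, r$part,
              fmt_coord(r$heading), wkt)
    }, character(1))
    writeLines(c("id,time,part,heading,wkt", rows), path)
  } else {
    feats <- lapply(recs, function(r) {
      ring <- rbind(r$ring, r$ring[1, , drop = FALSE])
      list(type = "Feature",
           properties = list(id = r$id, time = r$time, part = r$part,
                             heading = r$heading),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                             function(i) c(ring[i, 1], ring[i, 2])))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an oriented polygon series
#'
#' Inverse of [write_polygons()] for both supported formats.
#'
#' @param path file written by [write_polygons()].
#' @param format `"wkt"` or `"geojson"`.
#' @return a `polygon_series` data frame.
#' @export
read_polygons <- function(path, format = c("wkt", "geojson")) {
  format <- match.arg(format)
  recs <- list()
  if (format == "wkt") {
    lines <- readLines(path)
    for (ln in lines[-1]) {
      m <- regmatches(ln, regexec(
        '^([^,]*),([^,]*),([^,]*),([^,]*),"POLYGON\\(\\((.*)\\)\\)"$', ln))[[1]]
      if (length(m) != 6) stop_config("malformed WKT-CSV row: %s", ln)
      pairs <- strsplit(strsplit(m[6], ",\\s*")[[1]], "\\s+")
      ring <- do.call(rbind, lapply(pairs, as.numeric))
      ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
      recs[[length(recs) + 1]] <- list(id = m[2], time = as.integer(m[3]),
                                       part = m[4],
                                       heading = as.numeric(m[5]), ring = ring)
    }
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    for (f in gj$features) {
      coords <- f$geometry$coordinates[[1]]
      ring <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
      ring <- ring[-nrow(ring), , drop = FALSE]
      p <- f$properties
      recs[[length(recs) + 1]] <- list(id = p$id, time = as.integer(p$time),
                                       part = p$part,
                                       heading = as.numeric(p$heading),
                                       ring = ring)
    }
  }
  bind_polygon_records(recs)
}

#' Write a contact network as an edge-list CSV
#'
#' Columns `from_id,to_id,from_part,to_part,directed,weight`, rows in
#' lexicographic order. Parallel bout contributions are aggregated into one
#' row per edge before writing.
#'
#' @param net a [contact_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  if (nrow(e) > 0) {
    e <- e[order(e$from, e$to, e$from_part, e$to_part), , drop = FALSE]
  }
  df <- data.frame(from_id = e$from, to_id = e$to,
                   from_part = e$from_part, to_part = e$to_part,
                   directed = rep(isTRUE(net$directed), nrow(e)),
                   weight = e$weight, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list CSV written by [write_network()]
#'
#' @param path edge-list CSV.
#' @param nodes optional full node vector (isolated nodes are not
#'   recoverable from the edge list alone).
#' @return a [contact_network()].
#' @export
read_network <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  directed <- if (nrow(df) > 0) isTRUE(as.logical(df$directed[1])) else FALSE
  edges <- data.frame(from = as.character(df$from_id),
                      to = as.character(df$to_id),
                      from_part = as.character(df$from_part),
                      to_part = as.character(df$to_part),
                      weight = as.numeric(df$weight),
                      stringsAsFactors = FALSE)
  contact_network(edges,
                  nodes = nodes %||% sort(unique(c(edges$from, edges$to))),
                  directed = directed)
}

#' Read a planar model from JSON
#'
#' The file format is a JSON object with fields `reference_point` (length-2
#' array, metres), `forward_direction_deg` (degrees CCW from +x) and `parts`
#' (object mapping part names to arrays of `[x, y]` vertices). Two models
#' ship with the package: `calf.json` (head/anterior/posterior body sections)
#' and `visual_100m_120deg.json` (a 100 m, 120 degree visual field).
#'
#' @param path JSON file; bundled models can be located with
#'   `system.file("extdata", "calf.json", package = "polycontact")`.
#' @return a [planar_model()].
#' @export
read_planar_model <- function(path) {
  if (!file.exists(path)) stop_config("planar model file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  parts <- lapply(obj$parts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  planar_model(reference_point = as.numeric(obj$reference_point),
               forward_direction_deg = as.numeric(obj$forward_direction_deg),
               parts = parts)
}

#' Write a planar model to JSON
#' @param model a [planar_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_planar_model <- function(model, path) {
  jsonlite::write_json(
    list(reference_point = model$reference_point,
         forward_direction_deg = model$forward_direction_deg,
         parts = lapply(model$parts, function(m) {
           lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
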