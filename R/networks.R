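# Time-aggregated contact networks. Edge weight is contact frequency: the
# total number of in-contact timesteps accumulated by the dyad over the
# aggregation window (not the number of bouts).

#' Construct a contact network
#'
#' @param edges data frame with columns `from`, `to`, `from_part`,
#'   `to_part`, `weight`. For undirected networks edges are stored once with
#'   `from < to` lexicographically; self-edges are forbidden.
#' @param nodes character vector of all individuals (isolates included).
#' @param directed logical.
#' @param window optional `c(start, end)` epoch seconds.
#' @return a `contact_network` list.
#' @export
contact_network <- function(edges, nodes, directed = FALSE, window = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) stop_config("self-edges are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes)) {
      stop_config("edge endpoints must be in the node set")
    }
    if (!directed && any(edges$from > edges$to)) {
      stop_config("undirected edges must satisfy from < to")
    }
    if (any(edges$weight <= 0)) stop_config("edge weights must be >= 1")
    edges <- edges[order(edges$from, edges$to, edges$from_part,
                         edges$to_part), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, nodes = nodes, directed = directed,
                 window = window),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %s, %d nodes, %d edges, total weight %g\n",
              if (x$directed) "directed" else "undirected",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Aggregate contact bouts into a weighted network
#'
#' Sums bout lengths (in timesteps) per dyad into edge weights. For
#' undirected networks, asymmetric part pairs are folded: an `i`-head to
#' `j`-posterior bout and a `j`-head to `i`-posterior bout accumulate into
#' the same undirected `(i, j)` edge, whose part columns carry the sorted
#' part-pair label.
#'
#' @param bouts a `contact_bouts` table from [extract_bouts()].
#' @param nodes all individuals under study (the node set; individuals with
#'   no contacts stay as isolates and still count towards density).
#' @param directed build a directed network (visual fields) instead of an
#'   undirected one.
#' @param window optional `c(start, end)` aggregation window; bouts starting
#'   outside it are dropped.
#' @return a [contact_network()] with the contributing bouts attached as
#'   attribute `bouts`.
#' @export
build_network <- function(bouts, nodes, directed = FALSE, window = NULL) {
  b <- as.data.frame(bouts)
  if (!is.null(window)) {
    b <- b[b$start_time >= window[1] & b$end_time <= window[2], ,
           drop = FALSE]
  }
  if (nrow(b) == 0) {
    net <- contact_network(empty_edges(), nodes, directed, window)
    attr(net, "bouts") <- bouts[0, , drop = FALSE]
    return(net)
  }
  if (!directed) {
    swap <- b$id_a > b$id_b
    tmp <- b$id_a[swap]; b$id_a[swap] <- b$id_b[swap]; b$id_b[swap] <- tmp
    # canonical part-pair label irrespective of orientation
    pa <- pmin(b$part_a, b$part_b); pb <- pmax(b$part_a, b$part_b)
    b$part_a <- pa; b$part_b <- pb
  }
  key <- paste(b$id_a, b$id_b, b$part_a, b$part_b, sep = "\r")
  w <- tapply(b$n_timesteps, key, sum)
  parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  edges <- data.frame(from = parts[, 1], to = parts[, 2],
                      from_part = parts[, 3], to_part = parts[, 4],
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  net <- contact_network(edges, nodes, directed, window)
  attr(net, "bouts") <- bouts
  net
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0),
             from_part = character(0), to_part = character(0),
             weight = numeric(0), stringsAsFactors = FALSE)
}

#' Build a directed visual contact network
#'
#' Composes [visual_distances()], [detect_contacts()], [extract_bouts()] and
#' [build_network()]: a directed edge i -> j is incremented at every
#' timestep where j's point location lies within `spth` of i's visual-field
#' polygon.
#'
#' @param polygons visual-field `polygon_series`.
#' @param positions planar [fix_table()] on the same grid.
#' @param spth spatial threshold, metres (0 = strict point-in-polygon).
#' @param grid optional [grid_spec()] for bout extraction.
#' @param nodes node set; defaults to the union of ids present.
#' @return a directed [contact_network()] with attributes `bouts` and
#'   `flags` (the per-timestep contact table).
#' @export
build_visual_network <- function(polygons, positions, spth = 0, grid = NULL,
                                 nodes = NULL) {
  dist <- visual_distances(polygons, positions)
  flags <- detect_contacts(dist, spth)
  bouts <- extract_bouts(flags, grid = grid)
  nodes <- nodes %||% sort(unique(c(polygons$id, positions$id)))
  net <- build_network(bouts, nodes = nodes, directed = TRUE)
  attr(net, "flags") <- flags
  net
}

#' Convert a contact network to an igraph graph
#'
#' @param net a [contact_network()].
#' @return an `igraph` graph with edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "weight")],
    directed = net$directed,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Summary metrics of a contact network
#'
#' Computes the connectivity summaries used to characterise time-aggregated
#' contact networks:
#' * density: `E / (n(n-1)/2)` undirected, `E / (n(n-1))` directed;
#' * node degree: number of distinct partners per node (mean, SD over
#'   nodes);
#' * contact duration: bout lengths in timesteps (mean, SD over bouts);
#' * per-capita sum contacts: total edge weight incident to each node
#'   (mean, SD over nodes);
#' * daily degree: distinct partners per node per UTC calendar day (mean,
#'   SD), when bouts are available;
#' * instantaneous out-degree (directed networks with per-timestep flags):
#'   number of individuals inside a node's visual field at each timestep
#'   (mean, SD over node-timesteps).
#'
#' @param net a [contact_network()].
#' @param bouts optional `contact_bouts` (defaults to those attached by
#'   [build_network()]).
#' @param flags optional per-timestep contact table (defaults to the one
#'   attached by [build_visual_network()]).
#' @return named list of metrics.
#' @export
network_metrics <- function(net, bouts = NULL, flags = NULL) {
  bouts <- bouts %||% attr(net, "bouts")
  flags <- flags %||% attr(net, "flags")
  n <- length(net$nodes)
  e <- net$edges
  npairs <- if (net$directed) n * (n - 1) else n * (n - 1) / 2
  density <- if (npairs > 0) nrow(e) / npairs else NA_real_
  partners <- lapply(stats::setNames(net$nodes, net$nodes), function(v) {
    unique(c(e$to[e$from == v], e$from[e$to == v]))
  })
  deg <- vapply(partners, length, numeric(1))
  strength <- vapply(stats::setNames(net$nodes, net$nodes), function(v) {
    sum(e$weight[e$from == v]) + sum(e$weight[e$to == v])
  }, numeric(1))
  out <- list(
    n_nodes = n, n_edges = nrow(e), density = density,
    degree_mean = mean(deg), degree_sd = stats::sd(deg),
    per_capita_sum_mean = mean(strength),
    per_capita_sum_sd = stats::sd(strength)
  )
  if (!is.null(bouts) && nrow(bouts) > 0) {
    out$duration_mean <- mean(bouts$n_timesteps)
    out$duration_sd <- stats::sd(bouts$n_timesteps)
    day <- function(t) floor(t / 86400)
    # distinct partners per node per UTC day, expanded over bout spans
    dd <- new.env()
    for (k in seq_len(nrow(bouts))) {
      for (d in day(bouts$start_time[k]):day(bouts$end_time[k])) {
        ka <- paste(bouts$id_a[k], d); kb <- paste(bouts$id_b[k], d)
        assign(ka, union(get0(ka, dd, ifnotfound = character(0)),
                         bouts$id_b[k]), envir = dd)
        assign(kb, union(get0(kb, dd, ifnotfound = character(0)),
                         bouts$id_a[k]), envir = dd)
      }
    }
    daily <- vapply(ls(dd), function(k) length(get(k, dd)), numeric(1))
    out$daily_degree_mean <- mean(daily)
    out$daily_degree_sd <- stats::sd(daily)
  } else {
    out$duration_mean <- out$duration_sd <- NA_real_
    out$daily_degree_mean <- out$daily_degree_sd <- NA_real_
  }
  if (net$directed && !is.null(flags) && nrow(flags) > 0) {
    cnt <- tapply(flags$contact, paste(flags$id_a, flags$time), sum)
    out$out_degree_ts_mean <- mean(cnt)
    out$out_degree_ts_sd <- stats::sd(cnt)
  }
  out
}
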