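# RTLS-like synthetic data with known ground truth: correlated random walks
# in a rectangular arena with reflective boundaries, Gaussian positional
# error matching an accuracy model, and scripted contact events that hold a
# pair at an exact separation so the true bout table is known by
# construction.

#' Simulation configuration
#'
#' @param n_individuals number of tracked individuals (>= 1).
#' @param arena `c(width, height)` of the rectangular arena, metres; the
#'   arena is `[0, width] x [0, height]` with reflective boundaries.
#' @param interval fix interval, seconds.
#' @param n_timesteps number of grid timesteps (>= 2).
#' @param step_mean,step_sd per-interval step length distribution, metres
#'   (normal truncated at 0).
#' @param turning_concentration mean resultant length of the wrapped-normal
#'   turning-angle distribution, in `[0, 1]`; 1 walks straight, 0 turns
#'   uniformly.
#' @param accuracy an [accuracy_model()] for the reported (noisy) fixes, or
#'   `NULL` for error-free reporting.
#' @param scripted_events list of events, each a list with `pair`
#'   (length-2 indices or ids), `start`, `end` (epoch seconds on the grid),
#'   `target_distance` (metres), `offset_angle` (degrees; direction from the
#'   leader to the follower relative to the pair's +x line of travel,
#'   default 90), and optionally `anchor` (`c(x, y)` where the leader starts
#'   the event; defaults to its current position). During the event the pair
#'   walks in parallel along +x at `step_mean` per step, exactly
#'   `target_distance` apart.
#' @param eval_spth spatial threshold used to mark ground-truth point
#'   contacts, metres.
#' @param start_positions optional n x 2 matrix of initial positions
#'   (default: uniform in the arena).
#' @param start_headings optional initial headings, degrees.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 10, arena = c(50, 50), interval = 10,
                       n_timesteps = 360, step_mean = 0.3, step_sd = 0.1,
                       turning_concentration = 0.8, accuracy = NULL,
                       scripted_events = list(), eval_spth = 0.5,
                       start_positions = NULL, start_headings = NULL,
                       seed = 1L) {
  if (!is_count(n_individuals)) stop_config("n_individuals must be >= 1")
  if (length(arena) != 2 || any(arena <= 0)) {
    stop_config("arena must be positive c(width, height)")
  }
  if (!is_count(n_timesteps, min = 2L)) stop_config("n_timesteps must be >= 2")
  if (turning_concentration < 0 || turning_concentration > 1) {
    stop_config("turning_concentration must lie in [0, 1]")
  }
  if (!is.null(accuracy) && !inherits(accuracy, "accuracy_model")) {
    stop_config("accuracy must be an accuracy_model or NULL")
  }
  for (ev in scripted_events) {
    if (ev$target_distance > min(arena)) {
      stop_config("scripted event target_distance does not fit in the arena")
    }
  }
  structure(list(n_individuals = as.integer(n_individuals), arena = arena,
                 interval = as.integer(interval),
                 n_timesteps = as.integer(n_timesteps),
                 step_mean = step_mean, step_sd = step_sd,
                 turning_concentration = turning_concentration,
                 accuracy = accuracy, scripted_events = scripted_events,
                 eval_spth = eval_spth, start_positions = start_positions,
                 start_headings = start_headings, seed = as.integer(seed)),
            class = "sim_config")
}

reflect_into <- function(v, lo, hi) {
  # reflect a coordinate into [lo, hi]
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

#' Simulate tracks with ground truth
#'
#' Runs the correlated random walk described by the configuration, applies
#' scripted contact events, and reports three objects: the true planar
#' trajectories, the noisy trajectories (true plus per-coordinate Gaussian
#' error with SD `delta / z` from the accuracy model), and the ground-truth
#' per-timestep contact flags computed from the *true* positions at the
#' evaluation threshold.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `true` ([fix_table()]), `noisy`
#'   ([fix_table()]), `truth` (a `distance_table` with `contact` flags),
#'   `grid` (the [grid_spec()]) and `config`.
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  Tn <- cfg$n_timesteps
  ids <- sprintf("ind%02d", seq_len(n))
  times <- (seq_len(Tn) - 1L) * cfg$interval
  X <- matrix(NA_real_, Tn, n)
  Y <- matrix(NA_real_, Tn, n)
  if (is.null(cfg$start_positions)) {
    X[1, ] <- stats::runif(n, 0, cfg$arena[1])
    Y[1, ] <- stats::runif(n, 0, cfg$arena[2])
  } else {
    X[1, ] <- cfg$start_positions[, 1]
    Y[1, ] <- cfg$start_positions[, 2]
  }
  heading <- cfg$start_headings %||% stats::runif(n, 0, 360)
  rho <- cfg$turning_concentration
  sd_turn_deg <- if (rho >= 1) 0 else if (rho <= 0) Inf else {
    rad2deg(sqrt(-2 * log(rho)))
  }
  for (k in 2:Tn) {
    turn <- if (is.infinite(sd_turn_deg)) {
      stats::runif(n, -180, 180)
    } else if (sd_turn_deg == 0) {
      rep(0, n)
    } else {
      stats::rnorm(n, 0, sd_turn_deg)
    }
    heading <- norm_deg(heading + turn)
    step <- pmax(0, stats::rnorm(n, cfg$step_mean, cfg$step_sd))
    nx <- X[k - 1, ] + step * cos(deg2rad(heading))
    ny <- Y[k - 1, ] + step * sin(deg2rad(heading))
    # reflective boundaries flip position and heading
    bounce_x <- nx < 0 | nx > cfg$arena[1]
    bounce_y <- ny < 0 | ny > cfg$arena[2]
    X[k, ] <- reflect_into(nx, 0, cfg$arena[1])
    Y[k, ] <- reflect_into(ny, 0, cfg$arena[2])
    heading[bounce_x] <- norm_deg(180 - heading[bounce_x])
    heading[bounce_y] <- norm_deg(-heading[bounce_y])
  }
  # scripted events override movement: the pair walks along +x in lockstep,
  # exactly target_distance apart
  for (ev in cfg$scripted_events) {
    pa <- ev$pair[1]; pb <- ev$pair[2]
    ia <- if (is.character(pa)) match(pa, ids) else as.integer(pa)
    ib <- if (is.character(pb)) match(pb, ids) else as.integer(pb)
    ks <- which(times >= ev$start & times <= ev$end)
    if (length(ks) == 0) next
    off_angle <- deg2rad(ev$offset_angle %||% 90)
    offx <- ev$target_distance * cos(off_angle)
    offy <- ev$target_distance * sin(off_angle)
    anchor <- ev$anchor %||% c(X[ks[1], ia], Y[ks[1], ia])
    lx <- anchor[1] + (seq_along(ks) - 1) * cfg$step_mean
    ly <- rep(anchor[2], length(ks))
    X[ks, ia] <- lx;        Y[ks, ia] <- ly
    X[ks, ib] <- lx + offx; Y[ks, ib] <- ly + offy
    if (any(X[ks, c(ia, ib)] < 0 | X[ks, c(ia, ib)] > cfg$arena[1] |
            Y[ks, c(ia, ib)] < 0 | Y[ks, c(ia, ib)] > cfg$arena[2])) {
      stop_config("scripted event walks outside the arena")
    }
    # resume the walk where the event left the pair
    k_end <- ks[length(ks)]
    if (k_end < Tn && !any(vapply(cfg$scripted_events, function(e2) {
      times[k_end + 1] >= e2$start && times[k_end + 1] <= e2$end &&
        any(c(ia, ib) %in% c(e2$pair))
    }, logical(1)))) {
      for (kk in (k_end + 1):Tn) {
        for (ii in c(ia, ib)) {
          step <- max(0, stats::rnorm(1, cfg$step_mean, cfg$step_sd))
          X[kk, ii] <- reflect_into(X[kk - 1, ii] + step, 0, cfg$arena[1])
          Y[kk, ii] <- Y[kk - 1, ii]
        }
      }
    }
  }
  true_df <- data.frame(
    id = rep(ids, each = Tn), time = rep(times, times = n),
    x = as.vector(X), y = as.vector(Y), stringsAsFactors = FALSE)
  true <- fix_table(true_df, coordinates = "planar")
  noisy <- if (is.null(cfg$accuracy)) {
    true
  } else {
    s <- cfg$accuracy$sigma
    nd <- true_df
    nd$x <- nd$x + stats::rnorm(nrow(nd), 0, s)
    nd$y <- nd$y + stats::rnorm(nrow(nd), 0, s)
    fix_table(nd, coordinates = "planar")
  }
  truth <- detect_contacts(pairwise_distances(true, pairing = "point"),
                           cfg$eval_spth)
  list(true = true, noisy = noisy, truth = truth,
       grid = grid_spec(cfg$interval, 0L, Tn * cfg$interval),
       config = cfg)
}

#' Scripted contact scenarios
#'
#' Fixed configurations whose ground-truth contact structure is known by
#' construction:
#' * `converge_pair` — two walkers 5 m apart that close to 0.2 m for the
#'   final 40 timesteps: exactly one 40-timestep bout.
#' * `parallel_walk` — two walkers 0.3 m apart for the whole run: one bout
#'   spanning every timestep.
#' * `head_to_tail` — single-file walkers 2.4 m apart (nose to tail): with
#'   the bundled calf body model, contacts arise only in the
#'   head-to-posterior pairing, never head-to-head.
#' * `visual_crossing` — one walker 50 m directly ahead of another, both
#'   facing +x: the rear individual sees the front one (directed edge
#'   present) but not vice versa.
#'
#' @param name scenario name.
#' @return a [sim_config()].
#' @seealso [scenario_ground_truth()] for the closed-form bout tables.
#' @export
scripted_contact_scenario <- function(name = c("converge_pair",
                                               "parallel_walk",
                                               "head_to_tail",
                                               "visual_crossing")) {
  name <- match.arg(name)
  two_start <- rbind(c(10, 40), c(10, 45))
  switch(name,
    converge_pair = sim_config(
      n_individuals = 2, arena = c(100, 100), interval = 10,
      n_timesteps = 120, step_mean = 0.3, step_sd = 0,
      turning_concentration = 1, accuracy = accuracy_model(0.5, 0.90),
      eval_spth = 0.5, start_positions = two_start,
      start_headings = c(0, 0), seed = 42L,
      scripted_events = list(list(pair = c(1, 2), start = 800, end = 1190,
                                  target_distance = 0.2, offset_angle = 90,
                                  anchor = c(30, 40)))),
    parallel_walk = sim_config(
      n_individuals = 2, arena = c(100, 100), interval = 10,
      n_timesteps = 120, step_mean = 0.3, step_sd = 0,
      turning_concentration = 1, accuracy = NULL, eval_spth = 0.5,
      start_positions = two_start, start_headings = c(0, 0), seed = 42L,
      scripted_events = list(list(pair = c(1, 2), start = 0, end = 1190,
                                  target_distance = 0.3, offset_angle = 90,
                                  anchor = c(10, 50)))),
    head_to_tail = sim_config(
      n_individuals = 2, arena = c(100, 100), interval = 10,
      n_timesteps = 60, step_mean = 0.3, step_sd = 0,
      turning_concentration = 1, accuracy = NULL, eval_spth = 0.5,
      start_positions = two_start, start_headings = c(0, 0), seed = 42L,
      scripted_events = list(list(pair = c(1, 2), start = 0, end = 590,
                                  target_distance = 2.4, offset_angle = 180,
                                  anchor = c(50, 50)))),
    visual_crossing = sim_config(
      n_individuals = 2, arena = c(200, 200), interval = 1,
      n_timesteps = 60, step_mean = 0.5, step_sd = 0,
      turning_concentration = 1, accuracy = NULL, eval_spth = 0.5,
      start_positions = rbind(c(20, 100), c(25, 100)),
      start_headings = c(0, 0), seed = 42L,
      scripted_events = list(list(pair = c(1, 2), start = 0, end = 59,
                                  target_distance = 50, offset_angle = 0,
                                  anchor = c(20, 100))))
  )
}

#' Ground-truth bout table of a scripted scenario
#'
#' The closed-form point-contact bout table implied by the scenario
#' construction (true positions, evaluation threshold); for the polygon- and
#' visual-level expectations of `head_to_tail` and `visual_crossing` see the
#' scenario descriptions.
#'
#' @param name scenario name as in [scripted_contact_scenario()].
#' @return a `contact_bouts`-shaped data frame.
#' @export
scenario_ground_truth <- function(name = c("converge_pair", "parallel_walk",
                                           "head_to_tail",
                                           "visual_crossing")) {
  name <- match.arg(name)
  bout <- function(start, end, n) {
    data.frame(id_a = "ind01", part_a = "point", id_b = "ind02",
               part_b = "point", directed = FALSE, start_time = start,
               end_time = end, n_timesteps = n, stringsAsFactors = FALSE)
  }
  switch(name,
    converge_pair = bout(800L, 1190L, 40L),
    parallel_walk = bout(0L, 1190L, 120L),
    head_to_tail = bout(integer(0), integer(0), integer(0))[0, ],
    visual_crossing = bout(integer(0), integer(0), integer(0))[0, ]
  )
}
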