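# Null models by path randomisation and empirical-vs-null comparison.
# Randomising trajectories destroys temporal synchrony between individuals
# while preserving each individual's space use exactly, so contacts in the
# randomised replicates occur "at random" given the observed movement.

permute_blocks <- function(n_times, block_length) {
  blocks <- split(seq_len(n_times),
                  (seq_len(n_times) - 1) %/% block_length)
  unlist(blocks[sample(length(blocks))], use.names = FALSE)
}

#' Randomise movement paths
#'
#' Within each individual, the time series is cut into consecutive blocks of
#' `block_length` timesteps and the blocks' temporal order is permuted
#' uniformly at random. Timestamps stay on the grid; the location (or
#' polygon) blocks move between them, so the multiset of each individual's
#' locations, the record count and the timestamp set are preserved exactly.
#'
#' The `stage` matters when polygons are oriented from the movement data
#' itself: `"before_polygons"` permutes the fixes and re-derives headings
#' and polygons (orientations are re-estimated from the shuffled path),
#' whereas `"after_polygons"` permutes already-derived polygon records, so
#' the replicate keeps the empirical orientations.
#'
#' @param x a planar [fix_table()] (stage `"before_polygons"`) or a
#'   `polygon_series` (stage `"after_polygons"`).
#' @param block_length block size in timesteps (>= 1; e.g. one day of 10-s
#'   fixes is 8,640 timesteps).
#' @param stage `"before_polygons"` or `"after_polygons"`.
#' @param model optional [planar_model()]: with stage `"before_polygons"`,
#'   polygons are re-derived from the shuffled fixes and returned instead of
#'   the fixes.
#' @param immobility_threshold passed to [estimate_heading()] when
#'   re-deriving.
#' @param seed optional integer seed.
#' @return a randomised replicate of the same type as `x` (or a
#'   `polygon_series` when `model` is supplied). Individuals whose series is
#'   shorter than one block are left unpermuted with a warning.
#' @export
randomize_paths <- function(x, block_length,
                            stage = c("before_polygons", "after_polygons"),
                            model = NULL, immobility_threshold = 0,
                            seed = NULL) {
  stage <- match.arg(stage)
  if (!is_count(block_length)) {
    stop_config("block_length must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  if (stage == "before_polygons") {
    if (!inherits(x, "fix_table")) {
      stop_config("stage 'before_polygons' randomises a fix_table")
    }
    pieces <- lapply(split(seq_len(nrow(x)), x$id), function(idx) {
      n <- length(idx)
      if (n < block_length) {
        warning("series shorter than one block; left unpermuted")
        perm <- seq_len(n)
      } else {
        perm <- permute_blocks(n, block_length)
      }
      data.frame(id = x$id[idx[1]], time = x$time[idx],
                 x = x$x[idx][perm], y = x$y[idx][perm],
                 stringsAsFactors = FALSE)
    })
    out <- fix_table(do.call(rbind, pieces), coordinates = coord_system(x))
    if (!is.null(model)) {
      return(derive_polygons(
        estimate_heading(out, immobility_threshold = immobility_threshold),
        model))
    }
    return(out)
  }
  # after_polygons: move whole per-timestep polygon records between times
  if (!inherits(x, "polygon_series")) {
    stop_config("stage 'after_polygons' randomises a polygon series")
  }
  pieces <- lapply(split(seq_len(nrow(x)), x$id), function(idx) {
    times <- sort(unique(x$time[idx]))
    n <- length(times)
    if (n < block_length) {
      warning("series shorter than one block; left unpermuted")
      perm <- seq_len(n)
    } else {
      perm <- permute_blocks(n, block_length)
    }
    # record at old time times[perm[k]] is reassigned to times[k]
    remap <- stats::setNames(times, as.character(times[perm]))
    piece <- x[idx, , drop = FALSE]
    piece$time <- as.integer(remap[as.character(piece$time)])
    piece
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$id, out$time, out$part, out$vertex), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("polygon_series", "data.frame")
  out
}

off_diagonal <- function(m) m[row(m) != col(m)]

#' Two-sided permutation Mantel test
#'
#' Pearson correlation between the off-diagonal entries of two square
#' association matrices, with a permutation p-value from `n_perm`
#' simultaneous row/column permutations of the second matrix. The p-value is
#' two-sided and includes the observed statistic in the null set:
#' `p = (#\{|r_perm| >= |r_obs|\} + 1) / (n_perm + 1)`, so p is never zero.
#'
#' @param m1,m2 square matrices of equal dimension (diagonals ignored).
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional integer seed.
#' @return list with `r`, `p`, `n_perm`, and `degenerate` (TRUE when an
#'   off-diagonal is constant and r is undefined).
#' @export
mantel_test <- function(m1, m2, n_perm = 10000L, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1)) {
    stop_config("m1 and m2 must be square matrices of equal dimension")
  }
  if (!is_count(n_perm)) stop_config("n_perm must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  v1 <- off_diagonal(m1)
  if (stats::sd(v1) == 0 || stats::sd(off_diagonal(m2)) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                degenerate = TRUE))
  }
  r_obs <- stats::cor(v1, off_diagonal(m2))
  n <- nrow(m1)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_perm <- stats::cor(v1, off_diagonal(m2[idx, idx]))
    if (abs(r_perm) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       degenerate = FALSE)
}

#' Chi-squared goodness-of-fit of observed contacts against a null
#'
#' Compares observed per-node or per-dyad contact counts with expected
#' counts from null replicates: `X2 = sum((O - E)^2 / E)` with `df = k - 1`
#' after pooling, upper-tail p-value. Cells whose expected count is not
#' positive are pooled into a single cell first.
#'
#' @param observed,expected numeric vectors of equal length.
#' @return list with `statistic`, `df`, `p_value`, `n_pooled`.
#' @export
contact_chi2_test <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop_config("observed and expected must have equal length")
  }
  bad <- !(expected > 0)
  n_pooled <- 0L
  if (any(bad)) {
    if (all(bad)) stop_config("all cells have non-positive expectation")
    o_pool <- sum(observed[bad]); e_pool <- sum(expected[bad])
    observed <- observed[!bad]; expected <- expected[!bad]
    n_pooled <- sum(bad)
    if (e_pool > 0) {
      observed <- c(observed, o_pool)
      expected <- c(expected, e_pool)
    } else if (o_pool > 0) {
      stop_config("observed counts in cells with zero expectation")
    }
  }
  k <- length(expected)
  if (k < 2) stop_config("need at least 2 cells after pooling")
  stat <- sum((observed - expected)^2 / expected)
  df <- k - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_pooled = n_pooled)
}
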