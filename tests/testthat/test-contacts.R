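test_that("geometry distances handle touching, separated and nested shapes", {
  expect_equal(geometry_distance(unit_square(), unit_square(dx = 1)), 0)
  expect_equal(geometry_distance(unit_square(), unit_square(dx = 2)), 1)
  expect_equal(geometry_distance(c(0.5, 0.5), unit_square()), 0)
  expect_equal(geometry_distance(c(2, 0.5), unit_square()), 1)
  expect_equal(geometry_distance(c(0, 0), c(3, 4)), 5)
  # overlap and full containment are both distance 0
  expect_equal(geometry_distance(unit_square(), unit_square(0.5, 0.5)), 0)
  big <- unit_square() * 10
  expect_equal(geometry_distance(big, unit_square(2, 2)), 0)
  expect_error(geometry_distance(cbind(0:1, 0:1), unit_square()), "vertices")
})

test_that("polygon distances match the brute-force segment oracle", {
  set.seed(41)
  for (k in 1:500) {
    a <- random_convex_polygon(8, center = runif(2, -3, 3))
    b <- random_convex_polygon(8, center = runif(2, -3, 3))
    expect_equal(geometry_distance(a, b), oracle_polygon_dist(a, b),
                 tolerance = 1e-9)
  }
})

test_that("pairwise distances cover the requested part pairs only", {
  model <- calf_model()
  mk <- function(ids, xs, ys) {
    rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(id = ids[i], time = c(0, 10), x = c(xs[i] - 1, xs[i]),
                 y = ys[i], stringsAsFactors = FALSE)
    }))
    derive_polygons(estimate_heading(fix_table(rows), 0), model)
  }
  series <- mk(c("a", "b", "c"), c(0, 10, 20), c(0, 0, 0))

  hh <- pairwise_distances(series, "head:head")
  expect_equal(nrow(hh), 3)           # C(3,2) per timestep with data
  expect_true(all(hh$id_a < hh$id_b))
  expect_true(all(hh$distance >= 0))

  hp <- pairwise_distances(series[series$id != "c", ], "head:posterior")
  expect_equal(nrow(hp), 2)           # both ordered part combinations
  expect_setequal(paste(hp$id_a, hp$part_a), c("a head", "b head"))

  fb <- pairwise_distances(series[series$id != "c", ], "fullBody")
  expect_equal(nrow(fb), 1)
  # fullBody distance is the minimum over all part combinations
  mins <- min(vapply(c("head:head", "head:posterior", "posterior:posterior",
                       "anterior:anterior", "head:anterior",
                       "anterior:posterior"), function(p) {
    min(pairwise_distances(series[series$id != "c", ], p)$distance)
  }, numeric(1)))
  expect_equal(fb$distance, mins)

  expect_error(pairwise_distances(series, "head:tail"), "not in series")

  # undirected distances are symmetric under input relabelling
  relabeled <- series
  relabeled$id <- ifelse(relabeled$id == "a", "b",
                         ifelse(relabeled$id == "b", "a", "c"))
  hh2 <- pairwise_distances(relabeled, "head:head")
  expect_equal(sort(hh2$distance), sort(hh$distance), tolerance = 1e-12)
})

test_that("point pairing works planar and great-circle", {
  fx <- fix_table(data.frame(id = c("a", "b"), time = 0, x = c(0, 3),
                             y = c(0, 4)))
  d <- pairwise_distances(fx, "point")
  expect_equal(d$distance, 5)
  geo <- fix_table(data.frame(id = c("a", "b"), time = 0, x = c(0, 0),
                              y = c(0, 1)), coordinates = "geographic")
  dg <- pairwise_distances(geo, "point")
  expect_equal(dg$distance, 6371000 * pi / 180, tolerance = 1)
})

test_that("contact detection is inclusive at the threshold", {
  d <- data.frame(time = 0L, id_a = "a", part_a = "p", id_b = "b",
                  part_b = "p", distance = c(0, 0.56, 0.561))
  d$time <- c(0L, 10L, 20L)
  class(d) <- c("distance_table", "data.frame")
  flags <- detect_contacts(d, 0.56)
  expect_equal(flags$contact, c(TRUE, TRUE, FALSE))
  expect_true(detect_contacts(d[1, ], 0)$contact)
  expect_error(detect_contacts(d, -1), "spth")
})

test_that("contact sets are nested across thresholds", {
  set.seed(43)
  d <- data.frame(time = rep(0:49, 2) * 10L,
                  id_a = "a", part_a = "p",
                  id_b = rep(c("b", "c"), each = 50), part_b = "p",
                  distance = runif(100, 0, 2))
  class(d) <- c("distance_table", "data.frame")
  small <- which(detect_contacts(d, 0.3)$contact)
  large <- which(detect_contacts(d, 1.2)$contact)
  expect_true(all(small %in% large))
})

test_that("bout extraction finds maximal runs and respects gaps", {
  mk_flags <- function(bits, times = seq_along(bits) * 10 - 10) {
    d <- data.frame(time = as.integer(times), id_a = "a", part_a = "p",
                    id_b = "b", part_b = "p", distance = ifelse(bits, 0, 9))
    class(d) <- c("distance_table", "data.frame")
    detect_contacts(d, 0.5)
  }
  grid <- grid_spec(10, 0, 50)
  b <- extract_bouts(mk_flags(c(1, 1, 1, 0, 1)), grid)
  expect_equal(b$n_timesteps, c(3, 1))
  expect_equal(b$start_time, c(0, 40))
  expect_equal(b$end_time, c(20, 40))
  # invariant: n_timesteps = (end - start)/interval + 1 at max_gap = 0
  expect_equal(b$n_timesteps, (b$end_time - b$start_time) / 10 + 1)

  expect_equal(nrow(extract_bouts(mk_flags(c(0, 0, 0, 0, 0)), grid)), 0)

  # a merged bout still counts only in-contact timesteps
  merged <- extract_bouts(mk_flags(c(1, 1, 1, 0, 1)), grid, max_gap = 1)
  expect_equal(merged$n_timesteps, 4)

  # a missing timestep breaks bouts exactly like a non-contact one
  f <- mk_flags(c(1, 1, 1, 1, 1))
  f <- f[f$time != 20, ]
  b <- extract_bouts(f, grid)
  expect_equal(b$n_timesteps, c(2, 2))
})

test_that("total bout timesteps conserve the contact count on random strings", {
  set.seed(47)
  for (k in 1:20) {
    bits <- runif(60) < 0.4
    d <- data.frame(time = (0:59) * 10L, id_a = "a", part_a = "p",
                    id_b = "b", part_b = "p",
                    distance = ifelse(bits, 0, 9))
    class(d) <- c("distance_table", "data.frame")
    b <- extract_bouts(detect_contacts(d, 0.5), grid_spec(10, 0, 600))
    expect_equal(sum(b$n_timesteps), sum(bits))
  }
})
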