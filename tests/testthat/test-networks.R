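mk_bouts <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id_a = r[[1]], part_a = r[[2]], id_b = r[[3]], part_b = r[[4]],
               directed = FALSE, start_time = as.integer(r[[5]]),
               end_time = as.integer(r[[6]]), n_timesteps = as.integer(r[[7]]),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("contact_bouts", "data.frame")
  out
}

test_that("edge weights sum bout timesteps and fold asymmetric part pairs", {
  b <- mk_bouts(list("A", "fullBody", "B", "fullBody", 0, 20, 3))
  net <- build_network(b, nodes = c("A", "B"))
  expect_equal(net$edges$weight, 3)

  b <- mk_bouts(list("A", "fullBody", "B", "fullBody", 0, 20, 3),
                list("A", "fullBody", "B", "fullBody", 100, 110, 2))
  net <- build_network(b, nodes = c("A", "B"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 5)

  # i-head/j-posterior and j-head/i-posterior accumulate into one edge
  b <- mk_bouts(list("A", "head", "B", "posterior", 0, 0, 1),
                list("B", "head", "A", "posterior", 50, 60, 2))
  net <- build_network(b, nodes = c("A", "B"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_equal(net$edges$from, "A")
  expect_true(net$edges$from < net$edges$to)
})

test_that("network metrics match hand computation on a 4-node graph", {
  b <- mk_bouts(list("A", "p", "B", "p", 0, 20, 3),
                list("A", "p", "C", "p", 0, 0, 1),
                list("B", "p", "C", "p", 0, 10, 2),
                list("B", "p", "C", "p", 100, 100, 1))
  net <- build_network(b, nodes = c("A", "B", "C", "D"))
  m <- network_metrics(net)
  expect_equal(m$density, 3 / 6)
  expect_equal(m$degree_mean, mean(c(2, 2, 2, 0)))
  expect_equal(m$degree_sd, sd(c(2, 2, 2, 0)))
  # per-capita sum contacts: A = 3+1, B = 3+3, C = 1+3, D = 0
  expect_equal(m$per_capita_sum_mean, mean(c(4, 6, 4, 0)))
  expect_equal(m$duration_mean, mean(c(3, 1, 2, 1)))
  # conservation: sum of node strengths is twice the total edge weight
  expect_equal(sum(c(4, 6, 4, 0)), 2 * sum(net$edges$weight))
  expect_true(m$density >= 0 && m$density <= 1)
})

test_that("metrics agree with igraph on a random graph", {
  set.seed(59)
  ids <- sprintf("n%02d", 1:8)
  pairs <- t(combn(ids, 2))
  take <- runif(nrow(pairs)) < 0.5
  rows <- lapply(which(take), function(k) {
    list(pairs[k, 1], "p", pairs[k, 2], "p", 0, 0, sample(1:9, 1))
  })
  net <- build_network(do.call(mk_bouts, rows), nodes = ids)
  m <- network_metrics(net)
  g <- as_igraph(net)
  expect_equal(m$density, igraph::edge_density(g))
  expect_equal(m$degree_mean, mean(igraph::degree(g)))
  expect_equal(m$per_capita_sum_mean, mean(igraph::strength(g)))
})

test_that("a complete graph has density one", {
  ids <- sprintf("calf%02d", 1:70)
  pairs <- t(combn(ids, 2))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    list(pairs[k, 1], "fullBody", pairs[k, 2], "fullBody", 0, 0, 1)
  })
  net <- build_network(do.call(mk_bouts, rows), nodes = ids)
  expect_equal(network_metrics(net)$density, 1.00)
})

test_that("visual networks are directed and not symmetrised", {
  vf <- build_visual_field_model(100, 120)
  # observer at origin heading +y (moved from y=-1 to 0), targets ahead/behind
  obs <- fix_table(data.frame(id = "obs", time = c(0, 1), x = 0,
                              y = c(-1, 0)))
  states <- estimate_heading(obs, 0)
  polys <- derive_polygons(states, vf)
  inside <- fix_table(data.frame(id = c("obs", "tgt"), time = 1,
                                 x = c(0, 0), y = c(0, 50)))
  net <- build_visual_network(polys, inside, spth = 0)
  expect_true(net$directed)
  expect_equal(net$edges$from, "obs")
  expect_equal(net$edges$to, "tgt")

  behind <- fix_table(data.frame(id = c("obs", "tgt"), time = 1,
                                 x = c(0, 0), y = c(0, -1)))
  net2 <- build_visual_network(polys, behind, spth = 0)
  expect_equal(nrow(net2$edges), 0)

  # two opposed walkers: each faces away from the other -> no edges at all;
  # one walker behind another facing the same way -> a single asymmetric edge
  fx <- fix_table(data.frame(
    id = rep(c("i", "j"), each = 2), time = rep(c(0, 1), 2),
    x = c(0, 0, 0, 0), y = c(-1, 0, 31, 30)))
  st <- estimate_heading(fx, 0)        # i heads +y, j heads -y
  ps <- derive_polygons(st, vf)
  pos <- fix_table(data.frame(id = c("i", "j"), time = 1, x = 0,
                              y = c(0, 30)))
  net3 <- build_visual_network(ps, pos, spth = 0)
  expect_equal(paste(net3$edges$from, net3$edges$to),
               c("i j", "j i"))  # facing each other head-on: both see
  fx4 <- fix_table(data.frame(
    id = rep(c("i", "j"), each = 2), time = rep(c(0, 1), 2),
    x = c(0, 0, 0, 0), y = c(-1, 0, 29, 30)))
  ps4 <- derive_polygons(estimate_heading(fx4, 0), vf)
  pos4 <- fix_table(data.frame(id = c("i", "j"), time = 1, x = 0,
                               y = c(0, 30)))
  net4 <- build_visual_network(ps4, pos4, spth = 0)
  expect_equal(paste(net4$edges$from, net4$edges$to), "i j")
})

test_that("directed density uses ordered pairs", {
  b <- mk_bouts(list("A", "visual", "B", "point", 0, 0, 1))
  b$directed <- TRUE
  net <- build_network(b, nodes = c("A", "B", "C"), directed = TRUE)
  expect_equal(network_metrics(net)$density, 1 / 6)
})
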