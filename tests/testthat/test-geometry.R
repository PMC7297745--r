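test_that("headings follow relocations and respect the immobility threshold", {
  fx <- fix_table(data.frame(id = "a", time = c(0, 10), x = c(0, 1), y = 0))
  st <- estimate_heading(fx, 0)
  expect_true(is.na(st$heading[1]))
  expect_equal(st$heading[2], 0)

  fx <- fix_table(data.frame(id = "a", time = c(0, 10), x = 0, y = c(0, 2)))
  expect_equal(estimate_heading(fx, 0)$heading[2], 90)

  # sub-threshold wiggles freeze position and heading entirely
  fx <- fix_table(data.frame(id = "a", time = c(0, 10, 20),
                             x = c(0, 0.05, 0.05), y = c(0, 0, 0.05)))
  st <- estimate_heading(fx, 0.1)
  expect_true(all(is.na(st$heading)))
  expect_equal(st$x, c(0, 0, 0))
  expect_equal(st$y, c(0, 0, 0))

  # single-fix track: all undefined
  one <- fix_table(data.frame(id = "a", time = 0, x = 0, y = 0))
  expect_true(is.na(estimate_heading(one, 0)$heading))
})

test_that("with zero threshold every heading equals the step atan2 oracle", {
  set.seed(21)
  n <- 200
  steps <- cbind(rnorm(n), rnorm(n))
  pos <- apply(steps, 2, cumsum)
  fx <- fix_table(data.frame(id = "w", time = (0:n) * 10,
                             x = c(0, pos[, 1]), y = c(0, pos[, 2])))
  st <- estimate_heading(fx, 0)
  oracle <- (atan2(steps[, 2], steps[, 1]) * 180 / pi) %% 360
  expect_equal(st$heading[-1], oracle, tolerance = 1e-12)
  # invariant: every observed movement updated the pose
  expect_equal(st$x[-1], pos[, 1])
})

test_that("reference-point repositioning shifts along the heading and inverts", {
  st <- estimate_heading(straight_track(n = 3), 0)  # heading 0 where defined
  out <- reposition_reference_point(st, 1, 0)
  expect_equal(nrow(out), 2)  # undefined-heading record omitted
  expect_equal(out$x, st$x[-1] + 1)
  expect_equal(out$y, st$y[-1])

  up <- fix_table(data.frame(id = "a", time = c(0, 10), x = 0, y = c(0, 3)))
  stu <- estimate_heading(up, 0)
  shifted <- reposition_reference_point(stu, 1, 0)
  expect_equal(shifted$y, 3 + 1)  # heading 90: +1 in y

  # offset (d, 180) then (d, 0) recovers the original points
  set.seed(3)
  wander <- fix_table(data.frame(id = "a", time = (0:20) * 10,
                                 x = cumsum(rnorm(21)), y = cumsum(rnorm(21))))
  stw <- estimate_heading(wander, 0)
  fwd <- reposition_reference_point(stw, 2.5, 180)
  st2 <- stw[!is.na(stw$heading), ]
  st2$x <- fwd$x; st2$y <- fwd$y
  back <- reposition_reference_point(st2, 2.5, 0)
  expect_equal(back$x, stw$x[!is.na(stw$heading)], tolerance = 1e-9)
  expect_equal(back$y, stw$y[!is.na(stw$heading)], tolerance = 1e-9)
})

test_that("heading equal to the template forward reduces to pure translation", {
  model <- calf_model()
  st <- estimate_heading(straight_track(n = 3, step = 2), 0)
  series <- derive_polygons(st, model)  # headings 0 = template forward
  for (r in split_polygon_records(series)) {
    template <- model$parts[[r$part]]
    loc <- c(st$x[st$time == r$time], st$y[st$time == r$time])
    shift <- sweep(template, 2, model$reference_point)
    expected <- sweep(shift, 2, loc, `+`)
    expect_equal(r$ring, expected, tolerance = 1e-12)
  }
})

test_that("a 90-degree heading rotates the template by the rotation-matrix oracle", {
  model <- calf_model()
  fx <- fix_table(data.frame(id = "a", time = c(0, 10), x = 0, y = c(0, 5)))
  st <- estimate_heading(fx, 0)  # heading 90
  series <- derive_polygons(st, model)
  loc <- c(0, 5)
  for (r in split_polygon_records(series)) {
    template <- model$parts[[r$part]]
    centered <- sweep(template, 2, model$reference_point)
    expected <- sweep(rotate_ring(centered, 90), 2, loc, `+`)
    expect_equal(r$ring, expected, tolerance = 1e-9)
  }
})

test_that("derived polygons are rigid bodies at any heading", {
  model <- calf_model()
  set.seed(9)
  fx <- fix_table(data.frame(id = "a", time = (0:30) * 10,
                             x = cumsum(rnorm(31)), y = cumsum(rnorm(31))))
  series <- derive_polygons(estimate_heading(fx, 0), model)
  for (r in split_polygon_records(series)) {
    template <- model$parts[[r$part]]
    expect_equal(ring_edge_lengths_test(r$ring),
                 ring_edge_lengths_test(template), tolerance = 1e-9)
    expect_equal(ring_area_test(r$ring), ring_area_test(template),
                 tolerance = 1e-9)
  }
  # calf-specific edge lengths: 0.333 m head, 1 m body sections
  heads <- series[series$part == "head", ]
  r1 <- split_polygon_records(heads)[[1]]
  expect_equal(ring_edge_lengths_test(r1$ring), rep(0.333, 4),
               tolerance = 1e-9)
})

test_that("rotating all fixes rotates all derived polygons (equivariance)", {
  model <- calf_model()
  set.seed(13)
  xy <- cbind(cumsum(rnorm(12, sd = 0.5)), cumsum(rnorm(12, sd = 0.5)))
  fx <- fix_table(data.frame(id = "a", time = (0:11) * 10,
                             x = xy[, 1], y = xy[, 2]))
  base <- derive_polygons(estimate_heading(fx, 0), model)
  phi <- 37
  rot_xy <- rotate_ring(xy, phi)
  fx_rot <- fix_table(data.frame(id = "a", time = (0:11) * 10,
                                 x = rot_xy[, 1], y = rot_xy[, 2]))
  rotated <- derive_polygons(estimate_heading(fx_rot, 0), model)
  expect_equal(cbind(rotated$x, rotated$y),
               rotate_ring(cbind(base$x, base$y), phi), tolerance = 1e-6)
})

test_that("the bearing formula matches the equivalent textbook form on random triples", {
  set.seed(31)
  theta <- runif(1000, 0, 360)
  eta <- runif(1000, 0, 360)
  eta_star <- runif(1000, 0, 360)
  ours <- (theta + eta - eta_star) %% 360
  published_form <- (360 - (eta_star - (theta + eta))) %% 360
  expect_equal(ours, published_form, tolerance = 1e-9)
})

test_that("visual-field triangles have the stated opening geometry", {
  vf <- build_visual_field_model(100, 120)
  ring <- vf$parts$visual
  expect_equal(ring[1, ], c(0, 0))              # apex at the collar
  expect_equal(abs(ring[2:3, 1]), rep(100 * tan(pi / 3), 2),
               tolerance = 1e-9)                # base half-width ~173.205
  expect_equal(ring[2:3, 2], c(100, 100))

  vf2 <- build_visual_field_model(1, 90)
  expect_equal(vf2$parts$visual,
               cbind(c(0, 1, -1), c(0, 1, 1)), tolerance = 1e-12)
  # interior angles: apex + 2 equal base angles summing to 180
  base_angle <- function(apex) (180 - apex) / 2
  expect_equal(base_angle(120), 30)
  expect_error(build_visual_field_model(100, 180), "apex_angle")
  expect_error(build_visual_field_model(-1, 90), "height")
})

test_that("frozen spans re-emit the previous polygon unchanged", {
  model <- calf_model()
  fx <- fix_table(data.frame(id = "a", time = (0:3) * 10,
                             x = c(0, 1, 1.05, 1.02), y = 0))
  series <- derive_polygons(estimate_heading(fx, 0.1), model)
  recs <- split_polygon_records(series[series$part == "head", ])
  expect_equal(length(recs), 3)  # t=0 skipped (no heading yet)
  expect_equal(recs[[2]]$ring, recs[[1]]$ring)
  expect_equal(recs[[3]]$ring, recs[[1]]$ring)
  expect_equal(attr(series, "skip_report")$rows_removed, 1)
})
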