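fld_x <- field_vector(c(1, 0), strength = 300)

test_that("directedness hits its definitional limits and hand values", {
  expect_equal(directedness(straight_tracks(50, angle = 0), fld_x)$value, 1)
  expect_equal(directedness(straight_tracks(50, angle = pi), fld_x)$value, -1)
  # (1,0) and (0,1): mean of cos = (1 + 0)/2
  tk <- displacement_tracks(rbind(c(1, 0), c(0, 1)))
  expect_equal(directedness(tk, fld_x)$value, 0.5)
})

test_that("zero-net-displacement cells are excluded with a warning", {
  tk <- displacement_tracks(rbind(c(1, 0), c(0, 0)))
  expect_warning(d <- directedness(tk, fld_x), "zero net displacement")
  expect_equal(d$n, 1)
  expect_equal(d$n_excluded, 1)
  expect_equal(d$value, 1)
  expect_error(directedness(displacement_tracks(matrix(0, 1, 2)), fld_x)
               |> suppressWarnings(), "empty group")
})

test_that("speed is net displacement over elapsed time, with path-length
           auxiliaries", {
  tk <- displacement_tracks(rbind(c(12, 0)), elapsed_h = 6)
  expect_equal(speeds(tk)$value, 2)
  tk <- displacement_tracks(rbind(c(3, 4)), elapsed_h = 2)
  expect_equal(speeds(tk)$value, 2.5)
  # closed loop: net speed 0 but positive path speed
  loop <- tracks(data.frame(cell_id = "a", frame = 0:4,
                            time_h = (0:4) / 2,
                            x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0)))
  s <- speeds(loop)
  expect_equal(s$value, 0)
  expect_equal(s$per_cell$path_length, 4)
  expect_error(trajectory_speed(data.frame(time_h = 0, x = 0, y = 0)),
               "undefined speed")
})

test_that("net speed never exceeds path speed", {
  tk <- simulate_walks(walk_config(100, kappa_bias = 1, kappa_persist = 2,
                                   mix_weight = 0.5, seed = 10))
  s <- speeds(tk)$per_cell
  expect_true(all(s$speed <= s$path_speed + 1e-12))
})

test_that("orientation index distinguishes parallel, perpendicular and
           mixed axes", {
  expect_equal(orientation_index(rep(pi / 2, 20), fld_x)$value, -1)
  expect_equal(orientation_index(rep(0, 20), fld_x)$value, 1)
  expect_equal(orientation_index(rep(c(0, pi / 2), 10), fld_x)$value, 0)
  # NA axes excluded, not imputed
  oi <- orientation_index(c(0, NA, 0), fld_x)
  expect_equal(oi$n, 2)
  expect_equal(oi$n_excluded, 1)
  expect_error(orientation_index(c(NA_real_, NA_real_), fld_x),
               "empty group")
})

test_that("orientation index equals the real part of mean(exp(2i theta))", {
  set.seed(31)
  for (rep in 1:5) {
    th <- runif(50, 0, pi)
    oracle <- Re(mean(exp(2i * th)))
    expect_equal(orientation_index(th, fld_x)$value, oracle,
                 tolerance = 1e-12)
  }
})

test_that("mean area averages region areas", {
  expect_equal(mean_area(c(100, 300))$value, 200)
  expect_equal(mean_area(data.frame(area = 57.3))$value, 57.3)
  expect_error(mean_area(numeric(0)), "empty group")
})

test_that("metrics are invariant under a common rotation and directedness
           flips with the field", {
  tk <- simulate_walks(walk_config(60, kappa_bias = 2, seed = 12))
  a <- 0.83
  rot <- tk
  rot$x <- cos(a) * tk$x - sin(a) * tk$y
  rot$y <- sin(a) * tk$x + cos(a) * tk$y
  f_rot <- field_vector(c(cos(a), sin(a)))
  expect_equal(directedness(rot, f_rot)$value,
               directedness(tk, fld_x)$value, tolerance = 1e-9)
  expect_equal(speeds(rot)$value, speeds(tk)$value, tolerance = 1e-9)
  f_neg <- field_vector(c(-1, 0))
  expect_equal(directedness(tk, f_neg)$value,
               -directedness(tk, fld_x)$value, tolerance = 1e-12)
  th <- runif(40, 0, pi)
  expect_equal(orientation_index(th, f_neg)$value,
               orientation_index(th, fld_x)$value, tolerance = 1e-12)
})

test_that("directedness time series uses cumulative displacement and
           trends to 1 for strong bias", {
  tk <- simulate_walks(walk_config(400, kappa_bias = 5, mix_weight = 1,
                                   seed = 14))
  ts <- time_series(tk, fld_x, "directedness")
  expect_equal(nrow(ts), 36)           # frame 0 omitted
  expect_false(0 %in% ts$frame)
  expect_gt(mean(ts$value[30:36]), mean(ts$value[1:5]) - 0.02)
  expect_gt(ts$value[36], 0.9)
  # hand check one frame: cumulative from frame 0
  d3 <- directedness(tracks(as.data.frame(tk)[tk$frame %in% c(0, 3), ],
                            frame_interval = 10), fld_x)
  expect_equal(ts$value[ts$frame == 3], d3$value)
})

test_that("orientation time series is constant for frozen perpendicular
           shapes and errors on mismatched grids", {
  regions <- data.frame(frame_index = rep(0:5, each = 10),
                        axis_angle = pi / 2)
  ts <- time_series(regions, fld_x, "orientation")
  expect_equal(ts$value, rep(-1, 6))
  bad <- straight_tracks(2)
  bad <- tracks(as.data.frame(bad)[-3, ])   # knock one frame out
  expect_error(time_series(bad, fld_x, "directedness"), "alignment error")
})
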