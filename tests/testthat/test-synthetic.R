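test_that("walk configs are validated and simulation is seed-deterministic", {
  expect_error(walk_config(0), "n_cells")
  expect_error(walk_config(5, mix_weight = 1.2), "mix_weight")
  expect_error(walk_config(5, speed_mean = -1), "speed")
  cfg <- walk_config(4, n_steps = 12, kappa_bias = 3, mix_weight = 0.7,
                     kappa_persist = 2, seed = 42)
  expect_identical(simulate_walks(cfg), simulate_walks(cfg))
})

test_that("unbiased walks are isotropic and strongly biased walks are
           almost perfectly directed", {
  fld <- field_vector(c(1, 0))
  iso <- simulate_walks(walk_config(2000, kappa_bias = 0, kappa_persist = 0,
                                    seed = 5))
  expect_lt(abs(directedness(iso, fld)$value), 0.05)
  bias <- simulate_walks(walk_config(300, kappa_bias = 50, mix_weight = 1,
                                     seed = 5))
  expect_gt(directedness(bias, fld)$value, 0.99)
})

test_that("step-heading concentration matches the von Mises Bessel ratio", {
  # mean resultant length of headings vs I1(k)/I0(k) by quadrature
  for (kap in c(0.5, 2)) {
    tk <- simulate_walks(walk_config(700, n_steps = 36, kappa_bias = kap,
                                     mix_weight = 1, seed = 9))
    h <- step_headings(tk)
    mrl <- sqrt(mean(cos(h))^2 + mean(sin(h))^2)
    expect_equal(mrl, vm_mrl_quadrature(kap), tolerance = 0.02)
    expect_equal(vm_mrl_quadrature(kap), besselI(kap, 1) / besselI(kap, 0),
                 tolerance = 1e-8)   # quadrature oracle self-check
  }
})

test_that("rotating the target angle rotates the walks exactly
           (matched seeds)", {
  a <- simulate_walks(walk_config(50, kappa_bias = 4, mix_weight = 0.6,
                                  kappa_persist = 2, target_angle = 0,
                                  seed = 3))
  alpha <- 2 * pi / 5
  b <- simulate_walks(walk_config(50, kappa_bias = 4, mix_weight = 0.6,
                                  kappa_persist = 2, target_angle = alpha,
                                  seed = 3))
  expect_equal(b$x, cos(alpha) * a$x - sin(alpha) * a$y, tolerance = 1e-9)
  expect_equal(b$y, sin(alpha) * a$x + cos(alpha) * a$y, tolerance = 1e-9)
})

test_that("doubling speed_mean doubles displacements at matched seeds", {
  a <- simulate_walks(walk_config(40, speed_mean = 10, kappa_bias = 2,
                                  seed = 8))
  b <- simulate_walks(walk_config(40, speed_mean = 20, kappa_bias = 2,
                                  seed = 8))
  expect_equal(b$x, 2 * a$x, tolerance = 1e-9)
  expect_equal(b$y, 2 * a$y, tolerance = 1e-9)
})

test_that("shape stacks honour their axial-orientation parameters", {
  fld <- field_vector(c(1, 0))
  # hard perpendicular alignment -> ground-truth orientation index ~ -1
  sim <- simulate_shape_stack(shape_config(
    n_cells = 30, kappa_axial = 200, preferred_axis = pi / 2,
    image_shape = c(600L, 600L), pixel_size = 1, seed = 2))
  expect_lt(orientation_index(sim$truth$axis_angle, fld)$value, -0.99)
  # kappa 0 -> uniform axial orientations, index near 0 (truth, n large)
  many <- shape_config(2000, kappa_axial = 0, image_shape = c(600L, 600L),
                       n_frames = 40L, pixel_size = 1, seed = 4)
  sim2 <- simulate_shape_stack(many)
  expect_lt(abs(orientation_index(sim2$truth$axis_angle, fld)$value), 0.05)
})

test_that("requested ellipse area survives rasterization within 5%", {
  sim <- simulate_shape_stack(shape_config(
    n_cells = 1, mean_area = 400, area_cv = 0, aspect_mean = 2,
    image_shape = c(100L, 100L), pixel_size = 1, seed = 1))
  rm <- measure_labelmask_stack(sim$stack, 1)
  expect_equal(rm$area, 400, tolerance = 0.05)
})

test_that("impossible placements raise a placement error", {
  expect_error(simulate_shape_stack(shape_config(
    n_cells = 60, mean_area = 900, area_cv = 0, aspect_mean = 1,
    image_shape = c(80L, 80L), pixel_size = 1, seed = 1, max_tries = 20)),
    "placement error")
})

test_that("null pairs are uniform, independent, and reproducible", {
  p1 <- make_null_pair(2000, 30, seed = 6)
  expect_lt(resultant_vector(p1$a)$r, 0.05)
  p2 <- make_null_pair(2000, 30, seed = 6)
  expect_identical(p1$a$angles, p2$a$angles)
  expect_error(make_null_pair(1, 30), "sample sizes")
})
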