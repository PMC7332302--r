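test_that("channel resistances follow the conduction and duct formulas", {
  seg <- channel_segment(1e-3, 1e-3, 100e-6, conductivity = 1.536)
  expect_equal(electrical_resistance(seg), 1e-3 / (1.536 * 1e-7))
  expect_equal(electrical_resistance(channel_segment(2e-3, 1e-3, 100e-6)),
               2 * electrical_resistance(channel_segment(1e-3, 1e-3, 100e-6)))
  expect_equal(channel_segment(1, 1, 0.5)$conductivity, 1.536)  # default
  expect_error(channel_segment(1, -1, 0.5), "invalid segment")
  # hydraulics: interconnects vs mains, per unit length
  ic <- channel_segment(1, 0.84e-3, 10e-6)
  mn <- channel_segment(1, 2e-3, 100e-6)
  expect_gt(hydraulic_resistance(ic) / hydraulic_resistance(mn), 1000)
  sq <- channel_segment(1, 1e-4, 1e-4)
  expect_true(is.finite(hydraulic_resistance(sq)) &&
                hydraulic_resistance(sq) > 0)
  visc2 <- channel_segment(1, 0.84e-3, 10e-6, viscosity = 2 * 0.946e-3)
  expect_equal(hydraulic_resistance(visc2), 2 * hydraulic_resistance(ic))
  expect_error(hydraulic_resistance(channel_segment(1, 10e-6, 0.84e-3)),
               "convention error")
})

test_that("single resistors and parallel pairs obey Ohm and symmetry", {
  net <- channel_network(data.frame(from = "a", to = "b", resistance = 50),
                         source = list(type = "current", value = 2e-3,
                                       pos = "a"), ground = "b")
  sol <- solve_network(net)
  expect_equal(unname(sol$potentials["a"]), 0.1)   # V = I R
  par <- channel_network(
    data.frame(from = c("a", "a"), to = c("b", "b"),
               resistance = c(100, 100)),
    source = list(type = "current", value = 2e-3, pos = "a"), ground = "b")
  sp <- solve_network(par)
  expect_equal(sp$currents$current, c(1e-3, 1e-3))
})

test_that("divider currents match an independent mesh-analysis oracle", {
  R <- 100
  net <- channel_network(
    data.frame(from = c("s", "m", "m"), to = c("m", "g", "g"),
               resistance = c(R, 2 * R, 2 * R)),
    source = list(type = "current", value = 1e-3, pos = "s"), ground = "g")
  sol <- solve_network(net)
  # mesh oracle: loop 1 (source, forced i1 = 1 mA) runs s -> m -> g via the
  # first 2R; loop 2 circulates through both 2R branches.
  # KVL loop 2: 2R (i2 - i1) + 2R i2 = 0  =>  i2 = 2R i1 / 4R
  i1 <- 1e-3
  i2 <- (2 * R * i1) / (4 * R)
  expect_equal(sol$currents$current[sol$currents$from == "s"], 1e-3)
  br <- sol$currents$current[sol$currents$from == "m"]
  expect_equal(br, c(1e-3 - i2, i2), tolerance = 1e-12)
})

test_that("voltage sources give the same fields as equivalent current
           sources", {
  edges <- data.frame(from = c("a", "b", "b"), to = c("b", "c", "c"),
                      resistance = c(10, 40, 40))
  vnet <- channel_network(edges, source = list(type = "voltage", value = 3,
                                               pos = "a"), ground = "c")
  vs <- solve_network(vnet)
  # total resistance 10 + 20 = 30 -> 0.1 A from the source
  expect_equal(vs$source_current, 0.1, tolerance = 1e-12)
  inet <- channel_network(edges, source = list(type = "current", value = 0.1,
                                               pos = "a"), ground = "c")
  is <- solve_network(inet)
  expect_equal(vs$currents$current, is$currents$current, tolerance = 1e-12)
})

test_that("Kirchhoff residuals vanish and reciprocity holds on random
           connected networks", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(4:9, 1)
    nodes <- paste0("n", seq_len(n))
    # random spanning tree + extra chords guarantees connectivity
    e <- data.frame(from = nodes[1 + floor((seq_len(n - 1) - 1) *
                                             runif(n - 1))],
                    to = nodes[2:n],
                    resistance = 10^runif(n - 1, 0, 3))
    extra <- sample(n, 2)
    if (extra[1] != extra[2])
      e <- rbind(e, data.frame(from = nodes[extra[1]], to = nodes[extra[2]],
                               resistance = 10^runif(1, 0, 3)))
    src <- sample(nodes, 2)
    net <- channel_network(e, source = list(type = "current",
                                            value = 10^runif(1, -4, -1),
                                            pos = src[1]), ground = src[2])
    sol <- solve_network(net)
    expect_lt(sol$kcl_residual, 1e-9)
    # reciprocity: swapping terminals negates every edge current
    swap <- channel_network(e, source = list(type = "current",
                                             value = net$source$value,
                                             pos = src[2]), ground = src[1])
    ss <- solve_network(swap)
    expect_equal(ss$currents$current, -sol$currents$current,
                 tolerance = 1e-9)
  }
  disc <- channel_network(
    data.frame(from = c("a", "c"), to = c("b", "d"), resistance = c(1, 1)),
    source = list(type = "current", value = 1, pos = "a"), ground = "d")
  expect_error(solve_network(disc), "singular-network")
})

test_that("section field strengths and ratio scaling reproduce the chip's
           published values", {
  efs <- scale_to_max(c(5.25, 2.5, 1, 0), 300)
  expect_equal(efs[1], 300)
  expect_equal(efs[4], 0)
  expect_equal(efs[2], 142.8, tolerance = 0.001)  # 142.857 prints as 142.8
  expect_equal(efs[3], 57.1, tolerance = 0.002)
  expect_equal(scale_to_max(c(5.25, 2.5, 1, 0), 0), rep(0, 4))
  # EFS from current density: uniform series channel -> equal EFS
  segs <- rep(list(channel_segment(5e-3, 2e-3, 100e-6)), 3)
  se <- section_efs(rep(2e-4, 3), segs)
  expect_equal(se$efs, rep(2e-4 / (1.536 * 2e-7), 3))
  expect_equal(se$section_id, c("I", "II", "III"))
})

test_that("r2r ladders produce graded, roughly halving rung currents", {
  net <- r2r_ladder(4, r_series = 100)
  sol <- solve_network(net)
  rungs <- sol$currents[grepl("^T[1-9]", sol$currents$from) &
                          sol$currents$to == "REF", ]
  rungs <- rungs[!duplicated(rungs$from), ]   # drop the T1 termination
  rungs <- rungs[order(rungs$from), ]
  mag <- abs(rungs$current)
  expect_true(all(diff(mag) > 0))      # grows toward the source end
  ratios <- mag[-1] / mag[-length(mag)]
  expect_equal(ratios, rep(2, length(ratios)), tolerance = 1e-9)
  # ratios invariant to source magnitude over 3 decades
  for (I0 in c(1e-5, 1e-3, 1e-2)) {
    net2 <- net; net2$source$value <- I0
    m2 <- abs(solve_network(net2)$currents$current)
    expect_equal(m2 / abs(sol$currents$current), rep(I0 / 1e-3, length(m2)),
                 tolerance = 1e-9)
  }
})
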