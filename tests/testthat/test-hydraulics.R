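test_that("rectangular-duct resistance matches independent oracles", {
  # frozen value recomputed by hand from the exact series before building
  expect_equal(rect_duct_resistance(100e-6, 40e-6, 150e-6),
               2.59409e11, tolerance = 1e-4)
  # exact linearity in length and w/h exchange symmetry
  R1 <- rect_duct_resistance(80e-6, 30e-6, 100e-6)
  expect_equal(rect_duct_resistance(80e-6, 30e-6, 200e-6), 2 * R1)
  expect_equal(rect_duct_resistance(30e-6, 80e-6, 100e-6), R1)
  # cross-section Poisson finite-difference oracle (independent path)
  for (dims in list(c(100e-6, 40e-6), c(50e-6, 50e-6))) {
    expect_equal(rect_duct_resistance(dims[1], dims[2], 1e-4),
                 poisson_duct_resistance(dims[1], dims[2], 1e-4),
                 tolerance = 0.01)
  }
})

test_that("0.63 closed form tracks the exact series on its validity range", {
  for (r in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    Re <- rect_duct_resistance(1e-4, r * 1e-4, 1e-4)
    Ra <- rect_duct_resistance(1e-4, r * 1e-4, 1e-4, method = "approx")
    expect_lt(abs(Ra / Re - 1), 0.003)
  }
  # near the square duct the one-term form is known to overestimate
  Re <- rect_duct_resistance(1e-4, 1e-4, 1e-4)
  Ra <- rect_duct_resistance(1e-4, 1e-4, 1e-4, method = "approx")
  expect_gt(Ra / Re - 1, 0.10)
})

test_that("capillary resistance follows Hagen-Poiseuille scalings", {
  expect_equal(circular_capillary_resistance(capillary_spec(25, 20)),
               1.439392e16, tolerance = 1e-6)
  R25 <- circular_capillary_resistance(capillary_spec(25, 20))
  expect_equal(circular_capillary_resistance(capillary_spec(50, 20)),
               R25 / 16)
  expect_equal(circular_capillary_resistance(capillary_spec(25, 10)),
               R25 / 2)
})

test_that("network construction counts nodes and edges by layout", {
  g <- make_preset("40-2")
  net <- build_network(g)
  n_ch <- 20; n_ser <- 2
  expect_equal(nrow(net$nodes), 4 + n_ser * n_ch * 4)
  expect_equal(nrow(net$edges), n_ser * 2 * (n_ch + 1) + 3 * n_ser * n_ch)
  # a capillary adds exactly one node and one edge, all else untouched
  netc <- build_network(g, capillary = capillary_spec(25, 20))
  expect_equal(nrow(netc$nodes), nrow(net$nodes) + 1)
  expect_equal(nrow(netc$edges), nrow(net$edges) + 1)
  expect_equal(netc$edges$resistance[netc$edges$label != "capillary"],
               net$edges$resistance)
})

test_that("trivial one-edge network obeys the Ohm analogue", {
  net <- structure(list(
    nodes = data.frame(id = c("A", "B"), kind = "interior", value = 0,
                       stringsAsFactors = FALSE),
    edges = data.frame(id = 1L, from = "A", to = "B", resistance = 3e12,
                       label = "medium_segment", series = NA_integer_,
                       chamber = NA_integer_, stringsAsFactors = FALSE),
    geom_name = "trivial", n_series = 0L, n_chambers = 0L,
    has_capillary = FALSE), class = "hydraulic_network")
  q0 <- 2e-11
  sol <- solve_network(set_boundary(net, fixed_flow = c(A = q0),
                                    fixed_pressure = c(B = 0)))
  expect_equal(sol$edge_flows$flow, q0)
  expect_equal(unname(sol$node_pressures["A"]), 3e12 * q0)
})

test_that("sparse solver agrees with the dense oracle on random networks", {
  for (seed in 1:5) {
    net <- random_network(30, seed)
    sol <- solve_network(net)
    oracle <- dense_solve_oracle(net)
    scale <- max(abs(oracle))
    expect_lt(max(abs(sol$node_pressures[names(oracle)] - oracle)) / scale,
              1e-10)
    expect_lt(max_node_imbalance(sol), 1e-12)
  }
})

test_that("solution is invariant under node and edge reordering", {
  net <- random_network(20, 42)
  perm <- net
  set.seed(7)
  perm$nodes <- perm$nodes[sample(nrow(perm$nodes)), ]
  perm$edges <- perm$edges[sample(nrow(perm$edges)), ]
  p1 <- solve_network(net)$node_pressures
  p2 <- solve_network(perm)$node_pressures
  expect_equal(p2[names(p1)], p1, tolerance = 1e-12)
})

test_that("floating subgraphs are reported with the disconnected nodes", {
  net <- random_network(10, 3)
  net$nodes <- rbind(net$nodes,
                     data.frame(id = c("orph1", "orph2"), kind = "interior",
                                value = 0))
  net$edges <- rbind(net$edges,
                     data.frame(id = max(net$edges$id) + 1, from = "orph1",
                                to = "orph2", resistance = 1e12,
                                label = "medium_segment",
                                series = NA_integer_,
                                chamber = NA_integer_))
  expect_error(solve_network(net), "orph1.*orph2")
  expect_error(solve_network(random_network(5, 1)$nodes), "hydraulic_network")
})

test_that("perfusion of the chip conserves flow port to port", {
  for (preset in c("25-5", "40-2")) {
    g <- make_preset(preset)
    sol <- solve_perfusion(g, ulmin_to_m3s(1))
    expect_lt(max_node_imbalance(sol), 1e-12)
    ed <- sol$edge_flows
    out <- sum(vapply(c("medium_out", "cell_in", "cell_out"), function(p) {
      sum(ed$flow[ed$to == p]) - sum(ed$flow[ed$from == p])
    }, numeric(1)))
    expect_equal(out / sol$inlet_flow, 1, tolerance = 1e-12)
  }
})

test_that("creeping-flow responses are homogeneous of degree one", {
  g <- make_preset("40-2")
  s1 <- solve_perfusion(g, ulmin_to_m3s(1))
  s2 <- solve_perfusion(g, ulmin_to_m3s(2))
  expect_equal(s2$node_pressures, 2 * s1$node_pressures, tolerance = 1e-12)
  expect_equal(s2$edge_flows$flow, 2 * s1$edge_flows$flow, tolerance = 1e-12)
  m1 <- chamber_shear_map(s1, g); m2 <- chamber_shear_map(s2, g)
  expect_equal(m2$tau_cell, 2 * m1$tau_cell, tolerance = 1e-12)
})

test_that("wall shear matches the parallel-plate closed form", {
  expect_equal(wall_shear_rect(ulmin_to_m3s(9.5), 100e-6, 40e-6),
               4.096875, tolerance = 1e-9)
  expect_equal(wall_shear_rect(0, 100e-6, 40e-6), 0)
  expect_equal(wall_shear_rect(2e-10, 100e-6, 40e-6),
               2 * wall_shear_rect(1e-10, 100e-6, 40e-6))
})

test_that("chamber shear map is symmetric, monotone and vanishes at rest", {
  g <- make_preset("40-2")
  sol <- solve_perfusion(g, ulmin_to_m3s(5))
  sm <- chamber_shear_map(sol, g)
  s1 <- sm$tau_cell[sm$series == 1]
  s2 <- sm$tau_cell[sm$series == 2]
  expect_lt(max(abs(s1 - s2)) / max(s1), 1e-9)
  # strictly increasing global max over a decade of flows
  taus <- vapply(c(0.1, 0.5, 1, 5, 10), function(q) {
    attr(chamber_shear_map(solve_perfusion(g, ulmin_to_m3s(q)), g),
         "tau_max_global")
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  sm0 <- chamber_shear_map(solve_perfusion(g, 0), g)
  expect_equal(sm0$tau_cell, rep(0, nrow(sm0)))
  # mismatched geometry is refused
  expect_error(chamber_shear_map(sol, tiny_geom(3)), "not computed")
})

test_that("slit-mouth shear dominates chamber-bulk shear in these layouts", {
  g <- make_preset("40-2")
  sm <- chamber_shear_map(solve_perfusion(g, ulmin_to_m3s(9.5)), g)
  expect_true(all(sm$tau_slit > 100 * sm$tau_chamber))
})

test_that("pressure disturbances are damped by the capillary resistor", {
  expect_equal(hydrostatic_pressure(10), 974.133, tolerance = 1e-6)
  g <- make_preset("40-2")
  dp <- hydrostatic_pressure(10)
  # baseline without capillary: same pressure step straight at the inlet
  net0 <- set_boundary(build_network(g),
                       fixed_pressure = c(medium_in = dp, medium_out = 0,
                                          cell_in = 0, cell_out = 0))
  ed0 <- solve_network(net0)$edge_flows
  q0 <- max(abs(ed0$flow[ed0$label == "chamber"]))
  netc <- build_network(g, capillary = capillary_spec(25, 20))
  qc <- disturbance_flow(dp, netc)
  expect_lt(qc, q0 / 10)
  # linear in the applied step
  expect_equal(disturbance_flow(2 * dp, netc), 2 * qc, tolerance = 1e-12)
  expect_error(disturbance_flow(dp, build_network(g)), "no external capillary")
})

test_that("loading suction draws flow linearly and monotonically", {
  g252 <- make_preset("25-2")
  net <- build_network(g252)
  expect_equal(loading_flow(0, net), 0)
  q20 <- loading_flow(mbar_to_pa(-20), net)
  q35 <- loading_flow(mbar_to_pa(-35), net)
  expect_gt(q20, 0)  # suction draws flow toward the port
  expect_equal(loading_flow(mbar_to_pa(-40), net), 2 * q20,
               tolerance = 1e-12)
  expect_gt(q35, q20)
  # the 40-2 device loads at gentler suction but still flows inward
  expect_gt(loading_flow(mbar_to_pa(-20), build_network(make_preset("40-2"))),
            0)
})
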