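test_that("fast rescale and bisection agree on the shear-limited flow", {
  for (preset in c("25-5", "40-2")) {
    g <- make_preset(preset)
    qf <- max_flow_for_shear(g)
    qb <- max_flow_for_shear(g, method = "bisection")
    expect_lt(abs(qf / qb - 1), 1e-3)
  }
})

test_that("shear-limited flow is exactly linear in the shear ceiling", {
  g <- make_preset("40-2")
  q1 <- max_flow_for_shear(g, tau_max = 0.5)
  expect_equal(max_flow_for_shear(g, tau_max = 1.0), 2 * q1,
               tolerance = 1e-12)
})

test_that("budget concentration floor behaves at its limits", {
  p <- transport_params()
  # permeation alone covers demand: floor saturates
  expect_equal(budget_concentration_floor(0, 4000, p), p$c_sat)
  # no permeation: floor falls with cells and rises with flow
  f1 <- budget_concentration_floor(nlmin_to_m3s(375), 4000, p, 0)
  f2 <- budget_concentration_floor(nlmin_to_m3s(750), 4000, p, 0)
  expect_lt(f1, p$c_sat); expect_lt(f1, f2)
  expect_equal(f1, p$c_sat - 4000 * p$q_cell / nlmin_to_m3s(375),
               tolerance = 1e-12)
})

test_that("oxygen-limited minimum flow reproduces the design findings", {
  g <- make_preset("40-2")
  occ <- uniform_occupancy(100, 40)  # 4000 cells total
  # with PDMS permeation the chip needs no flow for oxygen at all
  q0 <- min_flow_for_oxygen(g, occupancy = occ)
  expect_equal(as.numeric(q0), 0)
  expect_true(attr(q0, "feasible"))
  # permeation disabled: a finite flow below the 375 nl/min operating
  # point already suffices
  q1 <- min_flow_for_oxygen(g, occupancy = occ, pdms = FALSE)
  expect_gt(as.numeric(q1), 0)
  expect_lt(as.numeric(q1), nlmin_to_m3s(375))
  # no cells, no constraint
  expect_equal(as.numeric(min_flow_for_oxygen(g,
    occupancy = uniform_occupancy(0, 40))), 0)
})

test_that("solver-based minimum flow agrees with the PDMS finding", {
  g <- tiny_geom(3)
  occ <- uniform_occupancy(100, 6)
  q <- min_flow_for_oxygen(g, occupancy = occ, method = "solver",
                           resolution = 6)
  expect_equal(as.numeric(q), 0)
  expect_true(attr(q, "feasible"))
})

test_that("oxygen sufficiency is insensitive to Km across a 10x range", {
  g <- tiny_geom(2)
  sol <- solve_perfusion(g, nlmin_to_m3s(37.5))
  dom <- assemble_domain(g, sol, uniform_occupancy(100, 4), resolution = 6)
  for (km in 0.005 * c(1 / sqrt(10), sqrt(10))) {
    p <- transport_params(Km = km)
    expect_true(oxygen_sufficient(steady_state(dom, p)))
  }
})

test_that("flow window composes the two constraints exactly", {
  g <- make_preset("40-2")
  occ <- uniform_occupancy(100, 40)
  p <- transport_params()
  cons <- design_constraints(p)
  w <- flow_window(g, params = p, occupancy = occ, constraints = cons)
  expect_s3_class(w, "flow_window")
  expect_equal(w$q_max, max_flow_for_shear(g, tau_max = cons$tau_max))
  expect_equal(w$q_min,
               as.numeric(min_flow_for_oxygen(g, p, occ,
                                              cons$hypoxia_threshold)))
  expect_true(w$feasible)
  expect_identical(w$binding_constraint_low, "none")
  expect_identical(w$binding_constraint_high, "shear")
  # the documented operating point sits inside the window
  expect_true(w$q_min <= nlmin_to_m3s(375) && nlmin_to_m3s(375) <= w$q_max)
})

test_that("incompatible constraints yield a structured empty window", {
  g <- make_preset("40-2")
  occ <- uniform_occupancy(100, 40)
  p <- transport_params(D_pdms = 0)  # gas-blocked ceiling forces q_min > 0
  cons <- design_constraints(p, tau_max = 1e-6)
  w <- flow_window(g, params = p, occupancy = occ, constraints = cons)
  expect_false(w$feasible)
  expect_gt(w$q_min, w$q_max)
  expect_identical(w$binding_constraint_low, "oxygen")
})

test_that("capillary catalogue is strictly ordered and selected correctly", {
  R <- vapply(list(capillary_spec(50, 10), capillary_spec(50, 20),
                   capillary_spec(25, 10), capillary_spec(25, 20)),
              circular_capillary_resistance, numeric(1))
  expect_true(all(diff(R) > 0))  # (50,10) < (50,20) < (25,10) < (25,20)
  g <- make_preset("40-2")
  # loose budget: least resistive tube wins
  loose <- design_constraints(max_disturbance_chamber_flow = 1e-6)
  sel <- select_capillary(geom = g, constraints = loose)
  expect_equal(m_to_um(sel$diameter), 50)
  expect_equal(sel$length, 0.10)
  # tight budget: nothing passes, most resistive returned with a flag
  tight <- design_constraints(max_disturbance_chamber_flow = 1e-22)
  sel2 <- suppressWarnings(select_capillary(geom = g, constraints = tight))
  expect_equal(m_to_um(sel2$diameter), 25)
  expect_equal(sel2$length, 0.20)
  expect_false(attr(sel2, "feasible"))
})

test_that("capillary selection is invariant under catalogue permutation", {
  g <- make_preset("40-2")
  cons <- design_constraints()
  cat0 <- default_capillary_catalog()
  base <- select_capillary(cat0, g, cons)
  for (seed in 1:3) {
    set.seed(seed)
    sel <- select_capillary(sample(cat0), g, cons)
    expect_equal(sel$diameter, base$diameter)
    expect_equal(sel$length, base$length)
  }
})

test_that("design report is deterministic and serialises byte-identically", {
  g <- make_preset("40-2")
  r1 <- design_report(g)
  r2 <- design_report(g)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_design_report(r1, f1); write_design_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(r1$window$operating_in_window)
  expect_gt(r1$oxygen$supply_ratio, 1)
})
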