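test_that("uniform saturation is the exact solution without sinks", {
  g <- tiny_geom(2)
  sol <- solve_perfusion(g, nlmin_to_m3s(50))
  dom <- assemble_domain(g, sol, uniform_occupancy(0, 4), resolution = 4)
  p <- transport_params(D_pdms = 0)
  f <- steady_state(dom, p)
  expect_lt(max(abs(f$concentration - p$c_sat), na.rm = TRUE), 1e-10)
  expect_equal(min_cell_zone_concentration(f), p$c_sat, tolerance = 1e-10)
})

test_that("zeroth-order uptake limit reproduces the parabolic slab profile", {
  n <- 200; L <- 200e-6; h <- 40e-6; rho <- 2e10; c0 <- 0.2
  dom <- slab_domain(n, L, h, rho, c0)
  p <- transport_params(Km = 1e-9, D_pdms = 0)  # c >> Km everywhere
  f <- steady_state(dom, p)
  x <- (seq_len(n) - 0.5) * L / n
  ana <- c0 - rho * p$q_cell / (2 * p$D_medium * h) * x * (2 * L - x)
  drop <- c0 - min(ana)
  expect_lt(max(abs(f$concentration[, 1] - ana)) / drop, 0.02)
})

test_that("first-order uptake limit reproduces the cosh slab profile", {
  n <- 200; L <- 200e-6; h <- 40e-6; rho <- 1.9e10; c0 <- 1e-4
  dom <- slab_domain(n, L, h, rho, c0)
  p <- transport_params(Km = 0.05, D_pdms = 0)  # c << Km everywhere
  f <- steady_state(dom, p)
  x <- (seq_len(n) - 0.5) * L / n
  kap <- sqrt(rho * p$q_cell / (p$Km * p$D_medium * h))
  ana <- c0 * cosh(kap * (L - x)) / cosh(kap * L)
  expect_gt(kap * L, 2)  # genuinely reaction-dominated
  expect_lt(max(abs(f$concentration[, 1] - ana)) / c0, 0.02)
})

test_that("assembled chip domains are conservative and correctly labelled", {
  g <- tiny_geom(3)
  sol <- solve_perfusion(g, nlmin_to_m3s(56))
  occ <- draw_occupancy("proliferative", 6, seed = 11)
  dom <- assemble_domain(g, sol, occ, resolution = 4)
  # labels partition: chambers carry cells, channel does not
  expect_true(all(dom$rho[dom$region == "chamber" & !is.na(dom$region)] > 0))
  expect_true(all(dom$rho[dom$region == "medium" & !is.na(dom$region)] == 0))
  # seeded cells conserved exactly on the grid
  expect_equal(domain_cell_total(dom), sum(occ$counts[1:3]),
               tolerance = 1e-12)
  # interpolated face fluxes are divergence-free cell by cell
  expect_lt(domain_divergence(dom), 1e-12)
  # refining the grid scales the cell count quadratically
  dom2 <- assemble_domain(g, sol, occ, resolution = 2)
  expect_equal(dom2$nx * dom2$ny / (dom$nx * dom$ny), 4, tolerance = 0.1)
  # too-coarse grids are refused with a suggestion
  expect_error(assemble_domain(g, sol, occ, resolution = 25),
               "too coarse.*18")
})

test_that("converged fields are bounded and close the mass balance", {
  g <- tiny_geom(3)
  sol <- solve_perfusion(g, nlmin_to_m3s(56))
  dom <- assemble_domain(g, sol, uniform_occupancy(100, 6), resolution = 4)
  p <- transport_params()
  f <- steady_state(dom, p)
  expect_true(all(f$concentration >= -1e-12, na.rm = TRUE))
  expect_true(all(f$concentration <= p$c_sat + 1e-12, na.rm = TRUE))
  mb <- oxygen_mass_balance(f)
  expect_lt(abs(mb$imbalance_rel), 1e-6)
  expect_gt(mb$uptake, 0)
})

test_that("halving the resolution moves the chamber minimum by under 2%", {
  g <- tiny_geom(3)
  sol <- solve_perfusion(g, nlmin_to_m3s(56))
  occ <- uniform_occupancy(100, 6)
  m8 <- min_cell_zone_concentration(
    steady_state(assemble_domain(g, sol, occ, resolution = 8)))
  m4 <- min_cell_zone_concentration(
    steady_state(assemble_domain(g, sol, occ, resolution = 4)))
  expect_lt(abs(m4 - m8) / m4, 0.02)
})

test_that("chamber minimum responds monotonically to demand and supply", {
  g <- tiny_geom(2)
  occ <- uniform_occupancy(100, 4)
  minc <- function(q_cell_scale, flow_nl) {
    p <- transport_params()
    p$q_cell <- p$q_cell * q_cell_scale
    sol <- solve_perfusion(g, nlmin_to_m3s(flow_nl))
    min_cell_zone_concentration(steady_state(assemble_domain(g, sol, occ,
                                                             resolution = 6),
                                             p))
  }
  by_demand <- vapply(c(0.5, 1, 2), minc, numeric(1), flow_nl = 37.5)
  expect_true(all(diff(by_demand) < 0))
  by_flow <- vapply(c(4, 400, 4000), function(q) minc(1, q), numeric(1))
  expect_true(all(diff(by_flow) >= -1e-12))
})

test_that("analytic oxygen budget matches hand arithmetic", {
  # convective supply only, at the documented operating point
  expect_equal(oxygen_budget(nlmin_to_m3s(375), 4000, pdms_window_area = 0),
               6.25, tolerance = 1e-12)
  expect_identical(oxygen_budget(nlmin_to_m3s(375), 0), Inf)
  # linear in flow when permeation is off
  expect_equal(oxygen_budget(nlmin_to_m3s(750), 4000, pdms_window_area = 0),
               12.5, tolerance = 1e-12)
  # permeation through the chamber ceilings covers the full demand alone
  expect_gt(oxygen_budget(0, 4000), 1)
})
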