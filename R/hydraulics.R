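# Lumped-parameter (Kirchhoff) hydraulics of the chip. At the chip's
# Reynolds numbers (Re << 1, creeping flow) every duct is a linear
# resistor, so the whole device reduces to a resistance network solved by
# nodal analysis, exactly as an electrical circuit.

#' Fluid properties
#'
#' Defaults are water at 37 degC, the perfusion condition of the device.
#'
#' @param viscosity dynamic viscosity, Pa s.
#' @param density density, kg/m^3.
#' @return an object of class `fluid_props`.
#' @export
fluid_props <- function(viscosity = 6.9e-4, density = 993) {
  stopifnot_positive(viscosity, density)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_props")
}

#' Hydraulic resistance of a rectangular duct
#'
#' Pressure-driven (Poiseuille) resistance `R = dP/Q` of a straight duct of
#' rectangular cross-section `width x height` and length `length`. The
#' default `"series"` method evaluates the exact Fourier-series solution
#' (truncated when converged to machine precision); `"approx"` is the
#' common one-term closed form `12 mu L / (w h^3 (1 - 0.63 h/w))`, accurate
#' to better than 0.3% for aspect ratios `h/w <= 0.5` but overestimating by
#' ~14% for a square duct. Width and height are interchangeable (swapped
#' internally so that `h <= w`).
#'
#' @param width,height,length duct dimensions, metres.
#' @param fluid a [fluid_props()].
#' @param method `"series"` (exact) or `"approx"` (0.63 closed form).
#' @param nterms odd-term cutoff for the series.
#' @return resistance in Pa s/m^3.
#' @export
#' @examples
#' rect_duct_resistance(100e-6, 40e-6, 150e-6)  # ~2.59e11 Pa s/m^3
rect_duct_resistance <- function(width, height, length, fluid = fluid_props(),
                                 method = c("series", "approx"),
                                 nterms = 301) {
  method <- match.arg(method)
  stopifnot_positive(width, height, length)
  w <- max(width, height); h <- min(width, height)
  mu <- fluid$viscosity
  if (method == "approx") {
    return(12 * mu * length / (w * h^3 * (1 - 0.63 * h / w)))
  }
  n <- seq(1, nterms, by = 2)
  S <- (192 / pi^5) * (h / w) * sum(tanh(n * pi * w / (2 * h)) / n^5)
  12 * mu * length / (w * h^3 * (1 - S))
}

#' External capillary resistor
#'
#' The thin capillary tube inserted between syringe and chip to
#' desensitise the device to pressure disturbances. The catalogue options
#' are 25 or 50 um inner diameter and 10 or 20 cm length.
#'
#' @param diameter inner diameter, um.
#' @param length tube length, cm.
#' @return an object of class `capillary_spec` (SI units).
#' @export
capillary_spec <- function(diameter = 25, length = 20) {
  stopifnot_positive(diameter, length)
  structure(list(diameter = um_to_m(diameter), length = cm_to_m(length)),
            class = "capillary_spec")
}

#' @rdname capillary_spec
#' @export
default_capillary_catalog <- function() {
  list(capillary_spec(50, 10), capillary_spec(50, 20),
       capillary_spec(25, 10), capillary_spec(25, 20))
}

#' Hagen-Poiseuille resistance of a circular capillary
#'
#' `R = 128 mu L / (pi d^4)`.
#'
#' @param cap a [capillary_spec()].
#' @param fluid a [fluid_props()].
#' @return resistance in Pa s/m^3.
#' @export
#' @examples
#' circular_capillary_resistance(capillary_spec(25, 20))  # ~1.44e16
circular_capillary_resistance <- function(cap, fluid = fluid_props()) {
  stopifnot(inherits(cap, "capillary_spec"))
  128 * fluid$viscosity * cap$length / (pi * cap$diameter^4)
}

# Resistance of one slit. Straight slits are a single rectangular duct;
# the discontinuous 90-degree anti-migration design is three rectangular
# ducts in series (entry leg, central channel, exit leg, equal path
# lengths) - at Re << 1 only the resistances matter, corner losses are
# negligible.
single_slit_resistance <- function(slit, fluid = fluid_props()) {
  stopifnot(inherits(slit, "slit_spec"))
  if (slit$style == "straight") {
    return(rect_duct_resistance(slit$width, slit$height, slit$length, fluid))
  }
  leg <- rect_duct_resistance(slit$width, slit$height, slit$length / 3, fluid)
  central <- rect_duct_resistance(slit$central_channel_width,
                                  slit$central_channel_height,
                                  slit$length / 3, fluid)
  2 * leg + central
}

# Parallel array of identical slits on one chamber side.
slit_array_resistance <- function(slit, fluid = fluid_props()) {
  single_slit_resistance(slit, fluid) / slit$count_per_side
}

#' Build the chip's hydraulic resistance network
#'
#' Reduces the chip to a node-edge resistor graph: per series, the medium
#' and cell channels are discretised into per-chamber segments, and every
#' chamber contributes a series path slit array -> chamber -> slit array
#' bridging its medium-channel junction to its cell-channel junction. The
#' four ports are boundary nodes (`medium_in`, `medium_out`, `cell_in`,
#' `cell_out`); the two chamber series hang on parallel channel branches
#' between the shared ports. An optional external capillary resistor adds
#' a `syringe` node ahead of `medium_in`.
#'
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_props()].
#' @param capillary optional [capillary_spec()].
#' @return an object of class `hydraulic_network` with `nodes` and `edges`
#'   data frames; boundary kinds are assigned later by [set_boundary()].
#' @export
build_network <- function(geom, fluid = fluid_props(), capillary = NULL) {
  stopifnot(inherits(geom, "device_geometry"))
  if (geom$slit$count_per_side < 1) stop("zero slit count", call. = FALSE)
  nser <- geom$chamber$series_count
  ncham <- geom$chamber$count_per_series

  R_med <- rect_duct_resistance(geom$medium_channel$width,
                                geom$medium_channel$height,
                                geom$medium_channel$segment_length, fluid)
  R_cell <- rect_duct_resistance(geom$cell_channel$width,
                                 geom$cell_channel$height,
                                 geom$cell_channel$segment_length, fluid)
  R_arr <- slit_array_resistance(geom$slit, fluid)
  R_ch <- rect_duct_resistance(geom$chamber$width, geom$chamber$height,
                               geom$chamber$length, fluid)

  nodes <- c("medium_in", "medium_out", "cell_in", "cell_out")
  from <- character(0); to <- character(0); R <- numeric(0)
  label <- character(0); series <- integer(0); chamber <- integer(0)
  add_edge <- function(a, b, r, lab, s = NA_integer_, ch = NA_integer_) {
    from <<- c(from, a); to <<- c(to, b); R <<- c(R, r)
    label <<- c(label, lab); series <<- c(series, s); chamber <<- c(chamber, ch)
  }
  for (s in seq_len(nser)) {
    m <- sprintf("m_%d_%d", s, seq_len(ncham))
    cc <- sprintf("c_%d_%d", s, seq_len(ncham))
    a <- sprintf("a_%d_%d", s, seq_len(ncham))
    b <- sprintf("b_%d_%d", s, seq_len(ncham))
    nodes <- c(nodes, m, cc, a, b)
    mpath <- c("medium_in", m, "medium_out")
    cpath <- c("cell_in", cc, "cell_out")
    for (j in seq_len(ncham + 1)) {
      add_edge(mpath[j], mpath[j + 1], R_med, "medium_segment", s)
      add_edge(cpath[j], cpath[j + 1], R_cell, "cell_segment", s)
    }
    for (j in seq_len(ncham)) {
      add_edge(m[j], a[j], R_arr, "slit_array", s, j)
      add_edge(a[j], b[j], R_ch, "chamber", s, j)
      add_edge(b[j], cc[j], R_arr, "slit_array", s, j)
    }
  }
  if (!is.null(capillary)) {
    stopifnot(inherits(capillary, "capillary_spec"))
    nodes <- c(nodes, "syringe")
    add_edge("syringe", "medium_in",
             circular_capillary_resistance(capillary, fluid), "capillary")
  }
  structure(list(
    nodes = data.frame(id = nodes, kind = "interior", value = 0,
                       stringsAsFactors = FALSE),
    edges = data.frame(id = seq_along(from), from = from, to = to,
                       resistance = R, label = label, series = series,
                       chamber = chamber, stringsAsFactors = FALSE),
    geom_name = geom$name, n_series = nser, n_chambers = ncham,
    has_capillary = !is.null(capillary)
  ), class = "hydraulic_network")
}

#' Assign boundary conditions to a network
#'
#' Marks nodes as `fixed_pressure` (gauge pressure in Pa) or `fixed_flow`
#' (net injected flow in m^3/s, positive into the network); all other
#' nodes remain interior mass-conservation nodes. At least one
#' `fixed_pressure` node is required to gauge the system.
#'
#' @param net a [build_network()] result.
#' @param fixed_flow,fixed_pressure named numeric vectors keyed by node id.
#' @return the network with boundary kinds assigned.
#' @export
set_boundary <- function(net, fixed_flow = NULL, fixed_pressure = NULL) {
  stopifnot(inherits(net, "hydraulic_network"))
  nd <- net$nodes
  nd$kind <- "interior"; nd$value <- 0
  for (nm in names(fixed_flow)) {
    i <- match(nm, nd$id)
    if (is.na(i)) stop(sprintf("unknown node '%s'", nm), call. = FALSE)
    nd$kind[i] <- "fixed_flow"; nd$value[i] <- fixed_flow[[nm]]
  }
  for (nm in names(fixed_pressure)) {
    i <- match(nm, nd$id)
    if (is.na(i)) stop(sprintf("unknown node '%s'", nm), call. = FALSE)
    if (nd$kind[i] != "interior") {
      stop(sprintf("node '%s' given two boundary conditions", nm),
           call. = FALSE)
    }
    nd$kind[i] <- "fixed_pressure"; nd$value[i] <- fixed_pressure[[nm]]
  }
  if (!any(nd$kind == "fixed_pressure")) {
    stop("at least one fixed_pressure node is required as gauge",
         call. = FALSE)
  }
  net$nodes <- nd
  net
}

#' Perfusion boundary conditions
#'
#' The standard operating condition: a flow rate imposed at the medium
#' inlet (at the syringe if an external capillary is present) and 0 Pa
#' gauge at the three other ports.
#'
#' @param net a [build_network()] result.
#' @param inlet_flow imposed flow, m^3/s.
#' @return the network with boundary kinds assigned.
#' @export
perfusion_bc <- function(net, inlet_flow) {
  inlet <- if (net$has_capillary) "syringe" else "medium_in"
  fp <- c(medium_out = 0, cell_in = 0, cell_out = 0)
  set_boundary(net, fixed_flow = stats::setNames(inlet_flow, inlet),
               fixed_pressure = fp)
}

#' Solve a hydraulic network
#'
#' Nodal analysis: conservation of flow at every non-fixed-pressure node
#' gives a sparse linear system in the nodal pressures, solved directly.
#' The solution is independent of node ordering; a floating subgraph (no
#' path to any fixed-pressure node) is reported as an error naming the
#' disconnected nodes.
#'
#' @param net a network with boundary conditions ([set_boundary()] /
#'   [perfusion_bc()]).
#' @return an object of class `flow_solution`: `node_pressures` (Pa, named),
#'   `edge_flows` (the edge table with a signed `flow` column, positive
#'   from -> to), and `inlet_flow` (total imposed flow, m^3/s).
#' @export
solve_network <- function(net) {
  stopifnot(inherits(net, "hydraulic_network"))
  nd <- net$nodes; ed <- net$edges
  if (!any(nd$kind == "fixed_pressure")) {
    stop("boundary conditions not set; see set_boundary()/perfusion_bc()",
         call. = FALSE)
  }
  if (any(ed$resistance <= 0)) stop("all edge resistances must be > 0",
                                    call. = FALSE)
  # connectivity: every node must reach a fixed-pressure node
  adj <- split(c(ed$to, ed$from), c(ed$from, ed$to))
  reached <- nd$id[nd$kind == "fixed_pressure"]
  frontier <- reached
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), reached)
    reached <- c(reached, nxt); frontier <- nxt
  }
  floating <- setdiff(nd$id, reached)
  if (length(floating)) {
    stop(sprintf("singular system: nodes not connected to any fixed-pressure node: %s",
                 paste(floating, collapse = ", ")), call. = FALSE)
  }

  free <- nd$id[nd$kind != "fixed_pressure"]
  fixedP <- stats::setNames(nd$value[nd$kind == "fixed_pressure"],
                            nd$id[nd$kind == "fixed_pressure"])
  g <- 1 / ed$resistance
  ia <- match(ed$from, free); ib <- match(ed$to, free)
  n <- length(free)
  b <- stats::setNames(rep(0, n), free)
  inj <- nd$kind == "fixed_flow"
  b[nd$id[inj]] <- nd$value[inj]

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(g)) {
    a <- ia[k]; bb <- ib[k]
    if (!is.na(a)) { ii <- c(ii, a); jj <- c(jj, a); xx <- c(xx, g[k]) }
    if (!is.na(bb)) { ii <- c(ii, bb); jj <- c(jj, bb); xx <- c(xx, g[k]) }
    if (!is.na(a) && !is.na(bb)) {
      ii <- c(ii, a, bb); jj <- c(jj, bb, a); xx <- c(xx, -g[k], -g[k])
    }
    if (!is.na(a) && is.na(bb)) b[a] <- b[a] + g[k] * fixedP[[ed$to[k]]]
    if (is.na(a) && !is.na(bb)) b[bb] <- b[bb] + g[k] * fixedP[[ed$from[k]]]
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  p_free <- as.numeric(Matrix::solve(G, b))
  pressures <- stats::setNames(rep(NA_real_, nrow(nd)), nd$id)
  pressures[free] <- p_free
  pressures[names(fixedP)] <- fixedP

  ed$flow <- (pressures[ed$from] - pressures[ed$to]) / ed$resistance
  inlet_flow <- sum(nd$value[inj])
  structure(list(node_pressures = pressures, edge_flows = ed,
                 inlet_flow = inlet_flow, network = net),
            class = "flow_solution")
}

#' One-call perfusion solve
#'
#' Convenience wrapper: build the network for a geometry, apply perfusion
#' boundary conditions and solve.
#'
#' @param geom a [device_geometry()].
#' @param inlet_flow imposed medium flow, m^3/s (see [ulmin_to_m3s()]).
#' @param fluid a [fluid_props()].
#' @param capillary optional [capillary_spec()].
#' @return a `flow_solution`.
#' @export
solve_perfusion <- function(geom, inlet_flow, fluid = fluid_props(),
                            capillary = NULL) {
  net <- build_network(geom, fluid, capillary)
  solve_network(perfusion_bc(net, inlet_flow))
}

#' Worst node imbalance of a solved network
#'
#' Maximum absolute net flow at interior nodes, relative to the inlet flow
#' (or to the largest edge flow when no flow was imposed). A correct
#' solution is conservative to near machine precision.
#'
#' @param sol a `flow_solution`.
#' @return dimensionless relative imbalance.
#' @export
max_node_imbalance <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  nd <- sol$network$nodes; ed <- sol$edge_flows
  interior <- nd$id[nd$kind == "interior"]
  outflow <- tapply(c(ed$flow, -ed$flow), c(ed$from, ed$to), sum)
  imb <- max(abs(outflow[interior]), 0)
  scale <- if (abs(sol$inlet_flow) > 0) abs(sol$inlet_flow)
    else max(abs(ed$flow))
  if (scale == 0) 0 else imb / scale
}

#' Wall shear stress between parallel plates
#'
#' Depth-mean wall shear of pressure-driven flow between plates:
#' `tau = 6 mu Q / (w h^2)`, with `h` the plate gap (duct height, the
#' dimension across which cells feel the gradient) and `w` the span. Used
#' as the local shear estimate in channels, chambers and slit mouths.
#'
#' @param flow volumetric flow through the duct, m^3/s.
#' @param width duct span, metres.
#' @param height plate gap, metres.
#' @param fluid a [fluid_props()].
#' @return shear stress, Pa.
#' @export
#' @examples
#' wall_shear_rect(ulmin_to_m3s(9.5), 100e-6, 40e-6)  # ~4.1 Pa free channel
wall_shear_rect <- function(flow, width, height, fluid = fluid_props()) {
  stopifnot_positive(width, height)
  6 * fluid$viscosity * flow / (width * height^2)
}

#' Per-chamber shear stress map
#'
#' For every chamber of a solved perfusion network, the through-flow and
#' two shear estimates at cell positions: `tau_chamber`, the parallel-plate
#' shear on the chamber floor/ceiling from the chamber through-flow, and
#' `tau_slit`, the shear inside one slit of the array (through-flow divided
#' over the slits; for discontinuous slits the maximum over legs and
#' central channel). The binding value `tau_cell = max(tau_chamber,
#' tau_slit)` is the shear the most exposed cells see; the attribute
#' `tau_max_global` is its maximum over chambers.
#'
#' @param sol a `flow_solution` from [solve_perfusion()].
#' @param geom the [device_geometry()] the network was built from.
#' @param fluid a [fluid_props()].
#' @return data frame (series, chamber, flow, tau_chamber, tau_slit,
#'   tau_cell) with attribute `tau_max_global`.
#' @export
chamber_shear_map <- function(sol, geom, fluid = fluid_props()) {
  stopifnot(inherits(sol, "flow_solution"), inherits(geom, "device_geometry"))
  net <- sol$network
  if (net$n_series != geom$chamber$series_count ||
      net$n_chambers != geom$chamber$count_per_series ||
      !identical(net$geom_name, geom$name)) {
    stop("solution was not computed for this geometry", call. = FALSE)
  }
  ed <- sol$edge_flows
  ch <- ed[ed$label == "chamber", ]
  q <- abs(ch$flow)
  tau_chamber <- wall_shear_rect(q, geom$chamber$width, geom$chamber$height,
                                 fluid)
  sl <- geom$slit
  q_slit <- q / sl$count_per_side
  tau_slit <- wall_shear_rect(q_slit, sl$width, sl$height, fluid)
  if (sl$style == "discontinuous_90") {
    tau_slit <- pmax(tau_slit,
                     wall_shear_rect(q_slit, sl$central_channel_width,
                                     sl$central_channel_height, fluid))
  }
  out <- data.frame(series = ch$series, chamber = ch$chamber, flow = q,
                    tau_chamber = tau_chamber, tau_slit = tau_slit,
                    tau_cell = pmax(tau_chamber, tau_slit))
  out <- out[order(out$series, out$chamber), ]
  rownames(out) <- NULL
  attr(out, "tau_max_global") <- max(out$tau_cell)
  out
}

#' Hydrostatic pressure of a liquid head
#'
#' `dP = rho g dh`, the disturbance produced by repositioning the syringe
#' relative to the chip.
#'
#' @param delta_h height difference, cm.
#' @param fluid a [fluid_props()].
#' @return pressure, Pa.
#' @export
#' @examples
#' hydrostatic_pressure(10)  # ~974 Pa for a 10 cm head
hydrostatic_pressure <- function(delta_h, fluid = fluid_props()) {
  fluid$density * .g0 * cm_to_m(delta_h)
}

#' Chamber flow induced by a pressure disturbance
#'
#' Applies a quasi-static pressure step at the syringe node of a network
#' fitted with the external capillary resistor (0 Pa at the three ports)
#' and returns the peak chamber through-flow it induces - the flux that,
#' unchecked, flushes cells out of the chambers. Requires the capillary
#' edge; a network without one is exactly the failure mode the resistor
#' was introduced to fix.
#'
#' @param delta_p pressure step at the syringe, Pa (see
#'   [hydrostatic_pressure()]).
#' @param net_with_capillary a network built with a [capillary_spec()].
#' @return peak chamber through-flow, m^3/s.
#' @export
disturbance_flow <- function(delta_p, net_with_capillary) {
  net <- net_with_capillary
  stopifnot(inherits(net, "hydraulic_network"))
  if (!net$has_capillary) {
    stop("network has no external capillary edge; add one with build_network(..., capillary = )",
         call. = FALSE)
  }
  net <- set_boundary(net,
                      fixed_pressure = c(syringe = delta_p, medium_out = 0,
                                         cell_in = 0, cell_out = 0))
  sol <- solve_network(net)
  ed <- sol$edge_flows
  max(abs(ed$flow[ed$label == "chamber"]))
}

#' Cell-channel flow during suction loading
#'
#' Applies a gauge suction pressure at one cell-channel port (0 Pa at the
#' other three) and returns the flow drawn through that port. Sign
#' convention: positive for flow drawn out of the chip toward the suction
#' source, i.e. a negative gauge pressure yields a positive loading flow.
#'
#' @param suction gauge pressure at the port, Pa (negative for suction;
#'   see [mbar_to_pa()]).
#' @param net a [build_network()] result.
#' @param port `"cell_out"` (default) or `"cell_in"`.
#' @return signed loading flow, m^3/s.
#' @export
loading_flow <- function(suction, net, port = c("cell_out", "cell_in")) {
  port <- match.arg(port)
  stopifnot(inherits(net, "hydraulic_network"))
  others <- setdiff(c("medium_in", "medium_out", "cell_in", "cell_out",
                      if (net$has_capillary) "syringe"), port)
  fp <- c(stats::setNames(suction, port), stats::setNames(rep(0,
          length(others)), others))
  sol <- solve_network(set_boundary(net, fixed_pressure = fp))
  ed <- sol$edge_flows
  into_port <- sum(ed$flow[ed$to == port]) - sum(ed$flow[ed$from == port])
  into_port
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat(sprintf("<hydraulic_network> %s: %d nodes, %d edges (%d chamber paths)%s\n",
              x$geom_name, nrow(x$nodes), nrow(x$edges),
              x$n_series * x$n_chambers,
              if (x$has_capillary) ", external capillary" else ""))
  invisible(x)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d nodes; inlet flow %.4g ul/min; max node imbalance %.2e\n",
              length(x$node_pressures), m3s_to_ulmin(x$inlet_flow),
              max_node_imbalance(x)))
  invisible(x)
}

#' @export
as.data.frame.flow_solution <- function(x, ...) x$edge_flows
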