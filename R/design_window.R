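# Operating-window analysis: combine the hepatocyte shear ceiling with the
# hypoxia floor into the admissible perfusion-flow interval, and size the
# external capillary resistor that desensitises the chip to pressure
# disturbances.

#' Design constraints
#'
#' The two biological constraints bounding the perfusion flow - the 0.5 Pa
#' shear ceiling tolerated by hepatocytes and the hypoxia floor on the
#' chamber oxygen concentration (default a tenth of saturation) - plus the
#' disturbance budget used for capillary sizing. When
#' `max_disturbance_chamber_flow` is `NULL` it defaults, at the point of
#' use, to the chamber through-flow at normal operation (375 nl/min):
#' disturbances should not exceed nominal perfusion.
#'
#' @param params a [transport_params()] (sets the hypoxia floor scale).
#' @param tau_max maximum acceptable shear stress at cell positions, Pa.
#' @param hypoxia_threshold minimum admissible chamber concentration,
#'   mol/m^3.
#' @param max_disturbance_chamber_flow disturbance budget, m^3/s, or `NULL`.
#' @param design_delta_p design-basis pressure disturbance, Pa (default: a
#'   10 cm hydrostatic head from repositioning the syringe).
#' @return an object of class `design_constraints`.
#' @export
design_constraints <- function(params = transport_params(), tau_max = 0.5,
                               hypoxia_threshold = 0.1 * params$c_sat,
                               max_disturbance_chamber_flow = NULL,
                               design_delta_p = hydrostatic_pressure(10)) {
  stopifnot_positive(tau_max, hypoxia_threshold, design_delta_p)
  if (!is.null(max_disturbance_chamber_flow)) {
    stopifnot_positive(max_disturbance_chamber_flow)
  }
  structure(list(tau_max = tau_max, hypoxia_threshold = hypoxia_threshold,
                 max_disturbance_chamber_flow = max_disturbance_chamber_flow,
                 design_delta_p = design_delta_p),
            class = "design_constraints")
}

#' Shear-limited maximum perfusion flow
#'
#' Largest inlet flow keeping the per-chamber shear at cell positions (the
#' maximum of chamber-bulk and slit-mouth shear, see [chamber_shear_map()])
#' at or below `tau_max`. Because creeping flow is linear, a single solve
#' at a reference flow and a rescale is exact; `method = "bisection"` is
#' the audit path, iterating on re-solves until the peak shear matches
#' `tau_max` to 0.1%. Both agree to the bisection tolerance.
#'
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_props()].
#' @param tau_max shear ceiling, Pa.
#' @param method `"rescale"` (fast, exact by linearity) or `"bisection"`.
#' @return maximum flow, m^3/s.
#' @export
#' @examples
#' m3s_to_ulmin(max_flow_for_shear(make_preset("40-2")))  # ~9.5
max_flow_for_shear <- function(geom, fluid = fluid_props(), tau_max = 0.5,
                               method = c("rescale", "bisection")) {
  method <- match.arg(method)
  stopifnot_positive(tau_max)
  peak_tau <- function(q) {
    sol <- solve_perfusion(geom, q, fluid)
    attr(chamber_shear_map(sol, geom, fluid), "tau_max_global")
  }
  q_ref <- ulmin_to_m3s(1)
  if (method == "rescale") {
    return(q_ref * tau_max / peak_tau(q_ref))
  }
  lo <- 0; hi <- q_ref
  while (peak_tau(hi) < tau_max) { lo <- hi; hi <- 2 * hi }
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    tm <- peak_tau(mid)
    if (abs(tm - tau_max) <= 1e-3 * tau_max) return(mid)
    if (tm < tau_max) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Analytic (well-mixed budget) concentration floor
#'
#' Whole-device mass-balance bound on the chamber concentration: the
#' saturated demand not covered by PDMS permeation must be met by the
#' convective stream, depressing it by `deficit / Q`. Clamped to
#' `[0, c_sat]`.
#'
#' @param inlet_flow perfusion flow, m^3/s.
#' @param total_cells total live cells.
#' @param p a [transport_params()].
#' @param pdms_window_area permeation window, m^2 (0 disables PDMS).
#' @return concentration floor, mol/m^3.
#' @export
budget_concentration_floor <- function(inlet_flow, total_cells,
                                       p = transport_params(),
                                       pdms_window_area =
                                         chamber_ceiling_area_default()) {
  deficit <- total_cells * p$q_cell -
    pdms_window_area * pdms_transfer_coeff(p) * p$ambient_c
  if (deficit <= 0) return(p$c_sat)
  if (inlet_flow <= 0) return(0)
  max(0, min(p$c_sat, p$c_sat - deficit / inlet_flow))
}

#' Oxygen-limited minimum perfusion flow
#'
#' Smallest flow keeping the chamber oxygen above the hypoxia threshold.
#' The default `"budget"` method inverts the analytic well-mixed balance
#' ([budget_concentration_floor()]); it returns 0 whenever PDMS permeation
#' alone covers the saturated demand - the device's central qualitative
#' property. `method = "solver"` scans the 2.5D field solver
#' (log-spaced scan then bisection on [min_cell_zone_concentration()]).
#' Infeasibility at the search ceiling is flagged via the `"feasible"`
#' attribute, not an error.
#'
#' @param geom a [device_geometry()].
#' @param params a [transport_params()].
#' @param occupancy an [draw_occupancy()] result.
#' @param hypoxia_threshold floor concentration, mol/m^3.
#' @param fluid a [fluid_props()] (solver method).
#' @param method `"budget"` or `"solver"`.
#' @param pdms logical; include PDMS permeation.
#' @param q_search_max search ceiling, m^3/s.
#' @param resolution solver grid resolution, um.
#' @return minimum flow, m^3/s, with attributes `feasible` and `method`.
#' @export
min_flow_for_oxygen <- function(geom, params = transport_params(),
                                occupancy = uniform_occupancy(
                                  n_chambers = geom$chamber$count_per_series *
                                    geom$chamber$series_count),
                                hypoxia_threshold = 0.1 * params$c_sat,
                                fluid = fluid_props(),
                                method = c("budget", "solver"),
                                pdms = TRUE,
                                q_search_max = ulmin_to_m3s(20),
                                resolution = 4) {
  method <- match.arg(method)
  N <- sum(occupancy$counts)
  done <- function(q, feasible = TRUE) {
    structure(q, feasible = feasible, method = method)
  }
  if (N == 0) return(done(0))
  if (hypoxia_threshold >= params$c_sat) {
    return(done(q_search_max, feasible = FALSE))
  }
  A <- if (pdms) chamber_ceiling_area(geom) else 0
  if (method == "budget") {
    deficit <- N * params$q_cell -
      A * pdms_transfer_coeff(params) * params$ambient_c
    if (deficit <= 0) return(done(0))
    q <- deficit / (params$c_sat - hypoxia_threshold)
    return(done(q, feasible = q <= q_search_max))
  }
  p <- params
  if (!pdms) p$D_pdms <- 0
  minc_at <- function(q) {
    sol <- solve_perfusion(geom, q, fluid)
    dom <- assemble_domain(geom, sol, occupancy, resolution = resolution)
    min_cell_zone_concentration(steady_state(dom, p))
  }
  if (minc_at(0) >= hypoxia_threshold) return(done(0))
  qs <- exp(seq(log(nlmin_to_m3s(1)), log(q_search_max), length.out = 7))
  hi <- NA; lo <- 0
  for (q in qs) {
    if (minc_at(q) >= hypoxia_threshold) { hi <- q; break }
    lo <- q
  }
  if (is.na(hi)) return(done(q_search_max, feasible = FALSE))
  for (k in 1:12) {
    mid <- sqrt(max(lo, nlmin_to_m3s(0.1)) * hi)
    if (hi / max(lo, nlmin_to_m3s(0.1)) < 1.02) break
    if (minc_at(mid) >= hypoxia_threshold) hi <- mid else lo <- mid
  }
  done(hi)
}

#' Admissible operating-flow window
#'
#' Combines the two constraints: the upper edge is the shear-limited
#' maximum flow, the lower edge the oxygen-limited minimum. The edges are
#' exactly the outputs of [max_flow_for_shear()] and
#' [min_flow_for_oxygen()]. An empty window is reported as an infeasible
#' structured result, not an error.
#'
#' @inheritParams min_flow_for_oxygen
#' @param fluid a [fluid_props()].
#' @param constraints a [design_constraints()].
#' @param oxygen_method passed to [min_flow_for_oxygen()].
#' @return an object of class `flow_window`: `q_min`, `q_max` (m^3/s),
#'   binding constraints and feasibility.
#' @export
#' @examples
#' w <- flow_window(make_preset("40-2"))
#' w$q_min <= nlmin_to_m3s(375) && nlmin_to_m3s(375) <= w$q_max  # TRUE
flow_window <- function(geom, fluid = fluid_props(),
                        params = transport_params(),
                        occupancy = uniform_occupancy(
                          n_chambers = geom$chamber$count_per_series *
                            geom$chamber$series_count),
                        constraints = design_constraints(params),
                        oxygen_method = "budget") {
  q_max <- max_flow_for_shear(geom, fluid, constraints$tau_max)
  q_min <- min_flow_for_oxygen(geom, params, occupancy,
                               constraints$hypoxia_threshold, fluid,
                               method = oxygen_method)
  feasible <- isTRUE(attr(q_min, "feasible")) && as.numeric(q_min) <= q_max
  structure(list(
    q_min = as.numeric(q_min), q_max = q_max,
    binding_constraint_low = if (as.numeric(q_min) > 0) "oxygen" else "none",
    binding_constraint_high = "shear",
    feasible = feasible, geom_name = geom$name,
    tau_max = constraints$tau_max,
    hypoxia_threshold = constraints$hypoxia_threshold
  ), class = "flow_window")
}

#' @export
print.flow_window <- function(x, ...) {
  cat(sprintf("<flow_window> %s: %s\n", x$geom_name,
              if (x$feasible) "feasible" else "EMPTY / infeasible"))
  cat(sprintf("  q_min = %.4g nl/min (binding: %s)\n",
              m3s_to_nlmin(x$q_min), x$binding_constraint_low))
  cat(sprintf("  q_max = %.4g ul/min (binding: %s, tau_max = %g Pa)\n",
              m3s_to_ulmin(x$q_max), x$binding_constraint_high, x$tau_max))
  invisible(x)
}

#' Select the external capillary resistor
#'
#' Picks, from a catalogue of capillary tubes, the least-resistive entry
#' whose induced peak chamber flow under the design-basis pressure
#' disturbance stays within the disturbance budget; ties are broken by
#' shorter length. If no entry is feasible the most resistive one is
#' returned with attribute `feasible = FALSE`. The result is invariant
#' under catalogue permutation.
#'
#' @param catalog list of [capillary_spec()] (default: the four available
#'   tubes, 25/50 um x 10/20 cm).
#' @param geom a [device_geometry()].
#' @param constraints a [design_constraints()]; a `NULL` disturbance
#'   budget defaults to the chamber through-flow at 375 nl/min operation.
#' @param fluid a [fluid_props()].
#' @return the selected [capillary_spec()], with attributes `feasible` and
#'   `disturbance_flow` (m^3/s).
#' @export
select_capillary <- function(catalog = default_capillary_catalog(), geom,
                             constraints = design_constraints(),
                             fluid = fluid_props()) {
  if (!length(catalog)) stop("empty capillary catalog", call. = FALSE)
  limit <- constraints$max_disturbance_chamber_flow
  if (is.null(limit)) {
    sol <- solve_perfusion(geom, nlmin_to_m3s(375), fluid)
    ed <- sol$edge_flows
    limit <- max(abs(ed$flow[ed$label == "chamber"]))
  }
  R <- vapply(catalog, circular_capillary_resistance, numeric(1),
              fluid = fluid)
  len <- vapply(catalog, function(cp) cp$length, numeric(1))
  ord <- order(R, len)
  qd <- rep(NA_real_, length(catalog))
  for (k in ord) {
    net <- build_network(geom, fluid, capillary = catalog[[k]])
    qd[k] <- disturbance_flow(constraints$design_delta_p, net)
    if (qd[k] <= limit) {
      return(structure(catalog[[k]], feasible = TRUE,
                       disturbance_flow = qd[k]))
    }
  }
  worst <- ord[length(ord)]
  warning("no catalog capillary meets the disturbance budget; returning the most resistive")
  structure(catalog[[worst]], feasible = FALSE,
            disturbance_flow = qd[worst])
}

#' Device design report
#'
#' Deterministic JSON-serialisable summary of the design analysis:
#' geometry echo (um units), operating window, capillary selection,
#' oxygen budget at the operating point, and parameter provenance.
#' Identical inputs give byte-identical reports.
#'
#' @inheritParams flow_window
#' @param operating_flow nominal flow, m^3/s.
#' @param catalog capillary catalogue.
#' @return a nested list; serialise with [write_design_report()].
#' @export
design_report <- function(geom, fluid = fluid_props(),
                          params = transport_params(),
                          occupancy = uniform_occupancy(
                            n_chambers = geom$chamber$count_per_series *
                              geom$chamber$series_count),
                          constraints = design_constraints(params),
                          operating_flow = nlmin_to_m3s(375),
                          catalog = default_capillary_catalog()) {
  win <- flow_window(geom, fluid, params, occupancy, constraints)
  cap <- select_capillary(catalog, geom, constraints, fluid)
  list(
    device = geom$name,
    geometry_um = list(
      chamber = list(width = m_to_um(geom$chamber$width),
                     height = m_to_um(geom$chamber$height),
                     length = m_to_um(geom$chamber$length)),
      slit = list(height = m_to_um(geom$slit$height),
                  width = m_to_um(geom$slit$width),
                  length = m_to_um(geom$slit$length),
                  count_per_side = geom$slit$count_per_side),
      medium_channel = list(width = m_to_um(geom$medium_channel$width),
                            segment_length =
                              m_to_um(geom$medium_channel$segment_length))),
    window = list(q_min_nlmin = m3s_to_nlmin(win$q_min),
                  q_max_ulmin = m3s_to_ulmin(win$q_max),
                  feasible = win$feasible,
                  binding_low = win$binding_constraint_low,
                  binding_high = win$binding_constraint_high,
                  operating_flow_nlmin = m3s_to_nlmin(operating_flow),
                  operating_in_window = win$feasible &&
                    operating_flow >= win$q_min & operating_flow <= win$q_max),
    oxygen = list(total_cells = sum(occupancy$counts),
                  supply_ratio = oxygen_budget(operating_flow,
                                               sum(occupancy$counts), params,
                                               chamber_ceiling_area(geom)),
                  hypoxia_threshold = constraints$hypoxia_threshold),
    capillary = list(diameter_um = m_to_um(cap$diameter),
                     length_cm = cap$length * 100,
                     feasible = attr(cap, "feasible"),
                     disturbance_chamber_flow_nlmin =
                       m3s_to_nlmin(attr(cap, "disturbance_flow"))),
    parameters = list(viscosity_Pas = fluid$viscosity,
                      q_cell_mol_s = params$q_cell, Km = params$Km,
                      c_sat = params$c_sat, tau_max_Pa = constraints$tau_max)
  )
}

#' @rdname design_report
#' @param report a [design_report()] result.
#' @param path output file.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
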