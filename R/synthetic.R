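# Seeded generators standing in for experimental inputs: per-chamber
# live-cell occupancy (the published mean +- SD summaries define the
# parent distribution) and log-normal parameter perturbations for
# Monte-Carlo design sensitivity.

.occupancy_scenarios <- list(
  proliferative = c(mean = 69, sd = 26),
  differentiated = c(mean = 52, sd = 23)
)

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw per-chamber live-cell occupancy
#'
#' Generates live-cell counts per chamber from a zero-truncated Normal
#' parent rounded to integers. The parent moments are the published
#' per-scenario summaries: mean 69, SD 26 for chips loaded with
#' proliferative cells and mean 52, SD 23 for already differentiated
#' cells. Truncation is by censoring (negative draws become empty
#' chambers), which keeps the large-sample mean within
#' `sigma * dnorm(mu/sigma) - mu * pnorm(-mu/sigma)` (< 0.1 cells here) of
#' the stated mean; [occupancy_parent_mean()] is the closed-form oracle
#' for the censored parent. Identical `(scenario, n_chambers, seed)` give
#' bit-identical draws and the global RNG state is left untouched.
#'
#' @param scenario `"proliferative"` or `"differentiated"`.
#' @param n_chambers number of chambers to draw (default 40 = 2 series
#'   of 20).
#' @param seed integer seed.
#' @return an object of class `occupancy_draw` with integer `counts`,
#'   `scenario` and `seed`.
#' @export
#' @examples
#' occ <- draw_occupancy("proliferative", seed = 1)
#' mean(occ$counts)
draw_occupancy <- function(scenario = c("proliferative", "differentiated"),
                           n_chambers = 40, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_chambers < 1) stop("'n_chambers' must be >= 1", call. = FALSE)
  par <- .occupancy_scenarios[[scenario]]
  counts <- with_seed(seed, {
    round(pmax(stats::rnorm(n_chambers, par[["mean"]], par[["sd"]]), 0))
  })
  structure(list(counts = as.integer(counts), scenario = scenario,
                 seed = as.integer(seed)),
            class = "occupancy_draw")
}

#' Exact mean of the censored occupancy parent
#'
#' `E[max(X, 0)] = mu * pnorm(mu/sigma) + sigma * dnorm(mu/sigma)` for
#' `X ~ Normal(mu, sigma)` - the large-sample target of
#' [draw_occupancy()] before rounding.
#'
#' @param scenario occupancy scenario name.
#' @return expected cells per chamber.
#' @export
occupancy_parent_mean <- function(scenario = c("proliferative",
                                               "differentiated")) {
  scenario <- match.arg(scenario)
  par <- .occupancy_scenarios[[scenario]]
  m <- par[["mean"]]; s <- par[["sd"]]
  m * stats::pnorm(m / s) + s * stats::dnorm(m / s)
}

#' Uniform occupancy
#'
#' Deterministic occupancy with the same count in every chamber - the
#' configuration used for nominal design calculations (e.g. 100 cells per
#' chamber for a 4000-cell device).
#'
#' @param cells_per_chamber live cells per chamber.
#' @param n_chambers number of chambers.
#' @return an `occupancy_draw`.
#' @export
uniform_occupancy <- function(cells_per_chamber = 100, n_chambers = 40) {
  structure(list(counts = as.integer(rep(cells_per_chamber, n_chambers)),
                 scenario = "uniform", seed = NA_integer_),
            class = "occupancy_draw")
}

#' @export
print.occupancy_draw <- function(x, ...) {
  cat(sprintf("<occupancy_draw> %s: %d chambers, mean %.1f cells (sd %.1f), total %d\n",
              x$scenario, length(x$counts), mean(x$counts),
              stats::sd(x$counts), sum(x$counts)))
  invisible(x)
}

#' Draw log-normal parameter perturbations
#'
#' Seeded multiplicative perturbations for design-sensitivity runs: each
#' draw perturbs viscosity, medium diffusivity, per-cell consumption, the
#' Michaelis constant and the medium-channel width by independent
#' log-normal factors with median 1 (meanlog 0). Default dispersions
#' reflect how well each quantity is controlled: fabrication and fluid
#' properties tightly (sdlog 0.05), diffusivity moderately (0.1), cell
#' metabolism loosely (0.2).
#'
#' @param n number of draws.
#' @param sdlog named numeric vector of log-scale dispersions for
#'   `viscosity`, `D_medium`, `q_cell`, `Km`, `channel_width` (zero allowed:
#'   degenerate, all multipliers 1).
#' @param seed integer seed.
#' @return an object of class `perturbation_set` with the `n x 5`
#'   multiplier matrix `draws`.
#' @export
draw_perturbations <- function(n = 100,
                               sdlog = c(viscosity = 0.05, D_medium = 0.1,
                                         q_cell = 0.2, Km = 0.2,
                                         channel_width = 0.05),
                               seed = 1) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  nms <- c("viscosity", "D_medium", "q_cell", "Km", "channel_width")
  if (!all(nms %in% names(sdlog))) {
    stop("'sdlog' must name all of: ", paste(nms, collapse = ", "),
         call. = FALSE)
  }
  if (any(sdlog < 0)) stop("dispersions must be >= 0", call. = FALSE)
  draws <- with_seed(seed, {
    m <- vapply(nms, function(k) stats::rlnorm(n, 0, sdlog[[k]]), numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, nms))
  })
  structure(list(draws = draws, seed = as.integer(seed), n = as.integer(n),
                 sdlog = sdlog[nms]),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat(sprintf("<perturbation_set> %d draws, seed %d; sdlog: %s\n", x$n,
              x$seed, paste(sprintf("%s=%.2g", colnames(x$draws),
                                    x$sdlog), collapse = ", ")))
  invisible(x)
}

#' Monte-Carlo design sensitivity
#'
#' Re-runs the design-window pipeline for each perturbation draw: the
#' shear-limited maximum flow, the oxygen-limited minimum flow (analytic
#' budget) and the budget concentration floor at the nominal operating
#' flow. Individual draw failures are flagged row-wise and the run
#' continues.
#'
#' @param geom a [device_geometry()].
#' @param perturbations a [draw_perturbations()] result.
#' @param occupancy an [draw_occupancy()] result.
#' @param fluid a [fluid_props()].
#' @param params a [transport_params()].
#' @param constraints a [design_constraints()].
#' @param operating_flow nominal perfusion flow, m^3/s (default
#'   375 nl/min).
#' @return data frame (draw, q_max, q_min, min_o2, ok) with flows in
#'   m^3/s and `min_o2` in mol/m^3; summary quantiles in attribute
#'   `"quantiles"`.
#' @export
run_sensitivity <- function(geom, perturbations, occupancy,
                            fluid = fluid_props(),
                            params = transport_params(),
                            constraints = design_constraints(params),
                            operating_flow = nlmin_to_m3s(375)) {
  stopifnot(inherits(perturbations, "perturbation_set"))
  m <- perturbations$draws
  n <- nrow(m)
  out <- data.frame(draw = seq_len(n), q_max = NA_real_, q_min = NA_real_,
                    min_o2 = NA_real_, ok = FALSE)
  for (k in seq_len(n)) {
    res <- try({
      fl <- fluid_props(viscosity = fluid$viscosity * m[k, "viscosity"],
                        density = fluid$density)
      g <- geom
      g$medium_channel$width <- geom$medium_channel$width *
        m[k, "channel_width"]
      pp <- params
      pp$D_medium <- params$D_medium * m[k, "D_medium"]
      pp$q_cell <- params$q_cell * m[k, "q_cell"]
      pp$Km <- params$Km * m[k, "Km"]
      qmax <- max_flow_for_shear(g, fl, constraints$tau_max)
      qmin <- min_flow_for_oxygen(g, pp, occupancy,
                                  constraints$hypoxia_threshold)
      floorc <- budget_concentration_floor(operating_flow,
                                           sum(occupancy$counts), pp,
                                           chamber_ceiling_area(g))
      out[k, c("q_max", "q_min", "min_o2")] <- c(qmax, qmin, floorc)
      out$ok[k] <- TRUE
    }, silent = TRUE)
    if (inherits(res, "try-error")) out$ok[k] <- FALSE
  }
  qs <- apply(out[out$ok, c("q_max", "q_min", "min_o2"), drop = FALSE], 2,
              stats::quantile, probs = c(0.05, 0.5, 0.95), na.rm = TRUE)
  attr(out, "quantiles") <- qs
  out
}
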