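# Depth-averaged (2.5D) steady oxygen transport. The chip is reduced to a
# structured 2D grid carrying, per cell, the local conveyance height, a
# conservative face-flux field interpolated from the solved hydraulic
# network, and a hepatocyte surface density. Oxygen obeys
#   div(h D grad c) - div(h u c) - rho q c/(Km + c) + k_pdms (c_amb - c) = 0
# with upwind convection, Michaelis-Menten uptake handled by Picard
# iteration, and permeation through the gas-permeable ceiling as a linear
# per-area membrane flux.

#' Oxygen transport parameters
#'
#' Physical constants for the oxygen model. `q_cell` is the per-cell
#' consumption rate (5e-17 mol/s/cell); Michaelis-Menten kinetics
#' `q_cell * c / (Km + c)` describe uptake. PDMS permeation is modelled as
#' a membrane flux `k (ambient_c - c)` per unit ceiling area with
#' `k = partition_pdms * D_pdms / pdms_thickness` - the partition
#' coefficient scales the membrane permeability, so the zero-flux
#' equilibrium remains `c = ambient_c`. `D_tissue` replaces the medium
#' diffusivity inside tissue-loaded chambers (defaults to `D_medium`);
#' set `D_pdms = 0` for an impermeable (gas-blocked) ceiling.
#'
#' @param D_medium oxygen diffusivity in medium, m^2/s.
#' @param D_pdms oxygen diffusivity in PDMS, m^2/s (0 allowed).
#' @param D_tissue effective diffusivity in tissue-loaded chambers, m^2/s;
#'   `NULL` means `D_medium`.
#' @param c_sat inlet/air-equilibrated concentration, mol/m^3.
#' @param partition_pdms PDMS/medium partition coefficient.
#' @param pdms_thickness ceiling slab thickness, m.
#' @param q_cell maximal per-cell consumption, mol/s/cell.
#' @param Km Michaelis constant, mol/m^3 (must be < `c_sat`).
#' @param ambient_c concentration equilibrated with the incubator
#'   atmosphere, mol/m^3 (default `c_sat`).
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(D_medium = 3.0e-9, D_pdms = 3.4e-9,
                             D_tissue = NULL, c_sat = 0.2,
                             partition_pdms = 10, pdms_thickness = 5e-3,
                             q_cell = 5e-17, Km = 0.005,
                             ambient_c = c_sat) {
  stopifnot_positive(D_medium, c_sat, partition_pdms, pdms_thickness,
                     q_cell, Km)
  if (D_pdms < 0) stop("'D_pdms' must be >= 0", call. = FALSE)
  if (!is.null(D_tissue)) stopifnot_positive(D_tissue)
  if (Km >= c_sat) stop("'Km' must be smaller than 'c_sat'", call. = FALSE)
  if (ambient_c < 0) stop("'ambient_c' must be >= 0", call. = FALSE)
  structure(list(D_medium = D_medium, D_pdms = D_pdms, D_tissue = D_tissue,
                 c_sat = c_sat, partition_pdms = partition_pdms,
                 pdms_thickness = pdms_thickness, q_cell = q_cell, Km = Km,
                 ambient_c = ambient_c),
            class = "transport_params")
}

pdms_transfer_coeff <- function(p) p$partition_pdms * p$D_pdms / p$pdms_thickness

#' Low-level structured transport domain
#'
#' Builds an `oxygen_domain` from raw matrices; [assemble_domain()] is the
#' geometry-aware constructor and this one serves reduced configurations
#' (validation slabs, custom layouts). Matrices are indexed `[i, j]` with
#' `i` along x (1..nx) and `j` along y (1..ny); `NA` region entries mark
#' inactive wall cells.
#'
#' @param region character matrix, entries in `"medium"`, `"slit"`,
#'   `"chamber"` or `NA`.
#' @param height conveyance height per cell, m.
#' @param rho hepatocyte surface density per cell, cells/m^2.
#' @param Fx `(nx+1) x ny` matrix of west-face volumetric fluxes, m^3/s,
#'   positive in +x; `Fx[i, j]` is the west face of cell `(i, j)`.
#' @param Fy `nx x (ny+1)` matrix of south-face fluxes, positive in +y.
#' @param dx cell width, m. @param dy cell heights, m (scalar or length ny).
#' @param dirichlet data frame (`i`, `j`, `side` in `"W"`/`"E"`, `value`)
#'   of Dirichlet boundary faces; `value = NA` means "use `c_sat`".
#' @param frac fluid (open-area) fraction per cell in (0, 1]; partially
#'   walled cells transport, react and permeate in proportion. Default 1.
#' @return an object of class `oxygen_domain`.
#' @export
oxygen_domain <- function(region, height, rho, Fx, Fy, dx, dy,
                          dirichlet = NULL, frac = NULL) {
  nx <- nrow(region); ny <- ncol(region)
  if (length(dy) == 1) dy <- rep(dy, ny)
  stopifnot(all(dim(height) == c(nx, ny)), all(dim(rho) == c(nx, ny)),
            all(dim(Fx) == c(nx + 1, ny)), all(dim(Fy) == c(nx, ny + 1)),
            length(dy) == ny, dx > 0, all(dy > 0))
  ok <- is.na(region) | region %in% c("medium", "slit", "chamber")
  if (!all(ok)) stop("invalid region labels", call. = FALSE)
  act <- !is.na(region)
  if (any(act & (is.na(height) | height <= 0))) {
    stop("active cells need positive conveyance height", call. = FALSE)
  }
  if (any(act & (is.na(rho) | rho < 0))) {
    stop("cell density must be >= 0 on active cells", call. = FALSE)
  }
  if (is.null(dirichlet)) {
    dirichlet <- data.frame(i = integer(0), j = integer(0),
                            side = character(0), value = numeric(0))
  }
  if (is.null(frac)) frac <- matrix(1, nx, ny)
  stopifnot(all(dim(frac) == c(nx, ny)))
  if (any(act & (is.na(frac) | frac <= 0 | frac > 1))) {
    stop("'frac' must lie in (0, 1] on active cells", call. = FALSE)
  }
  structure(list(region = region, height = height, rho = rho, Fx = Fx,
                 Fy = Fy, dx = dx, dy = dy, dirichlet = dirichlet,
                 frac = frac, nx = nx, ny = ny),
            class = "oxygen_domain")
}

#' Assemble the transport domain of one chamber series
#'
#' Rasterises the medium channel, slit strip and chambers of one series
#' onto a structured grid and interpolates the solved network flows into a
#' conservative face-flux field (plug flow per duct; the medium-channel
#' flow steps down across each chamber mouth by exactly that chamber's
#' through-flow, which leaves through the chamber far end toward the cell
#' channel). The slit strip carries an effective conveyance height of
#' `open-area fraction x slit height`. Cell densities place each chamber's
#' live-cell count uniformly over its rasterised floor, conserving the
#' seeded total exactly.
#'
#' @param geom a [device_geometry()].
#' @param sol a `flow_solution` from [solve_perfusion()] for `geom`.
#' @param occupancy an [draw_occupancy()] result (or integer vector of
#'   per-chamber live-cell counts, recycled across the device).
#' @param resolution target grid resolution, um. Must resolve the slit
#'   strip with at least two rows.
#' @param series which chamber series to rasterise (1-based).
#' @return an `oxygen_domain`.
#' @export
assemble_domain <- function(geom, sol, occupancy, resolution = 2,
                            series = 1) {
  stopifnot(inherits(geom, "device_geometry"), inherits(sol, "flow_solution"))
  counts <- if (inherits(occupancy, "occupancy_draw")) occupancy$counts
    else as.numeric(occupancy)
  ncham <- geom$chamber$count_per_series
  counts <- rep_len(counts, ncham * geom$chamber$series_count)
  counts <- counts[(series - 1) * ncham + seq_len(ncham)]

  res <- um_to_m(resolution)
  L_slit <- geom$slit$length
  if (round(L_slit / res) < 2) {
    stop(sprintf("resolution %g um too coarse to resolve the %g um slit strip; use <= %g um",
                 resolution, m_to_um(L_slit), floor(m_to_um(L_slit) / 2)),
         call. = FALSE)
  }
  pitch <- geom$medium_channel$segment_length
  w_mouth <- geom$chamber$width
  L_ch <- geom$chamber$length
  w_med <- geom$medium_channel$width

  nxp <- max(2L, round(pitch / res)); dx <- pitch / nxp
  nx <- nxp * ncham
  ny1 <- max(1L, round(L_ch / res));  dy1 <- L_ch / ny1   # chamber strip
  ny2 <- max(2L, round(L_slit / res)); dy2 <- L_slit / ny2 # slit strip
  ny3 <- max(2L, round(w_med / res)); dy3 <- w_med / ny3   # medium strip
  ny <- ny1 + ny2 + ny3
  dy <- c(rep(dy1, ny1), rep(dy2, ny2), rep(dy3, ny3))
  jmed <- ny1 + ny2 + seq_len(ny3)

  # network flows for this series
  ed <- sol$edge_flows
  first <- ed[ed$label == "medium_segment" & ed$series == series &
              ed$from == "medium_in", ]
  q_branch <- first$flow
  chamb <- ed[ed$label == "chamber" & ed$series == series, ]
  chamb <- chamb[order(chamb$chamber), ]
  q_ch <- chamb$flow  # positive = medium -> cell channel
  if (any(q_ch < -1e-18 * max(abs(q_branch), 1e-30))) {
    stop("reversed chamber through-flow; domain assembly assumes medium -> cell direction",
         call. = FALSE)
  }
  q_ch <- pmax(q_ch, 0)

  # mouth overlap fractions per column and chamber
  xf <- (0:nx) * dx                      # face positions
  xc <- (seq_len(ncham) - 0.5) * pitch   # mouth centres
  fr <- vapply(seq_len(ncham), function(j) {
    pmin(pmax((xf - (xc[j] - w_mouth / 2)) / w_mouth, 0), 1)
  }, numeric(nx + 1))                    # (nx+1) x ncham cumulative fraction
  Qm_face <- q_branch - as.numeric(fr %*% q_ch)  # medium flow at each x-face
  dq <- -diff(Qm_face)                   # per-column offtake (>= 0)
  frcol <- fr[-1, , drop = FALSE] - fr[-(nx + 1), , drop = FALSE]
  col_ch <- apply(frcol, 1, function(z) {
    k <- which(z > 1e-12); if (length(k)) k[1] else NA_integer_
  })                                     # chamber owning each column (or NA)
  mouth <- !is.na(col_ch)

  region <- matrix(NA_character_, nx, ny)
  region[, jmed] <- "medium"
  region[mouth, seq_len(ny1)] <- "chamber"
  region[mouth, ny1 + seq_len(ny2)] <- "slit"

  phi <- min(1, geom$slit$count_per_side * geom$slit$width / w_mouth)
  height <- matrix(NA_real_, nx, ny)
  height[, jmed] <- geom$medium_channel$height
  height[mouth, seq_len(ny1)] <- geom$chamber$height
  height[mouth, ny1 + seq_len(ny2)] <- phi * geom$slit$height

  # partially covered mouth columns are treated as porous (fluid fraction =
  # overlap), so the chamber footprint, ceiling area and seeded-cell total
  # are resolution-independent; density is uniform over the true footprint
  rho <- matrix(0, nx, ny)
  for (j in seq_len(ncham)) {
    cols <- which(frcol[, j] > 1e-12)
    rho[cols, seq_len(ny1)] <- counts[j] / (ny1 * dy1 * w_mouth)
  }
  frac <- matrix(1, nx, ny)
  fcol <- rep(1, nx)
  # frcol is normalised by the mouth width; the open fraction of a column
  # is its overlap length over dx
  fcol[mouth] <- pmin(1, frcol[cbind(which(mouth), col_ch[mouth])] *
                        w_mouth / dx)
  frac[, seq_len(ny1 + ny2)] <- fcol

  Fx <- matrix(0, nx + 1, ny)
  Fy <- matrix(0, nx, ny + 1)
  Fx[, jmed] <- Qm_face / ny3            # plug flow over the medium rows
  dq_col <- dq
  # vertical plug through slit + chamber strips (downward, -y), exiting
  # through the domain south face toward the cell channel
  for (j in seq_len(ny1 + ny2)) Fy[, j] <- -dq_col
  # telescoped redistribution inside the medium strip: each medium row
  # sheds its share of the offtake so every cell conserves exactly
  for (r in seq_len(ny3)) {
    Fy[, ny1 + ny2 + r] <- -dq_col * (1 - (r - 1) / ny3)
  }
  Fy[, ny + 1] <- 0

  dirichlet <- data.frame(i = 1L, j = jmed, side = "W", value = NA_real_)
  dom <- oxygen_domain(region, height, rho, Fx, Fy, dx, dy, dirichlet,
                       frac = frac)
  dom$meta <- list(series = series, counts = counts, resolution_um = resolution,
                   ny_strips = c(chamber = ny1, slit = ny2, medium = ny3))
  dom
}

#' Total seeded cells on a domain
#' @param dom an `oxygen_domain`.
#' @return total cell count represented on the grid.
#' @export
domain_cell_total <- function(dom) {
  area <- outer(rep(dom$dx, dom$nx), dom$dy) * dom$frac
  sum(dom$rho * area, na.rm = TRUE)
}

#' Worst cell-wise face-flux imbalance of a domain
#' @param dom an `oxygen_domain`.
#' @return maximum |net face flux| per cell, relative to the largest face flux.
#' @export
domain_divergence <- function(dom) {
  nx <- dom$nx; ny <- dom$ny
  div <- dom$Fx[seq_len(nx), ] - dom$Fx[seq_len(nx) + 1, ] +
    dom$Fy[, seq_len(ny)] - dom$Fy[, seq_len(ny) + 1]
  scale <- max(abs(dom$Fx), abs(dom$Fy), 1e-300)
  max(abs(div[!is.na(dom$region)])) / scale
}

# Shared finite-volume assembly. Returns the linear operator for
# diffusion + upwind convection + PDMS transfer, the source vector, and
# the bookkeeping needed for Picard iteration and mass audits.
.ox_assemble <- function(dom, p) {
  nx <- dom$nx; ny <- dom$ny
  act <- !is.na(dom$region)
  n <- sum(act)
  idx <- matrix(NA_integer_, nx, ny); idx[act] <- seq_len(n)
  Dmat <- matrix(NA_real_, nx, ny)
  Dmat[dom$region %in% c("medium", "slit")] <- p$D_medium
  Dmat[dom$region %in% "chamber"] <- if (is.null(p$D_tissue)) p$D_medium
    else p$D_tissue
  Dh <- Dmat * dom$height * dom$frac  # walls block transport pro rata
  dyrow <- matrix(dom$dy, nx, ny, byrow = TRUE)
  area <- dom$dx * dyrow * dom$frac   # fluid (ceiling/floor) area per cell

  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, v) { ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v) }
  harm <- function(a, b) 2 * a * b / (a + b)

  # interior x-faces
  iw <- which(act[-nx, , drop = FALSE] & act[-1, , drop = FALSE],
              arr.ind = TRUE)
  if (nrow(iw)) {
    L <- idx[cbind(iw[, 1], iw[, 2])]
    R <- idx[cbind(iw[, 1] + 1, iw[, 2])]
    Gd <- harm(Dh[cbind(iw[, 1], iw[, 2])], Dh[cbind(iw[, 1] + 1, iw[, 2])]) *
      dom$dy[iw[, 2]] / dom$dx
    Fv <- dom$Fx[cbind(iw[, 1] + 1, iw[, 2])]
    add(L, L, Gd + pmax(Fv, 0)); add(L, R, -(Gd + pmax(-Fv, 0)))
    add(R, R, Gd + pmax(-Fv, 0)); add(R, L, -(Gd + pmax(Fv, 0)))
  }
  # interior y-faces (possibly unequal dy across strip boundaries)
  iw <- which(act[, -ny, drop = FALSE] & act[, -1, drop = FALSE],
              arr.ind = TRUE)
  if (nrow(iw)) {
    S <- idx[cbind(iw[, 1], iw[, 2])]
    N <- idx[cbind(iw[, 1], iw[, 2] + 1)]
    dist <- (dom$dy[iw[, 2]] + dom$dy[iw[, 2] + 1]) / 2
    Gd <- harm(Dh[cbind(iw[, 1], iw[, 2])], Dh[cbind(iw[, 1], iw[, 2] + 1)]) *
      dom$dx / dist
    Fv <- dom$Fy[cbind(iw[, 1], iw[, 2] + 1)]
    add(S, S, Gd + pmax(Fv, 0)); add(S, N, -(Gd + pmax(-Fv, 0)))
    add(N, N, Gd + pmax(-Fv, 0)); add(N, S, -(Gd + pmax(Fv, 0)))
  }

  b <- numeric(n)
  dir_cell <- integer(0); dir_G <- dir_F <- dir_c <- numeric(0)
  dtab <- dom$dirichlet
  dkey <- if (nrow(dtab)) paste(dtab$i, dtab$j, dtab$side) else character(0)
  dir_val <- function(k) if (is.na(dtab$value[k])) p$c_sat else dtab$value[k]
  for (k in seq_len(nrow(dtab))) {
    i <- dtab$i[k]; j <- dtab$j[k]
    P <- idx[i, j]
    if (is.na(P)) stop("Dirichlet face on inactive cell", call. = FALSE)
    Fface <- if (dtab$side[k] == "W") dom$Fx[i, j] else -dom$Fx[i + 1, j]
    # Fface > 0 means inflow through this boundary face
    Gh <- Dh[i, j] * dom$dy[j] / (dom$dx / 2)
    c0 <- dir_val(k)
    add(P, P, Gh + pmax(-Fface, 0))
    b[P] <- b[P] + Gh * c0 + pmax(Fface, 0) * c0
    dir_cell <- c(dir_cell, P); dir_G <- c(dir_G, Gh)
    dir_F <- c(dir_F, Fface); dir_c <- c(dir_c, c0)
  }

  # remaining boundary faces with nonzero flux: advective outflow only
  out_cell <- integer(0); out_F <- numeric(0)
  bnd_side <- function(is, js, Fout, side) {
    if (!length(is)) return(invisible(NULL))
    keep <- !(paste(is, js, side) %in% dkey)
    is <- is[keep]; js <- js[keep]; Fout <- Fout[keep]
    if (!length(is)) return(invisible(NULL))
    P <- idx[cbind(is, js)]
    if (anyNA(P)) stop("flux through wall face", call. = FALSE)
    if (any(Fout < 0)) {
      stop("advective inflow through a non-Dirichlet boundary face",
           call. = FALSE)
    }
    add(P, P, Fout)
    out_cell <<- c(out_cell, P); out_F <<- c(out_F, Fout)
    invisible(NULL)
  }
  js <- which(dom$Fx[1, ] != 0)
  bnd_side(rep(1L, length(js)), js, -dom$Fx[1, js], "W")
  js <- which(dom$Fx[nx + 1, ] != 0)
  bnd_side(rep(nx, length(js)), js, dom$Fx[nx + 1, js], "E")
  is <- which(dom$Fy[, 1] != 0)
  bnd_side(is, rep(1L, length(is)), -dom$Fy[is, 1], "S")
  is <- which(dom$Fy[, ny + 1] != 0)
  bnd_side(is, rep(ny, length(is)), dom$Fy[is, ny + 1], "N")

  # idx[act] is already 1..n in column-major order, so act-masked vectors
  # are aligned with the unknown ordering
  kp <- pdms_transfer_coeff(p)
  diag_pdms <- kp * area[act]
  b <- b + diag_pdms * p$ambient_c
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)) +
    Matrix::Diagonal(n, diag_pdms)

  rho_act <- dom$rho[act]
  area_act <- area[act]
  list(A = A, b = b, n = n, idx = idx, act = act,
       uptake_cap = rho_act * p$q_cell * area_act,  # mol/s at saturation
       diag_pdms = diag_pdms, area_act = area_act,
       dir = list(cell = dir_cell, G = dir_G, F = dir_F, c0 = dir_c),
       out = list(cell = out_cell, F = out_F))
}

#' Steady oxygen field
#'
#' Solves the depth-averaged steady advection-diffusion-reaction problem
#' on a domain by finite volumes: harmonic-mean interface diffusivities,
#' first-order upwind convection, linear PDMS ceiling transfer, and
#' Michaelis-Menten uptake resolved by Newton iteration (the uptake
#' Jacobian is diagonal, `rho q Km / (Km + c)^2`, so each Newton step
#' costs one sparse solve and convergence is quadratic; steps are damped
#' if they would leave the physical range). Iteration stops when the
#' update is below `tol` relative to `c_sat`. The discretisation is
#' monotone, so the converged field stays within
#' `[0, max(c_sat, ambient_c)]`.
#'
#' @param dom an `oxygen_domain`.
#' @param p a [transport_params()].
#' @param tol convergence tolerance on the relative Newton update.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `oxygen_field`: `concentration` matrix
#'   (mol/m^3, `NA` on walls), `residual` (last relative update),
#'   `iterations`, and the domain/parameters used.
#' @export
steady_state <- function(dom, p = transport_params(), tol = 1e-8,
                         max_iter = 60) {
  stopifnot(inherits(dom, "oxygen_domain"), inherits(p, "transport_params"))
  asm <- .ox_assemble(dom, p)
  cmax <- max(p$c_sat, p$ambient_c)
  cv <- rep(p$c_sat, asm$n)
  it <- 0; res <- Inf
  while (it < max_iter) {
    it <- it + 1
    Fres <- as.numeric(asm$A %*% cv) + asm$uptake_cap * cv / (p$Km + cv) -
      asm$b
    J <- asm$A + Matrix::Diagonal(asm$n, asm$uptake_cap * p$Km /
                                    (p$Km + cv)^2)
    dc <- as.numeric(Matrix::solve(J, -Fres))
    step <- 1
    while (any(cv + step * dc < -1e-12 * cmax) && step > 1 / 64) step <- step / 2
    cv <- pmin(pmax(cv + step * dc, 0), cmax)
    res <- max(abs(dc)) * step / p$c_sat
    if (res < tol) break
  }
  c_prev <- cv
  if (res >= tol) {
    stop(sprintf("Newton iteration did not converge in %d iterations (last update %.3e)",
                 max_iter, res), call. = FALSE)
  }
  conc <- matrix(NA_real_, dom$nx, dom$ny)
  conc[asm$act] <- c_prev[asm$idx[asm$act]]
  structure(list(concentration = conc, residual = res, iterations = it,
                 domain = dom, params = p),
            class = "oxygen_field")
}

#' Mass audit of a converged oxygen field
#'
#' Recomputes influx (inlet advection + inlet diffusion + net PDMS
#' permeation), outflux (advective outflow) and Michaelis-Menten uptake
#' from the converged field, and their relative imbalance.
#'
#' @param field an `oxygen_field`.
#' @return list with `influx`, `outflux`, `uptake` (mol/s) and
#'   `imbalance_rel`.
#' @export
oxygen_mass_balance <- function(field) {
  stopifnot(inherits(field, "oxygen_field"))
  dom <- field$domain; p <- field$params
  asm <- .ox_assemble(dom, p)
  cv <- field$concentration[asm$act]
  influx <- sum(asm$dir$G * (asm$dir$c0 - cv[asm$dir$cell])) +
    sum(pmax(asm$dir$F, 0) * asm$dir$c0) +
    sum(asm$diag_pdms * (p$ambient_c - cv))
  outflux <- sum(asm$out$F * cv[asm$out$cell])
  uptake <- sum(asm$uptake_cap * cv / (p$Km + cv))
  scale <- max(abs(influx), 1e-300)
  list(influx = influx, outflux = outflux, uptake = uptake,
       imbalance_rel = (influx - outflux - uptake) / scale)
}

#' Minimum oxygen concentration in the cell zone
#'
#' Minimum of the converged field over chamber-labelled cells - the
#' quantity the hypoxia floor constrains. Returns `c_sat` when the domain
#' has no chamber cells.
#'
#' @param field an `oxygen_field`.
#' @param dom optional domain (defaults to the one stored in the field).
#' @return concentration, mol/m^3.
#' @export
min_cell_zone_concentration <- function(field, dom = field$domain) {
  stopifnot(inherits(field, "oxygen_field"))
  sel <- !is.na(dom$region) & dom$region == "chamber"
  if (!any(sel)) return(field$params$c_sat)
  min(field$concentration[sel])
}

#' @rdname min_cell_zone_concentration
#' @param threshold hypoxia threshold, mol/m^3 (default `0.1 * c_sat`).
#' @export
oxygen_sufficient <- function(field, threshold = 0.1 * field$params$c_sat,
                              dom = field$domain) {
  min_cell_zone_concentration(field, dom) >= threshold
}

#' Analytic oxygen supply budget
#'
#' Fast whole-device mass balance: the ratio of maximal supply (convective
#' inflow `Q c_sat` plus PDMS permeation over the ceiling window at its
#' maximal driving force) to maximal demand (`N q_cell`). A ratio above 1
#' means supply exceeds the saturated consumption of all cells; zero cells
#' give `Inf` (always sufficient).
#'
#' @param inlet_flow perfusion flow, m^3/s.
#' @param total_cells total live cells on the device.
#' @param p a [transport_params()].
#' @param pdms_window_area ceiling area available for permeation, m^2
#'   (0 disables the PDMS term).
#' @return dimensionless supply ratio.
#' @export
#' @examples
#' # convective term only, at the 375 nl/min operating point with 4000 cells
#' oxygen_budget(nlmin_to_m3s(375), 4000, pdms_window_area = 0)  # 6.25
oxygen_budget <- function(inlet_flow, total_cells, p = transport_params(),
                          pdms_window_area = chamber_ceiling_area_default()) {
  if (inlet_flow < 0 || total_cells < 0 || pdms_window_area < 0) {
    stop("budget arguments must be non-negative", call. = FALSE)
  }
  if (total_cells == 0) return(Inf)
  supply <- inlet_flow * p$c_sat +
    pdms_window_area * pdms_transfer_coeff(p) * p$ambient_c
  supply / (total_cells * p$q_cell)
}

#' Chamber ceiling area of a geometry
#'
#' Total PDMS ceiling area above the culture chambers - the permeation
#' window used by default in the analytic budget.
#'
#' @param geom a [device_geometry()].
#' @return area, m^2.
#' @export
chamber_ceiling_area <- function(geom) {
  stopifnot(inherits(geom, "device_geometry"))
  ch <- geom$chamber
  ch$width * ch$length * ch$count_per_series * ch$series_count
}

#' @rdname chamber_ceiling_area
#' @export
chamber_ceiling_area_default <- function() chamber_ceiling_area(make_preset("40-2"))

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("<oxygen_field> %d x %d grid; %d Newton iterations (residual %.2e)\n",
              x$domain$nx, x$domain$ny, x$iterations, x$residual))
  cat(sprintf("  min chamber-zone concentration: %.4g mol/m^3 (c_sat %.3g)\n",
              min_cell_zone_concentration(x), x$params$c_sat))
  invisible(x)
}

#' @export
as.data.frame.oxygen_field <- function(x, ...) {
  dom <- x$domain
  xs <- (seq_len(dom$nx) - 0.5) * dom$dx
  ys <- cumsum(dom$dy) - dom$dy / 2
  act <- which(!is.na(dom$region), arr.ind = TRUE)
  data.frame(x = xs[act[, 1]], y = ys[act[, 2]],
             region = dom$region[act],
             c = x$concentration[act])
}
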