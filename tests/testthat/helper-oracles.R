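# Independent oracles and small fixtures used across the suite.

# Dense nodal solve with row-replacement of Dirichlet nodes - a different
# assembly and solver path than the package's sparse eliminated system.
dense_solve_oracle <- function(net) {
  nd <- net$nodes; ed <- net$edges
  ids <- nd$id
  n <- length(ids)
  G <- matrix(0, n, n)
  b <- rep(0, n)
  g <- 1 / ed$resistance
  for (k in seq_len(nrow(ed))) {
    a <- match(ed$from[k], ids); bb <- match(ed$to[k], ids)
    G[a, a] <- G[a, a] + g[k]; G[bb, bb] <- G[bb, bb] + g[k]
    G[a, bb] <- G[a, bb] - g[k]; G[bb, a] <- G[bb, a] - g[k]
  }
  b[nd$kind == "fixed_flow"] <- nd$value[nd$kind == "fixed_flow"]
  for (i in which(nd$kind == "fixed_pressure")) {
    G[i, ] <- 0; G[i, i] <- 1; b[i] <- nd$value[i]
  }
  stats::setNames(solve(G, b), ids)
}

# Random connected resistor network with mixed boundary conditions.
random_network <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  from <- to <- character(0)
  for (k in 2:n_nodes) {                      # spanning tree
    from <- c(from, ids[sample(k - 1, 1)]); to <- c(to, ids[k])
  }
  extra <- max(2, round(n_nodes / 2))
  for (k in seq_len(extra)) {
    ab <- sample(n_nodes, 2)
    from <- c(from, ids[ab[1]]); to <- c(to, ids[ab[2]])
  }
  R <- 1e12 * stats::rlnorm(length(from), 0, 1.5)
  nodes <- data.frame(id = ids, kind = "interior", value = 0,
                      stringsAsFactors = FALSE)
  net <- structure(list(
    nodes = nodes,
    edges = data.frame(id = seq_along(from), from = from, to = to,
                       resistance = R, label = "medium_segment",
                       series = NA_integer_, chamber = NA_integer_,
                       stringsAsFactors = FALSE),
    geom_name = "random", n_series = 0L, n_chambers = 0L,
    has_capillary = FALSE), class = "hydraulic_network")
  set_boundary(net,
               fixed_flow = stats::setNames(1e-10 * stats::runif(1), ids[3]),
               fixed_pressure = stats::setNames(c(0, 50 * stats::runif(1)),
                                                ids[1:2]))
}

# Exact rectangular-duct resistance by solving the cross-section Poisson
# problem (mu lap u = -G, u = 0 on walls) with second-order finite
# differences - independent of the package's Fourier-series evaluation.
poisson_duct_resistance <- function(width, height, length, mu = 6.9e-4,
                                    n = 120) {
  nx <- n; ny <- max(12, round(n * height / width))
  dx <- width / nx; dy <- height / ny
  ix <- seq_len(nx - 1); iy <- seq_len(ny - 1)   # interior vertices
  id <- function(i, j) (j - 1) * (nx - 1) + i
  ii <- jj <- integer(0); xx <- numeric(0)
  grid <- expand.grid(i = ix, j = iy)
  P <- id(grid$i, grid$j)
  ii <- c(ii, P); jj <- c(jj, P); xx <- c(xx, rep(2 / dx^2 + 2 / dy^2,
                                                 length(P)))
  for (d in list(c(1, 0), c(-1, 0))) {
    keep <- grid$i + d[1] >= 1 & grid$i + d[1] <= nx - 1
    ii <- c(ii, P[keep]); jj <- c(jj, id(grid$i[keep] + d[1], grid$j[keep]))
    xx <- c(xx, rep(-1 / dx^2, sum(keep)))
  }
  for (d in list(c(0, 1), c(0, -1))) {
    keep <- grid$j + d[2] >= 1 & grid$j + d[2] <= ny - 1
    ii <- c(ii, P[keep]); jj <- c(jj, id(grid$i[keep], grid$j[keep] + d[2]))
    xx <- c(xx, rep(-1 / dy^2, sum(keep)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx)
  u <- as.numeric(Matrix::solve(A, rep(1 / mu, nrow(grid))))  # G = 1 Pa/m
  Q <- sum(u) * dx * dy
  length / Q
}

# 40-2 layout shrunk to a few chambers per series: every physical scale of
# the full device, small enough for repeated transport solves.
tiny_geom <- function(n_chambers = 3, preset = "40-2") {
  make_preset(preset,
              overrides = list(chamber = list(count_per_series = n_chambers)))
}

# 1D closed diffusion-reaction slab as a transport domain.
slab_domain <- function(n = 200, L = 200e-6, h = 40e-6, rho = 2e10,
                        c0 = 0.2) {
  oxygen_domain(region = matrix("chamber", n, 1),
                height = matrix(h, n, 1),
                rho = matrix(rho, n, 1),
                Fx = matrix(0, n + 1, 1), Fy = matrix(0, n, 2),
                dx = L / n, dy = 10e-6,
                dirichlet = data.frame(i = 1L, j = 1L, side = "W",
                                       value = c0))
}
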