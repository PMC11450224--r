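#' Linear 2-D pollen transport operator
#'
#' Builds a vertically integrated (well-mixed boundary layer) linear transport
#' operator on the analysis grid: first-order upwind advection on the daily
#' wind fields, explicit diffusion, and first-order deposition loss with a
#' rate derived from the taxon's grain diameter and density via Stokes
#' settling divided by the mixing height. Time steps are automatically
#' sub-stepped to keep the advection Courant number and the diffusion number
#' stable, so the scheme is never silently unstable. Lateral boundaries are
#' open (free outflow, zero inflow) by default; `boundary = "closed"` makes
#' all boundary faces no-flux, which conserves domain-total mass exactly and
#' is used in conservation tests.
#'
#' The per-day update is assembled as an explicit sparse matrix, so the
#' forward map is linear in emission and the adjoint is its exact discrete
#' transpose (see [adjoint_transport()]).
#'
#' @param grid A [grid_spec()].
#' @param meteo A `meteo_fields` object (hourly records are aggregated to
#'   daily-mean winds for transport).
#' @param taxon Optional [taxon_params()]; sets the deposition rate from
#'   grain size/density. Without it `deposition_rate` must be given.
#' @param params Optional overrides: `K` (horizontal diffusion, m2/s, default
#'   5000), `h_mix` (mixing height, m, default 1000), `boundary` ("open" or
#'   "closed"), `deposition_rate` (1/s, overrides the Stokes-derived value),
#'   `courant_max` (default 0.5), `diffusion_max` (default 0.25).
#' @return A `linear_transport` object with the per-day sub-step matrices.
#' @export
linear_transport <- function(grid, meteo, taxon = NULL, params = list()) {
  p <- utils::modifyList(list(
    K = 5000, h_mix = 1000, boundary = "open",
    deposition_rate = NULL, courant_max = 0.5, diffusion_max = 0.25
  ), params)
  if (is.null(p$deposition_rate)) {
    if (is.null(taxon)) stop("need a taxon (grain size) or deposition_rate")
    d_m <- taxon$grain_diameter_um * 1e-6
    v_s <- taxon$grain_density_kg_m3 * 9.81 * d_m^2 / (18 * 1.8e-5)  # Stokes
    p$deposition_rate <- v_s / p$h_mix
  }
  nx <- grid$nx; ny <- grid$ny
  # daily-mean winds
  days <- unique(meteo$dates)
  nd <- length(days)
  u <- array(0, c(nx, ny, nd)); v <- array(0, c(nx, ny, nd))
  if (meteo$dt_hours == 24) {
    u <- meteo$u; v <- meteo$v
  } else {
    for (d in seq_len(nd)) {
      sel <- which(meteo$dates == days[d])
      u[, , d] <- apply(meteo$u[, , sel, drop = FALSE], c(1, 2), mean)
      v[, , d] <- apply(meteo$v[, , sel, drop = FALSE], c(1, 2), mean)
    }
  }
  ops <- vector("list", nd)
  nsub <- integer(nd)
  day_s <- 86400
  for (d in seq_len(nd)) {
    ud <- u[, , d]; vd <- v[, , d]
    adv_c <- max(abs(ud)) * day_s / min(grid$dx) + max(abs(vd)) * day_s / grid$dy
    dif_c <- 2 * p$K * day_s * (1 / min(grid$dx)^2 + 1 / grid$dy^2)
    k <- max(1L, ceiling(adv_c / p$courant_max), ceiling(dif_c / p$diffusion_max))
    dt <- day_s / k
    ops[[d]] <- assemble_substep(grid, ud, vd, dt, p)
    nsub[d] <- k
  }
  structure(list(grid = grid, dates = days, ops = ops, nsub = nsub,
                 K = p$K, h_mix = p$h_mix, boundary = p$boundary,
                 deposition_rate = p$deposition_rate,
                 inject = day_s / (as.vector(grid$area_m2) * p$h_mix)),
            class = "linear_transport")
}

# one explicit sub-step matrix: deposition * (I + upwind advection + diffusion)
assemble_substep <- function(grid, u, v, dt, p) {
  nx <- grid$nx; ny <- grid$ny
  id <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(r, c, val) {
    val <- rep_len(val, length(r))
    c <- rep_len(c, length(r))
    keep <- val != 0
    ii <<- c(ii, r[keep]); jj <<- c(jj, c[keep]); xx <<- c(xx, val[keep])
  }
  # --- interior x-faces between (i,j) and (i+1,j)
  i <- rep(seq_len(nx - 1), times = ny); j <- rep(seq_len(ny), each = nx - 1)
  dxj <- grid$dx[j]
  uf <- 0.5 * (u[cbind(i, j)] + u[cbind(i + 1, j)])
  crt <- uf * dt / dxj
  donor <- ifelse(uf > 0, id(i, j), id(i + 1L, j))
  recv <- ifelse(uf > 0, id(i + 1L, j), id(i, j))
  add(recv, donor, abs(crt))
  add(donor, donor, -abs(crt))
  sdif <- p$K * dt / dxj^2
  add(id(i, j), id(i + 1L, j), sdif); add(id(i, j), id(i, j), -sdif)
  add(id(i + 1L, j), id(i, j), sdif); add(id(i + 1L, j), id(i + 1L, j), -sdif)
  # --- interior y-faces between (i,j) and (i,j+1); cell widths shrink with
  # latitude, so fluxes are weighted by the face width over the cell width to
  # keep the scheme mass-conserving on the lon-lat grid
  i <- rep(seq_len(nx), times = ny - 1); j <- rep(seq_len(ny - 1), each = nx)
  w_face <- 0.5 * (grid$dx[j] + grid$dx[j + 1])
  vf <- 0.5 * (v[cbind(i, j)] + v[cbind(i, j + 1)])
  crt <- abs(vf) * dt / grid$dy
  up <- vf > 0
  donor <- ifelse(up, id(i, j), id(i, j + 1L))
  recv <- ifelse(up, id(i, j + 1L), id(i, j))
  w_donor <- ifelse(up, grid$dx[j], grid$dx[j + 1])
  w_recv <- ifelse(up, grid$dx[j + 1], grid$dx[j])
  add(recv, donor, crt * w_face / w_recv)
  add(donor, donor, -crt * w_face / w_donor)
  sdif <- p$K * dt / grid$dy^2
  add(id(i, j), id(i, j + 1L), sdif * w_face / grid$dx[j])
  add(id(i, j), id(i, j), -sdif * w_face / grid$dx[j])
  add(id(i, j + 1L), id(i, j), sdif * w_face / grid$dx[j + 1])
  add(id(i, j + 1L), id(i, j + 1L), -sdif * w_face / grid$dx[j + 1])
  # --- boundary faces: open = outflow loss on outward wind, zero inflow
  if (p$boundary == "open") {
    j <- seq_len(ny)
    west <- id(1L, j); east <- id(nx, j)
    out_w <- pmax(-u[cbind(1L, j)], 0) * dt / grid$dx[j]
    out_e <- pmax(u[cbind(nx, j)], 0) * dt / grid$dx[j]
    add(west, west, -out_w); add(east, east, -out_e)
    i <- seq_len(nx)
    south <- id(i, 1L); north <- id(i, ny)
    out_s <- pmax(-v[cbind(i, 1L)], 0) * dt / grid$dy
    out_n <- pmax(v[cbind(i, ny)], 0) * dt / grid$dy
    add(south, south, -out_s); add(north, north, -out_n)
  }
  n <- nx * ny
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)) +
    Matrix::Diagonal(n)
  exp(-p$deposition_rate * dt) * A
}

#' @export
print.linear_transport <- function(x, ...) {
  cat(sprintf(
    "linear_transport: %d x %d grid, %d days, K = %g m2/s, h_mix = %g m, dep = %.3g 1/s, %s boundaries\n",
    x$grid$nx, x$grid$ny, length(x$dates), x$K, x$h_mix, x$deposition_rate,
    x$boundary))
  invisible(x)
}

# emission_field or raw array -> daily emission matrix [ncell x nd], grains/s
emission_daily_matrix <- function(transport, emission) {
  if (inherits(emission, "emission_field")) {
    E <- emission$E; dates <- emission$dates; dth <- emission$dt_hours
  } else {
    E <- emission; dates <- transport$dates; dth <- 24
  }
  nd <- length(transport$dates)
  ncell <- n_cells(transport$grid)
  out <- matrix(0, ncell, nd)
  if (dth == 24) {
    if (dim(E)[3] != nd) stop("emission and transport time axes differ")
    out[] <- E
  } else {
    for (d in seq_len(nd)) {
      sel <- which(dates == transport$dates[d])
      out[, d] <- rowMeans(matrix(E[, , sel], ncell))
    }
  }
  out
}

#' Forward transport: emission to near-surface concentration
#'
#' Applies the linear transport operator to an emission history, producing
#' daily near-surface concentrations (grains/m3) in the well-mixed layer.
#' Linear in emission by construction.
#'
#' @param transport A [linear_transport()] object.
#' @param emission An `emission_field` (see [compute_emission()]) or an
#'   `nx x ny x nd` array of emission rates (grains/s per cell) on the
#'   transport time axis.
#' @return A `concentration_field` object: array `conc` (`nx x ny x nd`,
#'   grains/m3), `dates`, `grid`.
#' @export
forward_transport <- function(transport, emission) {
  E <- emission_daily_matrix(transport, emission)
  grid <- transport$grid
  nd <- length(transport$dates)
  ncell <- n_cells(grid)
  conc <- matrix(0, ncell, nd)
  c_now <- numeric(ncell)
  for (d in seq_len(nd)) {
    c_now <- c_now + transport$inject * E[, d]
    A <- transport$ops[[d]]
    for (s in seq_len(transport$nsub[d])) c_now <- as.numeric(A %*% c_now)
    conc[, d] <- c_now
  }
  structure(list(conc = array(conc, c(grid$nx, grid$ny, nd)),
                 dates = transport$dates, grid = grid),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("concentration_field: %d x %d grid, %d days, max %.3g grains/m3\n",
              x$grid$nx, x$grid$ny, dim(x$conc)[3], max(x$conc)))
  invisible(x)
}

#' Adjoint transport: concentration sensitivities to emission sensitivities
#'
#' Exact discrete adjoint (transpose) of [forward_transport()]: for any
#' emission `e` and concentration-shaped weights `w`,
#' `sum(forward(e) * w) == sum(e * adjoint(w))` to round-off. This is the
#' gradient engine of the variational assimilation and of station footprints.
#'
#' @param transport A [linear_transport()] object.
#' @param weights Array `nx x ny x nd` of weights on the daily concentration
#'   field.
#' @return Array `nx x ny x nd` of sensitivities with respect to the emission
#'   rate (per grains/s per cell and day).
#' @export
adjoint_transport <- function(transport, weights) {
  grid <- transport$grid
  nd <- length(transport$dates)
  ncell <- n_cells(grid)
  if (!all(dim(weights) == c(grid$nx, grid$ny, nd))) {
    stop("weights shape must match grid and transport time axis")
  }
  W <- matrix(weights, ncell, nd)
  G <- matrix(0, ncell, nd)
  carry <- numeric(ncell)
  for (d in rev(seq_len(nd))) {
    lam <- W[, d] + carry
    A <- transport$ops[[d]]
    for (s in seq_len(transport$nsub[d])) lam <- as.numeric(Matrix::crossprod(A, lam))
    G[, d] <- transport$inject * lam
    carry <- lam
  }
  array(G, c(grid$nx, grid$ny, nd))
}

#' Seasonal footprint of a monitoring station
#'
#' Adjoint run seeded with the station's bilinear sampling kernel on every day
#' of the window. The resulting map gives, for each grid cell, the
#' concentration sum the station would record over the window per unit
#' constant emission rate (1 grain/s) in that cell — the area the station's
#' observations can constrain.
#'
#' @param transport A [linear_transport()] object.
#' @param station List or one-row data frame with `lon`, `lat` (in-domain).
#' @param window Length-2 `Date` vector (inclusive); defaults to the full
#'   transport record.
#' @return An `nx x ny` non-negative matrix (zero for a zero-length window).
#' @export
station_footprint <- function(transport, station, window = NULL) {
  grid <- transport$grid
  if (!in_domain(grid, station$lon, station$lat)) {
    stop("station outside the grid domain")
  }
  if (is.null(window)) window <- range(transport$dates)
  sel <- transport$dates >= window[1] & transport$dates <= window[2]
  nd <- length(transport$dates)
  W <- array(0, c(grid$nx, grid$ny, nd))
  if (any(sel)) {
    bw <- bilinear_weights(grid, station$lon, station$lat)
    Wm <- matrix(W, n_cells(grid), nd)
    Wm[bw$idx, sel] <- bw$w
    W <- array(Wm, dim(W))
  }
  G <- adjoint_transport(transport, W)
  matrix(rowSums(matrix(G, n_cells(grid), nd)), grid$nx, grid$ny)
}
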