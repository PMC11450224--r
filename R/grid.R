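#' Regular lon-lat analysis grid
#'
#' Defines a cell-centered regular longitude-latitude grid. All gridded fields
#' in the package (meteorology, emission, concentration, correction maps) live
#' on such a grid, stored as matrices/arrays with dimension `c(nx, ny[, nt])`
#' where `x` indexes longitude and `y` latitude.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain edges in degrees.
#' @param nx,ny Number of cells along longitude / latitude (both >= 2).
#' @return An object of class `grid_spec` with cell centers (`lon`, `lat`),
#'   cell sizes in degrees (`dlon`, `dlat`) and metres (`dx` per latitude row,
#'   `dy`), and per-cell area `area_m2` (an `nx x ny` matrix).
#' @examples
#' g <- grid_spec(0, 40, 35, 65, nx = 40, ny = 30)
#' dim(g$area_m2)
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, nx, ny) {
  stopifnot(lon_max > lon_min, lat_max > lat_min)
  if (nx < 2 || ny < 2) stop("grid must have at least 2x2 cells")
  dlon <- (lon_max - lon_min) / nx
  dlat <- (lat_max - lat_min) / ny
  lon <- lon_min + (seq_len(nx) - 0.5) * dlon
  lat <- lat_min + (seq_len(ny) - 0.5) * dlat
  # metre sizes of a cell: meridional constant, zonal shrinks with latitude
  m_per_deg <- 111195  # mean great-circle metres per degree
  dy <- dlat * m_per_deg
  dx <- dlon * m_per_deg * cos(lat * pi / 180)  # one value per latitude row
  area <- outer(rep(1, nx), dx * dy)
  structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    nx = nx, ny = ny, dlon = dlon, dlat = dlat,
    lon = lon, lat = lat, dx = dx, dy = dy, area_m2 = area
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, lon [%g, %g], lat [%g, %g], %g x %g deg\n",
              x$nx, x$ny, x$lon_min, x$lon_max, x$lat_min, x$lat_max,
              x$dlon, x$dlat))
  invisible(x)
}

n_cells <- function(grid) grid$nx * grid$ny

#' Cell-center coordinates as a matrix
#'
#' @param grid A [grid_spec()].
#' @return A `(nx*ny) x 2` matrix of `lon, lat` cell centers in column-major
#'   (x fastest) order, matching `as.vector()` of an `nx x ny` field matrix.
#' @export
cell_centers <- function(grid) {
  cbind(lon = rep(grid$lon, times = grid$ny),
        lat = rep(grid$lat, each = grid$nx))
}

in_domain <- function(grid, lon, lat) {
  lon >= grid$lon_min & lon <= grid$lon_max &
    lat >= grid$lat_min & lat <= grid$lat_max
}

#' Bilinear interpolation weights at a point
#'
#' Returns the (up to four) cell indices and weights that bilinearly
#' interpolate a cell-centered field to `(lon, lat)`. Points between the
#' domain edge and the first cell-center row/column are clamped to the edge
#' centers, so weights always sum to one for in-domain points.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Point coordinates (degrees), inside the domain.
#' @return List with integer vector `idx` (linear cell indices) and numeric
#'   `w` (weights summing to 1).
#' @export
bilinear_weights <- function(grid, lon, lat) {
  if (!in_domain(grid, lon, lat)) stop("point outside the grid domain")
  fx <- (lon - grid$lon[1]) / grid$dlon
  fy <- (lat - grid$lat[1]) / grid$dlat
  fx <- min(max(fx, 0), grid$nx - 1)
  fy <- min(max(fy, 0), grid$ny - 1)
  i0 <- floor(fx); j0 <- floor(fy)
  i0 <- min(i0, grid$nx - 2); j0 <- min(j0, grid$ny - 2)
  tx <- fx - i0; ty <- fy - j0
  ii <- c(i0 + 1L, i0 + 2L, i0 + 1L, i0 + 2L)
  jj <- c(j0 + 1L, j0 + 1L, j0 + 2L, j0 + 2L)
  w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  keep <- w > 0
  idx <- (jj - 1L) * grid$nx + ii
  list(idx = idx[keep], w = w[keep])
}

#' Great-circle distance between points (km)
#'
#' @param p,q Two-column `lon, lat` matrices (or length-2 vectors).
#' @return Distance(s) in kilometres (Haversine).
#' @export
gc_distance_km <- function(p, q) {
  geosphere::distHaversine(p, q) / 1000
}

# pairwise great-circle distance matrix in km between two point sets
gc_distance_matrix_km <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  out <- matrix(0, nrow(p), nrow(q))
  for (k in seq_len(nrow(q))) {
    out[, k] <- geosphere::distHaversine(p, q[k, ]) / 1000
  }
  out
}
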