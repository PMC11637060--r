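# Linear-array probe geometry and simulation grids.

#' Linear-array probe geometry
#'
#' The clinical probe emulated throughout the package: 128 elements at a
#' 0.3 mm pitch (38.4 mm aperture) with a 7 MHz centre frequency. On a
#' simulation grid the element footprint is derived from the grid spacing:
#' `round(pitch/dx)` grid points per pitch, of which one is the kerf whenever
#' the pitch covers more than one point (11 + 1 on the 0.025 mm grid,
#' 5 + 1 on the 0.05 mm reconstruction grid).
#'
#' @param n_elements number of array elements.
#' @param pitch element pitch in mm.
#' @param center_frequency transmit centre frequency in Hz.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(n_elements = 128L, pitch = 0.3,
                           center_frequency = 7e6) {
  stopifnot(n_elements >= 1, pitch > 0, center_frequency > 0)
  structure(
    list(n_elements = as.integer(n_elements), pitch = pitch,
         center_frequency = center_frequency,
         aperture = n_elements * pitch),
    class = "probe_geometry"
  )
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %d elements, pitch %.2f mm (%.1f mm aperture), fc %.2f MHz\n",
              x$n_elements, x$pitch, x$aperture, x$center_frequency / 1e6))
  invisible(x)
}

#' Simulation grid for the acoustic solver
#'
#' A square (or rectangular) grid with uniform spacing, an absorbing boundary
#' layer of at least 10 points on every edge, and a time step satisfying a
#' CFL condition against the maximum sound speed. The standard medium extent
#' is 38.4 mm per side, so `nx * dx = 38.4` for the grid families used here
#' (1536 x 0.025 mm, 512 x 0.075 mm, 256 x 0.15 mm, 128 x 0.3 mm).
#'
#' @param n grid points per side, or `c(nz, nx)`.
#' @param dx grid spacing in mm.
#' @param pml absorbing layer thickness in grid points (>= 10).
#' @param cfl CFL number (<= 0.3 recommended).
#' @param c_max maximum sound speed (m/s) used to fix the time step; fixing it
#'   globally (default 1800) keeps the solver sampling rate identical across
#'   phantoms of a dataset.
#' @return An object of class `sim_grid` with fields `nz`, `nx`, `dx` (mm),
#'   `dt` (s), `pml`, `cfl`.
#' @export
sim_grid <- function(n = 256L, dx = 38.4 / n[1], pml = 10L, cfl = 0.3,
                     c_max = 1800) {
  if (length(n) == 1L) n <- c(n, n)
  stopifnot(pml >= 10, cfl > 0, cfl <= 0.6, dx > 0)
  dt <- cfl * dx * 1e-3 / c_max
  structure(list(nz = as.integer(n[1]), nx = as.integer(n[2]), dx = dx,
                 dt = dt, pml = as.integer(pml), cfl = cfl, c_max = c_max),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d at %.4g mm (%.1f x %.1f mm), dt %.3g ns, PML %d\n",
              x$nz, x$nx, x$dx, x$nz * x$dx, x$nx * x$dx, x$dt * 1e9, x$pml))
  invisible(x)
}

# Map the probe onto a grid: returns per-element grid columns (list), the
# probe row (just inside the absorbing layer) and element centre x-positions
# in mm relative to the aperture centre.
probe_on_grid <- function(probe, grid) {
  ppp <- max(1L, as.integer(rnd(probe$pitch / grid$dx)))
  elem_pts <- if (ppp > 1L) ppp - 1L else 1L
  span <- probe$n_elements * ppp - (if (ppp > 1L) 1L else 0L)
  if (span > grid$nx) {
    stop("probe aperture (", span, " points) does not fit on grid (nx = ",
         grid$nx, ")")
  }
  offset <- (grid$nx - span) %/% 2L
  cols <- vector("list", probe$n_elements)
  for (e in seq_len(probe$n_elements)) {
    start <- offset + (e - 1L) * ppp + 1L
    cols[[e]] <- start:(start + elem_pts - 1L)
  }
  x_centres <- (seq_len(probe$n_elements) - (probe$n_elements + 1) / 2) *
    probe$pitch
  list(cols = cols, row = grid$pml + 1L, elem_pts = elem_pts, ppp = ppp,
       x_centres = x_centres)
}

# Linear index (column-major, nz rows) of a physical location given laterally
# in mm (0 = aperture centre) and in depth (mm below the probe row).
grid_index <- function(grid, probe_row, x_mm, depth_mm) {
  i <- probe_row + as.integer(rnd(depth_mm / grid$dx))
  j <- as.integer(rnd(grid$nx / 2 + 0.5 + x_mm / grid$dx))
  if (any(i < 1 | i > grid$nz | j < 1 | j > grid$nx)) {
    stop("coordinate outside the simulation grid")
  }
  (j - 1L) * grid$nz + i
}
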