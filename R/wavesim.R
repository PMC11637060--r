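# Forward acoustic simulation: tone bursts, generic propagation, single
# plane-wave pulse-echo acquisition and PA forward propagation.
#
# The solver integrates the first-order velocity-pressure system on a
# staggered grid (4th-order in space, leapfrog in time) with a graded
# absorbing sponge of >= 10 cells on all four edges. Medium attenuation
# (dB/(MHz cm)) is applied as a uniform per-step amplitude decay evaluated at
# the transmit centre frequency.

#' Windowed tone burst
#'
#' A sinusoid at the transmit centre frequency under a Hann window spanning
#' `n_cycles` cycles (the pulse used for single-plane-wave transmissions is a
#' 2-cycle burst at 7 MHz).
#'
#' @param fc centre frequency in Hz.
#' @param n_cycles number of cycles (duration `n_cycles / fc`).
#' @param fs sampling rate in Hz; must exceed `2 * fc`.
#' @return An object of class `waveform`: numeric samples with attributes
#'   `sample_rate` and `fc`.
#' @export
tone_burst <- function(fc, n_cycles, fs) {
  if (fs <= 2 * fc) stop("sampling rate must exceed twice the centre frequency")
  n <- round(n_cycles / fc * fs)
  if (n < 1) {
    s <- numeric(0)
  } else {
    t <- (seq_len(n) - 0.5) / fs
    w <- 0.5 * (1 - cos(2 * pi * t * fc / n_cycles))
    s <- sin(2 * pi * fc * t) * w
    s <- s - mean(s)
  }
  structure(s, sample_rate = fs, fc = fc, class = "waveform")
}

#' RF channel frame
#'
#' @param data channels x samples matrix.
#' @param sample_rate sampling rate in Hz.
#' @param transmit `"plane_wave"` or `"pa_passive"`.
#' @param t0 time of the first sample in seconds.
#' @param meta optional list of provenance metadata.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(data, sample_rate, transmit = "plane_wave", t0 = 0,
                     meta = list()) {
  stopifnot(is.matrix(data), all(is.finite(data)), sample_rate > 0)
  transmit <- match.arg(transmit, c("plane_wave", "pa_passive"))
  structure(list(data = data, sample_rate = sample_rate, transmit = transmit,
                 t0 = t0, meta = meta),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame:%s> %d channels x %d samples at %.3g MHz\n",
              x$transmit, nrow(x$data), ncol(x$data), x$sample_rate / 1e6))
  invisible(x)
}

# graded absorbing sponge: per-cell multiplicative decay, quadratic profile
build_sponge <- function(nz, nx, pml, strength = 0.35) {
  prof <- function(n) {
    w <- rep(1, n)
    d <- seq_len(pml)
    taper <- exp(-strength * ((pml - d + 1) / pml)^2)
    w[d] <- taper
    w[n - d + 1L] <- taper
    w
  }
  outer(prof(nz), prof(nx), pmin)
}

# per-step absorption factor from dB/(MHz cm) attenuation at frequency fc
absorption_factor <- function(medium, fc, dt) {
  alpha_db_m <- medium$attenuation * (fc / 1e6) * 100   # dB per metre at fc
  alpha_np_m <- alpha_db_m / 8.685889638                # Nepers per metre
  exp(-alpha_np_m * medium$sos * dt)
}

# stagger-averaged inverse densities
half_grid_inv_rho <- function(rho) {
  nz <- nrow(rho); nx <- ncol(rho)
  rx <- rho
  rx[, seq_len(nx - 1)] <- 0.5 * (rho[, seq_len(nx - 1)] + rho[, 2:nx])
  rz <- rho
  rz[seq_len(nz - 1), ] <- 0.5 * (rho[seq_len(nz - 1), ] + rho[2:nz, ])
  list(x = 1 / rx, z = 1 / rz)
}

#' Propagate acoustic waves through a heterogeneous medium
#'
#' Generic driver for the staggered-grid solver. Supports three source modes:
#' an initial pressure field released at `t = 0` (PA forward), an additive
#' time-varying pressure source at given grid indices (pulse-echo transmit),
#' and a Dirichlet pressure condition enforcing recorded traces at the sensor
#' line (time reversal).
#'
#' @param medium an [acoustic_medium()].
#' @param grid a [sim_grid()] matching the medium shape.
#' @param t_end simulated time in seconds (determines the step count).
#' @param p0 optional initial pressure matrix.
#' @param source_idx integer grid indices of source points (column-major).
#' @param source_sig numeric vector (recycled over points, additive mode) or
#'   `nt x n_src` matrix of per-point signals at the solver rate.
#' @param source_mode `"none"`, `"additive"` or `"dirichlet"`.
#' @param sensor_idx integer grid indices recorded at every step.
#' @param fc frequency (Hz) at which the attenuation law is evaluated.
#' @param record_energy if `TRUE`, the per-step total squared pressure is
#'   returned (used to verify the absorbing boundary).
#' @return A list with `rf` (sensors x steps matrix at the solver rate),
#'   `p_final` (pressure field after the last step), `dt`, and optionally
#'   `energy`.
#' @export
propagate <- function(medium, grid, t_end, p0 = NULL, source_idx = integer(),
                      source_sig = numeric(), source_mode = "none",
                      sensor_idx = integer(), fc = 7e6,
                      record_energy = FALSE) {
  if (!all(medium$shape == c(grid$nz, grid$nx))) {
    stop("medium and grid shapes disagree")
  }
  if (grid$dt > grid$cfl * grid$dx * 1e-3 / max(medium$sos) + 1e-15) {
    stop("time step violates the CFL condition for this medium")
  }
  source_mode <- match.arg(source_mode, c("none", "additive", "dirichlet"))
  nt <- as.integer(ceiling(t_end / grid$dt))
  mode_code <- match(source_mode, c("none", "additive", "dirichlet")) - 1L
  if (mode_code > 0L) {
    if (is.matrix(source_sig)) {
      sig <- source_sig
    } else {
      sig <- matrix(as.numeric(source_sig), ncol = 1L)
    }
    if (nrow(sig) < nt) {
      sig <- rbind(sig, matrix(0, nt - nrow(sig), ncol(sig)))
    } else if (nrow(sig) > nt) {
      sig <- sig[seq_len(nt), , drop = FALSE]
    }
    if (mode_code == 2L && ncol(sig) != length(source_idx)) {
      stop("dirichlet sources need one signal column per source point")
    }
  } else {
    sig <- matrix(0, nt, 1L)
  }
  if (is.null(p0)) p0 <- matrix(0, grid$nz, grid$nx)
  inv_rho <- half_grid_inv_rho(medium$density)
  res <- .fdtd_run(
    c2rho = medium$density * medium$sos^2,
    inv_rho_x = inv_rho$x, inv_rho_z = inv_rho$z,
    sponge = build_sponge(grid$nz, grid$nx, grid$pml),
    damp = absorption_factor(medium, fc, grid$dt),
    p0 = p0,
    source_idx = as.integer(source_idx) - 1L,
    source_sig = sig, source_mode = mode_code,
    sensor_idx = as.integer(sensor_idx) - 1L,
    dt = grid$dt, dx = grid$dx * 1e-3, nt = nt,
    record_energy = record_energy
  )
  if (any(!is.finite(res$p_final))) {
    stop("numerical instability: non-finite field values")
  }
  res$dt <- grid$dt
  res
}

# average sensor-point traces over each element's grid points -> 128 x nt
aggregate_elements <- function(rf_points, pg) {
  n_el <- length(pg$cols)
  lens <- lengths(pg$cols)
  out <- matrix(0, n_el, ncol(rf_points))
  pos <- 1L
  for (e in seq_len(n_el)) {
    rows <- pos:(pos + lens[e] - 1L)
    out[e, ] <- if (length(rows) > 1L) colMeans(rf_points[rows, , drop = FALSE])
                else rf_points[rows, ]
    pos <- pos + lens[e]
  }
  out
}

#' Single-plane-wave pulse-echo acquisition
#'
#' All probe elements are excited simultaneously (0 degree steering) with the
#' transmit burst; the backscattered field is recorded per element at the
#' solver rate with no receive focusing. Element recordings average the
#' pressure over each element's grid points.
#'
#' @param medium an [acoustic_medium()].
#' @param probe a [probe_geometry()].
#' @param burst a [tone_burst()]; it is resampled to the solver rate if
#'   needed.
#' @param grid a [sim_grid()].
#' @param t_end recorded time in seconds (default 51.2 us, the two-way time
#'   of the full 38.4 mm depth at ~1500 m/s recorded as 1024 samples at
#'   20 MHz).
#' @return An [rf_frame()] (`transmit = "plane_wave"`) at the solver rate.
#' @export
plane_wave_pulse_echo <- function(medium, probe, burst = NULL, grid,
                                  t_end = 51.2e-6) {
  pg <- probe_on_grid(probe, grid)
  if (is.null(burst)) {
    burst <- tone_burst(probe$center_frequency, 2, 1 / grid$dt)
  }
  sig <- resample_waveform(burst, 1 / grid$dt)
  pts <- probe_point_indices(pg, grid)
  res <- propagate(medium, grid, t_end, source_idx = pts,
                   source_sig = as.numeric(sig), source_mode = "additive",
                   sensor_idx = pts, fc = attr(burst, "fc") %||% probe$center_frequency)
  rf_frame(aggregate_elements(res$rf, pg), sample_rate = 1 / res$dt,
           transmit = "plane_wave",
           meta = list(grid_n = c(grid$nz, grid$nx), dx = grid$dx,
                       fc = attr(burst, "fc")))
}

#' PA forward propagation from an initial pressure field
#'
#' Releases the initial pressure distribution at `t = 0` and records the
#' pressure at the probe elements, using the same forward model as the
#' time-reversal reconstruction.
#'
#' @inheritParams plane_wave_pulse_echo
#' @param p0 initial pressure matrix shaped to the grid.
#' @param fc frequency at which the attenuation law is evaluated (Hz).
#' @return An [rf_frame()] (`transmit = "pa_passive"`) at the solver rate.
#' @export
pa_forward <- function(medium, p0, probe, grid, t_end = 51.2e-6, fc = 7e6) {
  stopifnot(all(dim(p0) == medium$shape))
  pg <- probe_on_grid(probe, grid)
  pts <- probe_point_indices(pg, grid)
  res <- propagate(medium, grid, t_end, p0 = p0, sensor_idx = pts, fc = fc)
  rf_frame(aggregate_elements(res$rf, pg), sample_rate = 1 / res$dt,
           transmit = "pa_passive",
           meta = list(grid_n = c(grid$nz, grid$nx), dx = grid$dx, fc = fc))
}

# linear indices of all element grid points, in element order
probe_point_indices <- function(pg, grid) {
  unlist(lapply(pg$cols, function(cols) (cols - 1L) * grid$nz + pg$row))
}

# resample a waveform to a target rate by cubic spline
resample_waveform <- function(w, fs_out) {
  fs_in <- attr(w, "sample_rate")
  if (is.null(fs_in) || abs(fs_in - fs_out) < 1e-9 * fs_out) {
    return(as.numeric(w))
  }
  n_in <- length(w)
  if (n_in == 0L) return(numeric(0))
  t_in <- (seq_len(n_in) - 0.5) / fs_in
  t_out <- seq(0.5 / fs_out, t_in[n_in], by = 1 / fs_out)
  spline(t_in, as.numeric(w), xout = t_out, method = "natural")$y
}
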