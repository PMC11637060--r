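# Time-reversal PA image reconstruction with a constant or pixel-wise sound
# speed. The reference reconstruction grid is 788 (Z) x 768 (X) at 0.05 mm
# (768 interior rows plus 10 absorbing points at the probe edge and its
# opposite), with the probe mapped at 5 grid points per element + 1 kerf.
# Scaled-down grids keep the same geometry at a coarser spacing.

#' Reconstructed PA image
#'
#' @param values matrix of reconstructed initial pressure (arbitrary units;
#'   negative lobes are retained until display normalization).
#' @param pixel_size pixel size in mm.
#' @param sos_source `"constant"`, `"autofocus"`, `"dl"` or `"ground_truth"`.
#' @param meta provenance list.
#' @return An object of class `pa_image`.
#' @export
pa_image <- function(values, pixel_size = 0.05, sos_source = "constant",
                     meta = list()) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  sos_source <- match.arg(sos_source,
                          c("constant", "autofocus", "dl", "ground_truth"))
  structure(list(values = values, pixel_size = pixel_size,
                 sos_source = sos_source, meta = meta),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image:%s> %d x %d at %.3g mm\n", x$sos_source,
              nrow(x$values), ncol(x$values), x$pixel_size))
  invisible(x)
}

#' Normalized intensity of a PA image
#'
#' Maps an image to `[0, 1]` by the maximum absolute value (identically zero
#' images stay zero). Intensity thresholds (e.g. the 0.35 signal/background
#' split of the SNR metric) presume this normalization.
#'
#' @param img a [pa_image()] or matrix.
#' @return A matrix of normalized intensities in `[0, 1]`.
#' @export
pa_intensity <- function(img) {
  v <- if (inherits(img, "pa_image")) img$values else img
  m <- max(abs(v))
  if (m == 0) return(abs(v))
  abs(v) / m
}

#' Resample an RF frame to the reconstruction layout
#'
#' Maps 128 x 1024 acquisition RF to 640 x 4096: the channel axis is
#' interpolated by a factor of 5 (matching the 5 grid points per element of
#' the reconstruction grid) with a cubic spline, and the time axis by a
#' factor of 4 with exact band-limited (FFT zero-padding) interpolation.
#'
#' @param rf an [rf_frame()] or 128 x 1024 matrix at 20 MHz.
#' @return An [rf_frame()] of shape 640 x 4096 at 80 MHz.
#' @export
upsample_rf <- function(rf) {
  x <- if (inherits(rf, "rf_frame")) rf$data else rf
  fs <- if (inherits(rf, "rf_frame")) rf$sample_rate else 20e6
  if (!all(dim(x) == c(128L, 1024L))) {
    stop("expected a 128 x 1024 RF frame, got ",
         paste(dim(x), collapse = " x "))
  }
  xt <- t(apply(x, 1, fft_interp, factor = 4L))
  n_in <- 128L; n_out <- 640L
  ch_in <- seq_len(n_in)
  ch_out <- seq(0.5 + 0.1, n_in + 0.5 - 0.1, length.out = n_out)
  out <- apply(xt, 2, function(col) {
    spline(ch_in, col, xout = pmin(pmax(ch_out, 1), n_in),
           method = "natural")$y
  })
  rf_frame(out, sample_rate = fs * 4,
           transmit = if (inherits(rf, "rf_frame")) rf$transmit else "pa_passive",
           meta = list(upsampled = TRUE))
}

# band-limited interpolation by spectral zero padding
fft_interp <- function(x, factor) {
  n <- length(x)
  X <- fft(x)
  m <- n * factor
  Y <- complex(m)
  half <- n %/% 2
  if (n %% 2 == 0) {
    Y[1:half] <- X[1:half]
    Y[(m - half + 2):m] <- X[(half + 2):n]
    # split the Nyquist bin symmetrically
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
  } else {
    Y[1:(half + 1)] <- X[1:(half + 1)]
    Y[(m - half + 1):m] <- X[(half + 2):n]
  }
  # unnormalized inverse FFT over m = n * factor points: dividing by n keeps
  # the time-domain amplitude
  Re(fft(Y, inverse = TRUE)) / n
}

#' Interpolate a SoS map onto the reconstruction grid
#'
#' Bilinear upsampling of a 384 x 384 SoS estimate (or label) to 768 x 768
#' pixels; constant maps are preserved exactly and no overshoot is introduced.
#'
#' @param map a [sos_map()] or matrix in m/s.
#' @param size output side length (default 768).
#' @return A `size x size` matrix in m/s.
#' @export
interpolate_sos_map <- function(map, size = 768L) {
  v <- unclass(map)
  attributes(v) <- list(dim = dim(map))
  if (any(!is.finite(v))) stop("non-finite values in SoS map")
  resize_field(v, size, size)
}

#' Zero the first time steps of PA RF data
#'
#' Early samples are dominated by source-induced system noise; the acquisition
#' convention zeroes the first 150 of 1024 samples. When applied after time
#' resampling, `n` scales with the resampling factor (150 -> 600 after the
#' 4x upsampling).
#'
#' @param rf an [rf_frame()] or matrix.
#' @param n number of leading time samples to zero at the 1024-sample layout.
#' @param upsampled if `TRUE`, `n` is scaled by 4 for the 4096-sample layout.
#' @return The modified input (same class).
#' @export
zero_first_time_steps <- function(rf, n = 150L, upsampled = FALSE) {
  n_eff <- if (upsampled) 4L * n else n
  if (inherits(rf, "rf_frame")) {
    zero_early_samples(rf, n_eff)
  } else {
    if (n_eff >= ncol(rf)) stop("n must be smaller than the sample count")
    rf[, seq_len(n_eff)] <- 0
    rf
  }
}

#' Reconstruction grid for time reversal
#'
#' @param dx grid spacing in mm (0.05 for the reference 788 x 768 grid).
#' @param pml absorbing layer thickness (10 points).
#' @param cfl CFL number.
#' @param c_max maximum admissible sound speed for the time step.
#' @return A [sim_grid()] with `nz = nx_interior + 2*pml` rows.
#' @export
recon_grid <- function(dx = 0.05, pml = 10L, cfl = 0.3, c_max = 1800) {
  nx <- as.integer(rnd(38.4 / dx))
  sim_grid(c(nx + 2L * pml, nx), dx = dx, pml = pml, cfl = cfl, c_max = c_max)
}

#' Time-reversal PA reconstruction
#'
#' Re-emits the time-reversed sensor traces as a Dirichlet pressure condition
#' on the transducer line of a simulated medium parameterized by the supplied
#' sound speed (scalar or pixel-wise field), and returns the interior field
#' after the last (i.e. `t = 0`) step, cropped to the square imaging region.
#' Positivity is not enforced.
#'
#' @param rf a 640 x 4096 [rf_frame()] from [upsample_rf()] (80 MHz), or any
#'   `n_src x n_t` frame whose channels correspond to equally spaced
#'   sub-element positions across the aperture.
#' @param sos scalar sound speed (m/s) or a square matrix covering the
#'   interior imaging region (768 x 768 at the reference resolution; it is
#'   resampled to the grid if needed).
#' @param probe a [probe_geometry()].
#' @param grid a [recon_grid()].
#' @param sos_source provenance tag stored in the image.
#' @return A [pa_image()] of the interior region (`nx x nx`).
#' @export
time_reversal <- function(rf, sos, probe = probe_geometry(),
                          grid = recon_grid(), sos_source = "constant") {
  x <- if (inherits(rf, "rf_frame")) rf$data else rf
  fs <- if (inherits(rf, "rf_frame")) rf$sample_rate else 80e6
  nxi <- grid$nx
  if (is.matrix(sos)) {
    if (any(!is.finite(sos)) || any(sos <= 0)) {
      stop("sos field must be positive and finite")
    }
    sos_int <- if (all(dim(sos) == c(nxi, nxi))) sos else
      resize_field(sos, nxi, nxi)
  } else {
    if (sos <= 0) stop("sos must be positive")
    sos_int <- matrix(sos, nxi, nxi)
  }
  if (max(sos_int) > grid$c_max) {
    stop("sos exceeds the grid's stability bound; rebuild recon_grid with a larger c_max")
  }
  # embed interior field into the full grid (replicate rows into the PML)
  full <- matrix(0, grid$nz, grid$nx)
  full[(grid$pml + 1L):(grid$pml + nxi), ] <- sos_int
  full[seq_len(grid$pml), ] <- rep(sos_int[1, ], each = grid$pml)
  full[(grid$pml + nxi + 1L):grid$nz, ] <- rep(sos_int[nxi, ],
                                               each = grid$pml)
  medium <- acoustic_medium(sos = full, dx = grid$dx)

  pg <- probe_on_grid(probe, grid)
  pts <- probe_point_indices(pg, grid)
  # map the n_src traces onto the element grid points: both are equally
  # spaced across the aperture, so snap each trace to the nearest point and
  # average traces sharing a point
  n_src <- nrow(x)
  src_pos <- seq(0, 1, length.out = n_src)
  pt_pos <- seq(0, 1, length.out = length(pts))
  assign_pt <- vapply(src_pos, function(p) which.min(abs(pt_pos - p)), 1L)
  traces <- matrix(0, length(pts), ncol(x))
  counts <- tabulate(assign_pt, nbins = length(pts))
  for (k in seq_len(n_src)) {
    traces[assign_pt[k], ] <- traces[assign_pt[k], ] + x[k, ]
  }
  nonzero <- counts > 0
  traces[nonzero, ] <- traces[nonzero, ] / counts[nonzero]

  # reverse in time and interpolate to the solver step
  t_end <- ncol(x) / fs
  nt <- as.integer(ceiling(t_end / grid$dt))
  t_rev <- (seq_len(nt) - 1) * grid$dt
  src_t <- (seq_len(ncol(x)) - 0.5) / fs
  sig <- matrix(0, nt, length(pts))
  rev_idx <- rev(seq_len(ncol(x)))
  for (k in seq_len(length(pts))) {
    if (!nonzero[k]) next
    sig[, k] <- approx(src_t, traces[k, rev_idx], xout = t_rev, rule = 2)$y
  }
  res <- propagate(medium, grid, t_end, source_idx = pts, source_sig = sig,
                   source_mode = "dirichlet", fc = probe$center_frequency)
  interior <- res$p_final[(grid$pml + 1L):(grid$pml + nxi), ]
  pa_image(interior, pixel_size = grid$dx, sos_source = sos_source,
           meta = list(grid_n = c(grid$nz, grid$nx), dx = grid$dx,
                       fs = fs))
}

#' Project a forward-grid initial pressure onto image coordinates
#'
#' Reconstructed images use probe-relative coordinates (row 1 = transducer
#' line), while forward-simulation fields include the absorbing boundary rows
#' above the probe. This crops the boundary rows, rescales to the
#' reconstruction pixel size and pads to the square image shape so that a
#' simulated initial pressure can serve as a reference for reconstruction
#' metrics.
#'
#' @param p0 initial pressure matrix on the forward grid.
#' @param grid the forward [sim_grid()].
#' @param rg the [recon_grid()] of the reconstruction.
#' @return An `rg$nx` x `rg$nx` matrix in image coordinates.
#' @export
project_p0 <- function(p0, grid, rg = recon_grid(grid$dx)) {
  crop <- p0[(grid$pml + 1L):grid$nz, , drop = FALSE]
  nz_px <- as.integer(rnd(nrow(crop) * grid$dx / rg$dx))
  nx_px <- as.integer(rnd(ncol(crop) * grid$dx / rg$dx))
  r <- if (nz_px == nrow(crop) && nx_px == ncol(crop)) crop else
    resize_field(crop, nz_px, nx_px)
  out <- matrix(0, rg$nx, rg$nx)
  iz <- seq_len(min(rg$nx, nz_px))
  ix <- seq_len(min(rg$nx, nx_px))
  off <- (rg$nx - length(ix)) %/% 2L
  out[iz, off + ix] <- r[iz, ix]
  out
}

#' Full PA reconstruction pipeline from acquisition RF
#'
#' Composes the reconstruction stages: early-time zeroing, resampling of the
#' 128 x 1024 frame to 640 x 4096, interpolation of the SoS map (when a map
#' is supplied) and time reversal. The SoS provenance is recorded in the
#' returned image.
#'
#' @param rf_raw 128 x 1024 [rf_frame()] (or matrix) at 20 MHz.
#' @param sos_spec a scalar SoS in m/s, a [sos_map()] or a plain matrix.
#' @param probe a [probe_geometry()].
#' @param grid a [recon_grid()].
#' @param n_zero leading samples zeroed at the 1024-sample layout.
#' @param sos_source provenance tag; defaults to `"constant"` for scalars and
#'   to the map role otherwise.
#' @param t_max optional recording horizon in seconds: trailing samples
#'   beyond it are dropped before time reversal, shortening the solve when
#'   all sources are shallow.
#' @return A [pa_image()].
#' @export
reconstruct <- function(rf_raw, sos_spec, probe = probe_geometry(),
                        grid = recon_grid(), n_zero = 150L,
                        sos_source = NULL, t_max = NULL) {
  if (!inherits(rf_raw, "rf_frame")) {
    rf_raw <- rf_frame(rf_raw, 20e6, transmit = "pa_passive")
  }
  rf_raw <- zero_first_time_steps(rf_raw, n_zero)
  rf_up <- upsample_rf(rf_raw)
  if (!is.null(t_max)) {
    n_keep <- min(ncol(rf_up$data), ceiling(t_max * rf_up$sample_rate))
    rf_up$data <- rf_up$data[, seq_len(n_keep), drop = FALSE]
  }
  if (is.matrix(sos_spec) || inherits(sos_spec, "sos_map")) {
    src <- sos_source %||%
      (if (identical(attr(sos_spec, "role"), "ground_truth")) "ground_truth"
       else "dl")
    field <- interpolate_sos_map(sos_spec, size = grid$nx)
    time_reversal(rf_up, field, probe, grid, sos_source = src)
  } else {
    time_reversal(rf_up, as.numeric(sos_spec), probe, grid,
                  sos_source = sos_source %||% "constant")
  }
}
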