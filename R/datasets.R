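# End-to-end dataset generation: phantom -> rasterized medium -> pulse-echo
# simulation -> conditioned 128 x 1024 RF frame + 384 x 384 SoS label, plus
# optional PA point-source acquisition for reconstruction studies.

#' Simulation profile
#'
#' Bundles the grids, probe and conditioning settings of a simulation
#' campaign. The full-scale profile reproduces the reference setup (1536^2
#' medium at 0.025 mm, 7 MHz transmit, 788 x 768 reconstruction grid at
#' 0.05 mm). The desk profile keeps the same 38.4 mm geometry on coarser
#' grids with the transmit frequency scaled to preserve at least five grid
#' points per wavelength, so that whole-dataset builds and reconstruction
#' sweeps run on a single CPU.
#'
#' @param grid_n medium grid points per side.
#' @param fc transmit centre frequency in Hz.
#' @param recon_dx reconstruction grid spacing in mm.
#' @param t_end recorded time in seconds.
#' @param snr_range thermal-noise SNR bounds in dB (see
#'   [add_thermal_noise()]).
#' @param n_cycles transmit burst length in cycles (default 2).
#' @param use_system_noise whether to inject synthetic system noise.
#' @param autofocus_step sweep step of the autofocus baseline in m/s.
#' @return A named list of simulation settings.
#' @export
sim_profile <- function(grid_n = 1536L, fc = 7e6, recon_dx = 0.05,
                        t_end = 51.2e-6, snr_range = c(40, 80),
                        use_system_noise = TRUE, autofocus_step = 5,
                        n_cycles = 2) {
  dx <- 38.4 / grid_n
  list(grid = sim_grid(grid_n, dx),
       probe = probe_geometry(center_frequency = fc),
       fc = fc,
       recon = recon_grid(recon_dx),
       t_end = t_end,
       snr_range = snr_range,
       n_cycles = n_cycles,
       use_system_noise = use_system_noise,
       autofocus_step = autofocus_step,
       n_zero_us = 50L,
       n_zero_pa = 150L)
}

#' Desk-scale simulation profile
#'
#' 128^2 medium grid at 0.3 mm with a 1 MHz transmit (6.2 mm wavelength at
#' the lowest background SoS, i.e. >= 4.7 points per wavelength; 1 MHz
#' carries the same two-cycle burst shape as the full-scale 7 MHz transmit),
#' and a matching 148 x 128 reconstruction grid at 0.3 mm.
#'
#' @param grid_n medium grid side (default 128).
#' @param fc transmit frequency (default 1 MHz).
#' @param ... further arguments passed to [sim_profile()].
#' @return A simulation profile list.
#' @export
desk_profile <- function(grid_n = 128L, fc = 1e6, ...) {
  sim_profile(grid_n = grid_n, fc = fc, recon_dx = 38.4 / grid_n, ...)
}

#' Simulate the acquisition of one phantom
#'
#' Rasterizes the spec, applies echogenicity and scatterer fields, runs the
#' single-plane-wave pulse-echo simulation and conditions the RF into the
#' network-ready 128 x 1024 frame; optionally also simulates PA acquisition
#' from point sources with the same forward model used for reconstruction.
#'
#' @param spec a [phantom_spec()].
#' @param sim a [sim_profile()] / [desk_profile()] list.
#' @param seed integer seed for the stochastic stages.
#' @param pa_sources optional matrix of `(x, z)` point-source positions (mm,
#'   probe-relative); disks of `pa_radius_mm` are rasterized when positive.
#' @param pa_radius_mm PA absorber radius in mm (0 = single pixel, smoothed
#'   point sources use `pa_sigma_cells`).
#' @param pa_sigma_cells when > 0, point sources are Gaussian blobs of this
#'   width (in grid cells) instead of binary pixels, keeping them
#'   band-limited on the simulation grid.
#' @param condition whether to condition the US RF (TGC, downsampling, noise,
#'   normalization) or return it raw.
#' @return A list with `medium`, `label` ([sos_map()]), `rf` (conditioned
#'   128 x 1024 [rf_frame()]), and when PA sources are given `pa_rf`
#'   (128 x 1024 PA frame at 20 MHz), `p0` (initial pressure on the medium
#'   grid) and `sos_field_recon` (true SoS resampled for reconstruction).
#' @export
simulate_phantom_rf <- function(spec, sim = desk_profile(), seed = spec$rng_seed,
                                pa_sources = NULL, pa_radius_mm = 0,
                                pa_sigma_cells = 2, condition = TRUE) {
  medium <- rasterize_medium(spec, sim$grid)
  medium <- apply_echogenicity(medium, seed = seed)
  medium <- sprinkle_scatterers(medium, seed = seed, fc = sim$fc)$medium
  label <- label_from_medium(medium)

  burst <- tone_burst(sim$fc, sim$n_cycles %||% 2, 1 / sim$grid$dt)
  rf_raw <- plane_wave_pulse_echo(medium, sim$probe, burst, sim$grid,
                                  t_end = sim$t_end)
  rf <- if (condition) {
    bank <- if (isTRUE(sim$use_system_noise)) {
      make_noise_bank(seed = substream_seed(seed, "bank"), fc = sim$fc)
    } else NULL
    condition_rf(rf_raw, tgc_fc = sim$fc, noise_bank = bank,
                 snr_range = sim$snr_range, seed = seed)
  } else rf_raw

  out <- list(medium = medium, label = label, rf = rf, spec = spec)

  if (!is.null(pa_sources)) {
    p0 <- place_point_absorbers(pa_sources, sim$grid, radius_mm = pa_radius_mm)
    if (pa_radius_mm <= 0 && pa_sigma_cells > 0) {
      p0 <- smooth_field(p0, pa_sigma_cells)
      p0 <- p0 / max(p0)
    }
    pa_raw <- pa_forward(medium, p0, sim$probe, sim$grid,
                         t_end = sim$t_end, fc = sim$fc)
    out$pa_rf <- downsample_to_20mhz(pa_raw)
    out$p0 <- p0
    out$sos_field_recon <- resize_field(medium$sos_bulk, sim$recon$nx,
                                        sim$recon$nx)
  }
  out
}

# separable gaussian smoothing (reflecting edges), sigma in cells
smooth_field <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
  sm1 <- function(v) stats::filter(pad(v), k)[(r + 1):(r + length(v))]
  m2 <- apply(m, 2, sm1)
  t(apply(t(m2), 2, sm1))
}

#' Build a training dataset of RF frames and SoS labels
#'
#' Samples phantoms, simulates and conditions their pulse-echo acquisition
#' and collects `(rf, label)` pairs for network training. Phantom geometry,
#' speckle and noise substreams all derive from `seed`.
#'
#' @param n number of phantoms.
#' @param seed integer top-level seed.
#' @param sim a [sim_profile()] list.
#' @param config generation bounds ([phantom_gen_config()]); pass
#'   `n_inclusions = c(0, 0)` for homogeneous-only datasets.
#' @param progress print a dot per phantom.
#' @return A list of class `rf_dataset`: `rf` (N x 128 x 1024 array),
#'   `labels` (N x 384 x 384 array), `specs` (list), `seed`, `sim_settings`.
#' @export
simulate_rf_dataset <- function(n, seed = 1L, sim = desk_profile(),
                                config = phantom_gen_config(),
                                progress = FALSE) {
  rf <- array(0, dim = c(n, 128L, 1024L))
  labels <- array(0, dim = c(n, 384L, 384L))
  specs <- vector("list", n)
  for (k in seq_len(n)) {
    s <- substream_seed(seed, paste0("phantom-", k))
    spec <- sample_training_phantom(s, config)
    prep <- simulate_phantom_rf(spec, sim, seed = s)
    rf[k, , ] <- prep$rf$data
    labels[k, , ] <- prep$label
    specs[[k]] <- spec
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(rf = rf, labels = labels, specs = specs, seed = seed,
                 sim_settings = sim[c("fc", "t_end", "snr_range")]),
            class = "rf_dataset")
}

#' @export
print.rf_dataset <- function(x, ...) {
  cat(sprintf("<rf_dataset> %d frames (128 x 1024) with 384 x 384 labels, seed %d\n",
              dim(x$rf)[1], x$seed))
  invisible(x)
}
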