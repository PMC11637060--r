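# Shared fixtures, built once per test session and cached. All simulations
# use the desk-scale geometry (38.4 mm medium on coarse grids with the
# transmit frequency scaled to keep >= 5 grid points per wavelength).

.fx <- new.env(parent = emptyenv())

fx_cache <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# homogeneous 1500 m/s medium on a 128^2 grid
fx_grid128 <- function() sim_grid(128)

fx_probe1mhz <- function() probe_geometry(center_frequency = 1e6)

fx_homog_medium <- function(c0 = 1500, n = 128) {
  acoustic_medium(sos = matrix(c0, n, n), dx = 38.4 / n)
}

# Gaussian-blob initial pressure at probe-relative (x, z) mm
fx_blob_p0 <- function(grid, x_mm, z_mm, sigma_cells = 2) {
  p0 <- place_point_absorbers(cbind(x_mm, z_mm), grid)
  p0 <- pasos:::smooth_field(p0, sigma_cells)
  p0 / max(p0)
}

# PA acquisition of a single blob at (3, 12) mm in homogeneous 1500 m/s,
# desk 128^2 grid; returns the 20 MHz 128 x 1024 frame plus geometry
fx_point_pa <- function() {
  fx_cache("point_pa", function() {
    grid <- fx_grid128()
    probe <- fx_probe1mhz()
    med <- fx_homog_medium()
    p0 <- fx_blob_p0(grid, 3, 12)
    rf <- downsample_to_20mhz(
      pa_forward(med, p0, probe, grid, t_end = 51.2e-6, fc = 1e6))
    list(rf = rf, grid = grid, probe = probe, p0 = p0, src = c(3, 12))
  })
}

# plane-wave pulse-echo of a speckle phantom (homogeneous 1480 background)
fx_speckle_pe <- function() {
  fx_cache("speckle_pe", function() {
    grid <- fx_grid128()
    probe <- fx_probe1mhz()
    spec <- phantom_spec(1480, rng_seed = 42L)
    med <- sprinkle_scatterers(rasterize_medium(spec, grid), fc = 1e6)$medium
    burst <- tone_burst(1e6, 2, 1 / grid$dt)
    rf <- plane_wave_pulse_echo(med, probe, burst, grid, t_end = 51.2e-6)
    list(rf = rf, grid = grid, probe = probe, spec = spec)
  })
}

# tiny network configuration (same topology, minimal widths)
fx_tiny_cfg <- function() sosnet_config_small(width_scale = 128)

# small homogeneous-background RF dataset for learning tests
fx_tiny_dataset <- function(n = 6) {
  fx_cache(paste0("tinyds", n), function() {
    simulate_rf_dataset(n, seed = 11, sim = desk_profile(),
                        config = phantom_gen_config(n_inclusions = c(0L, 0L)))
  })
}

expect_within <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected), tol)
}
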