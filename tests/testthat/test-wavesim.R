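# Acoustic forward solver: tone bursts, travel times, boundary absorption,
# reciprocity, scattering linearity.

test_that("tone burst has the stated duration, zero mean and spectral peak", {
  b <- tone_burst(7e6, 2, 100e6)
  expect_equal(length(b), round(2 / 7e6 * 100e6))
  expect_lt(abs(mean(b)), 1e-12)
  expect_true(all(is.finite(b)))
  # spectral peak at fc within one FFT bin
  n <- 4096
  s <- c(as.numeric(b), numeric(n - length(b)))
  spec <- Mod(fft(s))[1:(n / 2)]
  f_peak <- (which.max(spec) - 1) * 100e6 / n
  expect_lt(abs(f_peak - 7e6), 100e6 / length(b) + 100e6 / n)
  expect_length(tone_burst(7e6, 0, 100e6), 0)
  expect_error(tone_burst(7e6, 2, 10e6), "twice")
})

test_that("zero sources produce identically zero RF", {
  grid <- sim_grid(64, 38.4 / 64)
  med <- acoustic_medium(sos = matrix(1500, 64, 64), dx = grid$dx)
  res <- propagate(med, grid, 10e-6, sensor_idx = c(2000L, 3000L))
  expect_true(all(res$rf == 0))
  expect_true(all(res$p_final == 0))
})

test_that("point-source travel time matches distance / sound speed", {
  fx <- fx_point_pa()
  pg <- pasos:::probe_on_grid(fx$probe, fx$grid)
  e <- which.min(abs(pg$x_centres - fx$src[1]))
  t_arr <- arrival_time(fx$rf$data[e, ], fx$rf$sample_rate, "peak")
  expect_lt(abs(t_arr - fx$src[2] * 1e-3 / 1500), 2 / fx$rf$sample_rate)
})

test_that("absorbing boundary removes in-grid energy after the wave exits", {
  grid <- sim_grid(128)
  med <- fx_homog_medium()
  p0 <- fx_blob_p0(grid, 0, 19.2, sigma_cells = 3)
  res <- propagate(med, grid, 60e-6, p0 = p0, record_energy = TRUE,
                   fc = 1e6)
  expect_lt(tail(res$energy, 1) / max(res$energy), 0.01)
})

test_that("reciprocity: swapping point source and receiver preserves the trace", {
  # for the variable-c wave operator, the Green's function between a
  # point mass injection and a pressure receiver is symmetric once the
  # recorded trace is weighted by c^2 at the source location
  grid <- sim_grid(128)
  spec <- phantom_spec(1500,
                       layers = list(layer_inclusion(z_top = 16, sos = 1560)),
                       rng_seed = 8L)
  med <- rasterize_medium(spec, grid)
  a <- grid_index(grid, grid$pml + 1L, -6, 8)
  b <- grid_index(grid, grid$pml + 1L, 7, 24)
  s <- tone_burst(0.7e6, 2, 1 / grid$dt)
  run <- function(src, rec) {
    propagate(med, grid, 40e-6, source_idx = src,
              source_sig = as.numeric(s), source_mode = "additive",
              sensor_idx = rec, fc = 0.7e6)$rf[1, ]
  }
  r_ab <- run(a, b) * med$sos[a]^2
  r_ba <- run(b, a) * med$sos[b]^2
  rel <- sqrt(mean((r_ab - r_ba)^2)) / sqrt(mean(r_ab^2))
  expect_lt(rel, 0.01)
})

test_that("scatterer-free homogeneous medium yields no backscatter", {
  grid <- sim_grid(128)
  probe <- fx_probe1mhz()
  med <- fx_homog_medium()
  burst <- tone_burst(1e6, 2, 1 / grid$dt)
  rf <- plane_wave_pulse_echo(med, probe, burst, grid, t_end = 40e-6)
  n0 <- round(8e-6 * rf$sample_rate)
  crosstalk <- sqrt(mean(rf$data[, seq_len(n0)]^2))
  late <- sqrt(mean(rf$data[, n0:ncol(rf$data)]^2))
  expect_lt(late, 0.05 * crosstalk)
})

test_that("single scatterer echo follows the plane-wave hyperbola", {
  # 0.7 MHz transmit on the 0.3 mm grid (>= 6.6 points per wavelength) keeps
  # differential grid dispersion across the aperture below one sample
  grid <- sim_grid(128)
  probe <- probe_geometry(center_frequency = 0.7e6)
  burst <- tone_burst(0.7e6, 2, 1 / grid$dt)
  ref <- plane_wave_pulse_echo(fx_homog_medium(), probe, burst, grid,
                               t_end = 40e-6)
  mk <- function(fac) {
    m <- fx_homog_medium()
    m$density[grid_index(grid, grid$pml + 1L, 5, 10)] <- 1020 * fac
    m
  }
  rf <- plane_wave_pulse_echo(mk(1.6), probe, burst, grid, t_end = 40e-6)
  echo <- rf$data - ref$data
  pg <- pasos:::probe_on_grid(probe, grid)
  d <- 10e-3
  els <- c(32L, 64L, 100L)
  t_meas <- vapply(els, function(e) {
    arrival_time(echo[e, ], rf$sample_rate, "peak")
  }, numeric(1))
  t_geo <- vapply(els, function(e) {
    xe <- pg$x_centres[e] * 1e-3
    (d + sqrt(d^2 + (xe - 5e-3)^2)) / 1500
  }, numeric(1))
  # common pulse delay cancels in channel differences; 1 sample at 20 MHz
  expect_lt(max(abs((t_meas - t_meas[2]) - (t_geo - t_geo[2]))), 50e-9)

  # Born regime: doubling the scatterer amplitude doubles the echo
  e1 <- plane_wave_pulse_echo(mk(1.015), probe, burst, grid,
                              t_end = 40e-6)$data - ref$data
  e2 <- plane_wave_pulse_echo(mk(1.03), probe, burst, grid,
                              t_end = 40e-6)$data - ref$data
  expect_lt(abs(max(abs(e2)) / max(abs(e1)) - 2), 0.1)
})

test_that("pa_forward superposes sources and respects p0 = 0", {
  grid <- sim_grid(128)
  probe <- fx_probe1mhz()
  med <- fx_homog_medium()
  zero <- pa_forward(med, matrix(0, 128, 128), probe, grid, t_end = 20e-6,
                     fc = 1e6)
  expect_true(all(zero$data == 0))
  # two equal sources at equal radius from the centre element arrive together
  # with twice the amplitude of one
  pg <- pasos:::probe_on_grid(probe, grid)
  e <- 64L
  xe <- pg$x_centres[e]
  p1 <- fx_blob_p0(grid, xe - 8, 15)
  p2 <- fx_blob_p0(grid, xe + 8, 15)
  r1 <- pa_forward(med, p1, probe, grid, t_end = 30e-6, fc = 1e6)$data[e, ]
  r12 <- pa_forward(med, p1 + p2, probe, grid, t_end = 30e-6,
                    fc = 1e6)$data[e, ]
  expect_lt(abs(max(abs(r12)) / max(abs(r1)) - 2), 0.1)
})

test_that("CFL violations and shape mismatches are rejected", {
  grid <- sim_grid(128)
  med <- acoustic_medium(sos = matrix(2200, 128, 128), dx = grid$dx)
  expect_error(propagate(med, grid, 1e-6), "CFL")
  expect_error(propagate(fx_homog_medium(n = 64), grid, 1e-6), "shapes")
})

test_that("halving dx changes arrival by under a sample and amplitude by < 5%", {
  arr <- function(n, sigma_cells) {
    grid <- sim_grid(n)
    probe <- probe_geometry(center_frequency = 0.5e6)
    med <- acoustic_medium(sos = matrix(1500, n, n), dx = grid$dx)
    p0 <- place_point_absorbers(cbind(0, 15), grid,
                                smooth_sigma = sigma_cells)
    rf <- downsample_to_20mhz(pa_forward(med, p0, probe, grid,
                                         t_end = 14e-6, fc = 0.5e6))
    pg <- pasos:::probe_on_grid(probe, grid)
    e <- which.min(abs(pg$x_centres))
    c(t = arrival_time(rf$data[e, ], rf$sample_rate, "peak"),
      amp = max(abs(rf$data[e, ])))
  }
  coarse <- arr(128, 2)  # 0.6 mm source width on both grids
  fine <- arr(256, 4)
  expect_lt(abs(coarse["t"] - fine["t"]), 1 / 20e6)
  expect_lt(abs(coarse["amp"] / fine["amp"] - 1), 0.05)
})
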