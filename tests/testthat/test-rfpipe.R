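# RF conditioning chain and B-mode beamformer.

synth_rf <- function(f_tone, fs = 100e6, n = 5120, n_ch = 4) {
  t <- (seq_len(n) - 1) / fs
  rf_frame(t(replicate(n_ch, sin(2 * pi * f_tone * t))), fs)
}

test_that("TGC gain follows the closed-form depth law", {
  rf <- rf_frame(matrix(1, 2, 1000), 20e6)
  out <- apply_tgc(rf, alpha = 0.5, c_ref = 1540, fc = 7e6)
  expect_equal(out$data[1, 1], 1)  # t = 0 -> unit gain
  # depth 1 cm: t = 2 * 0.01 / 1540, gain = 10^(0.5 * 7 * 1 / 20)
  t_1cm <- 2 * 0.01 / 1540
  i <- round(t_1cm * 20e6) + 1
  expect_within(out$data[1, i], 10^0.175, 0.01)
  # alpha = 0 is the identity; negative alpha rejected
  expect_identical(apply_tgc(rf, alpha = 0)$data, rf$data)
  expect_error(apply_tgc(rf, alpha = -1), "non-negative")
})

test_that("downsampling yields 128x1024-format output with correct band", {
  rf <- synth_rf(3e6)
  out <- downsample_to_20mhz(rf)
  expect_equal(dim(out$data), c(4L, 1024L))
  expect_equal(out$sample_rate, 20e6)
  # 3 MHz passband tone preserved within 1 %
  mid <- out$data[1, 100:900]
  expect_within(max(abs(mid)), 1, 0.01)
  # 12 MHz tone (above the 10 MHz output Nyquist) attenuated > 40 dB
  out2 <- downsample_to_20mhz(synth_rf(12e6))
  expect_lt(max(abs(out2$data[1, 100:900])), 10^(-40 / 20))
  # shorter input than the 1024-sample window is zero-padded
  short <- rf_frame(matrix(rnorm(4 * 500), 4), 20e6)
  out3 <- downsample_to_20mhz(short)
  expect_equal(dim(out3$data), c(4L, 1024L))
  expect_true(all(out3$data[, 520:1024] == 0))
})

test_that("early-sample zeroing is exact, bounded and idempotent", {
  rf <- rf_frame(matrix(1, 128, 1024), 20e6)
  z <- zero_early_samples(rf, 50)
  expect_true(all(rowSums(z$data) == 974))
  expect_identical(zero_early_samples(z, 50)$data, z$data)
  expect_identical(zero_early_samples(rf, 0)$data, rf$data)
  expect_error(zero_early_samples(rf, 1024), "smaller")
})

test_that("channel normalization gives mean 0 / sd 1 and flags dead channels", {
  x <- matrix(rnorm(128 * 1024, mean = 3, sd = 7), 128)
  x[5, ] <- 2  # constant channel
  rf <- normalize_channels(rf_frame(x, 20e6))
  expect_true(all(abs(rowMeans(rf$data)) < 1e-6))
  sds <- apply(rf$data[-5, ], 1, sd)
  expect_true(all(abs(sds - 1) < 1e-6))
  expect_true(all(rf$data[5, ] == 0))
  expect_equal(rf$meta$degenerate_channels, 5L)
  # idempotence
  again <- normalize_channels(rf)
  expect_equal(again$data[-5, ], rf$data[-5, ], tolerance = 1e-10)
})

test_that("thermal noise hits the drawn per-channel SNR", {
  x <- matrix(sin(2 * pi * (1:1024) / 16), 128, 1024, byrow = TRUE)
  rf <- rf_frame(x, 20e6)
  noisy <- add_thermal_noise(rf, snr_db = 30, seed = 4)
  noise <- noisy$data - x
  snr_meas <- 10 * log10(mean(rowMeans(x^2) / rowMeans(noise^2)))
  expect_within(snr_meas, 30, 0.5)
  # infinite SNR disables the stage; inverted bounds rejected
  expect_identical(add_thermal_noise(rf, snr_db = Inf)$data, x)
  expect_error(add_thermal_noise(rf, snr_range = c(80, 40)), "inverted")
  # different seeds: different noise, same marginal power within 10 %
  n1 <- add_thermal_noise(rf, snr_db = 20, seed = 1)$data - x
  n2 <- add_thermal_noise(rf, snr_db = 20, seed = 2)$data - x
  expect_false(identical(n1, n2))
  expect_within(mean(n1^2) / mean(n2^2), 1, 0.1)
})

test_that("system noise fills the early window reproducibly", {
  bank <- make_noise_bank(seed = 3, n_segments = 8, rms = 0.5)
  expect_equal(dim(bank), c(8L, 50L))
  x <- matrix(0, 128, 1024)
  rf <- rf_frame(x, 20e6)
  noisy <- add_system_noise(rf, bank, seed = 6)
  early_rms <- sqrt(mean(noisy$data[, 1:50]^2))
  expect_within(early_rms, 0.5, 0.05)
  expect_true(all(noisy$data[, 51:1024] == 0))
  # seeded draw is reproducible; empty bank errors; NULL disables
  again <- add_system_noise(rf, bank, seed = 6)
  expect_identical(noisy$data, again$data)
  expect_error(add_system_noise(rf, bank[0, , drop = FALSE]), "empty")
  expect_identical(add_system_noise(rf, NULL)$data, x)
})

test_that("full conditioning chain maps solver RF to a contract frame", {
  fx <- fx_speckle_pe()
  bank <- make_noise_bank(seed = 2, fc = 1e6)
  out <- condition_rf(fx$rf, tgc_fc = 1e6, noise_bank = bank, seed = 9)
  expect_equal(dim(out$data), c(128L, 1024L))
  expect_true(all(is.finite(out$data)))
  expect_true(all(abs(rowMeans(out$data)) < 1e-6))
  live <- setdiff(1:128, out$meta$degenerate_channels)
  expect_true(all(abs(apply(out$data[live, ], 1, sd) - 1) < 1e-6))
  expect_equal(out$meta$stage_order,
               c("tgc", "downsample", "zero", "system_noise",
                 "thermal_noise", "normalize"))
  # stochastic stages reproducible from the pipeline seed
  again <- condition_rf(fx$rf, tgc_fc = 1e6, noise_bank = bank, seed = 9)
  expect_identical(out$data, again$data)
})

test_that("B-mode localizes a point scatterer and degrades with wrong c", {
  grid <- sim_grid(128)
  probe <- probe_geometry(center_frequency = 0.7e6)
  burst <- tone_burst(0.7e6, 2, 1 / grid$dt)
  ref <- plane_wave_pulse_echo(fx_homog_medium(), probe, burst, grid,
                               t_end = 51.2e-6)
  med <- fx_homog_medium()
  med$density[pasos:::grid_index(grid, grid$pml + 1L, 4, 14)] <- 1020 * 1.8
  rf <- plane_wave_pulse_echo(med, probe, burst, grid, t_end = 51.2e-6)
  echo <- rf
  echo$data <- rf$data - ref$data   # isolate the scattered field
  echo <- downsample_to_20mhz(echo)
  bm <- das_bmode(echo, c = 1500, probe = probe, pixel_mm = 0.3,
                  pulse_delay = 1.35 / 0.7e6)
  pk <- which(bm$envelope == max(bm$envelope), arr.ind = TRUE)[1, ]
  expect_lt(abs(bm$z[pk[1]] - 14), 0.9)   # within 3 pixels axially
  expect_lt(abs(bm$x[pk[2]] - 4), 0.65)   # within 2 pixels laterally
  # 5 % sound-speed error displaces the axial peak by ~5 % of depth
  bm2 <- das_bmode(echo, c = 1500 * 1.05, probe = probe, pixel_mm = 0.3,
                   pulse_delay = 1.35 / 0.7e6)
  pk2 <- which(bm2$envelope == max(bm2$envelope), arr.ind = TRUE)[1, ]
  expect_within(bm2$z[pk2[1]] - bm$z[pk[1]], 0.05 * 14, 0.5)
  # zero RF floors the display
  bm0 <- das_bmode(rf_frame(matrix(0, 128, 1024), 20e6), c = 1540,
                   probe = probe)
  expect_true(all(bm0$image == -50))
  expect_warning(das_bmode(echo, c = 1200, probe = probe), "outside")
})
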