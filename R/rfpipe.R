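# RF conditioning: time-gain compensation, downsampling to the 20 MHz /
# 1024-sample acquisition format, early-sample zeroing, per-channel
# normalization, thermal and system noise injection, and a delay-and-sum
# B-mode beamformer for visualization.

#' Time gain compensation
#'
#' Amplifies each sample by `10^(alpha * fc_MHz * depth_cm / 20)` where the
#' two-way depth mapping `depth = c_ref * t / 2` converts sample time to
#' centimetres. The default compensates 0.5 dB/(MHz cm) at 1540 m/s and the
#' 7 MHz transmit frequency.
#'
#' @param rf an [rf_frame()].
#' @param alpha attenuation compensation in dB/(MHz cm); must be >= 0.
#' @param c_ref reference sound speed in m/s.
#' @param fc frequency in Hz at which the gain law is evaluated.
#' @return The compensated [rf_frame()].
#' @export
apply_tgc <- function(rf, alpha = 0.5, c_ref = 1540, fc = 7e6) {
  if (alpha < 0) stop("alpha must be non-negative")
  t <- rf$t0 + (seq_len(ncol(rf$data)) - 1) / rf$sample_rate
  depth_cm <- c_ref * t / 2 * 100
  gain <- 10^(alpha * (fc / 1e6) * depth_cm / 20)
  rf$data <- sweep(rf$data, 2, gain, `*`)
  rf$meta$tgc <- c(alpha = alpha, c_ref = c_ref, fc = fc)
  rf
}

#' Downsample RF data to the 20 MHz / 1024-sample acquisition format
#'
#' Applies a zero-phase anti-aliasing low-pass (FIR, cutoff 0.9 x the output
#' Nyquist) when the solver rate exceeds the output rate, then resamples each
#' channel by cubic spline onto the output time grid. The output is truncated
#' or zero-padded to exactly `n_out` samples.
#'
#' @param rf an [rf_frame()] at the solver rate.
#' @param fs_out output sampling rate in Hz (default 20 MHz).
#' @param n_out output sample count (default 1024).
#' @return An [rf_frame()] of shape `channels x n_out` at `fs_out`.
#' @export
downsample_to_20mhz <- function(rf, fs_out = 20e6, n_out = 1024L) {
  fs_in <- rf$sample_rate
  x <- rf$data
  n_in <- ncol(x)
  if (fs_in > fs_out * (1 + 1e-9)) {
    wc <- 0.9 * (fs_out / 2) / (fs_in / 2)
    # transition band: 10 % of the output Nyquist (Hamming window design)
    ord <- 2L * as.integer(ceiling(3.3 / (0.05 * fs_out / fs_in) / 2))
    ord <- max(24L, min(ord, 2L * (n_in %/% 6L)))
    b <- as.numeric(signal::fir1(ord, wc))
    x <- t(apply(x, 1, function(ch) signal::filtfilt(b, 1, ch)))
  }
  t_in <- (seq_len(n_in) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  keep <- t_out <= t_in[n_in]
  out <- matrix(0, nrow(x), n_out)
  for (i in seq_len(nrow(x))) {
    out[i, keep] <- spline(t_in, x[i, ], xout = t_out[keep],
                           method = "natural")$y
  }
  rf_frame(out, sample_rate = fs_out, transmit = rf$transmit, t0 = rf$t0,
           meta = rf$meta)
}

#' Zero the earliest RF samples
#'
#' Removes electrical cross-talk from the transmit pulse by zeroing the first
#' `n` samples of every channel (the acquisition convention zeroes the first
#' 50 of 1024).
#'
#' @param rf an [rf_frame()].
#' @param n number of leading samples to zero; must be < the sample count.
#' @return The modified [rf_frame()].
#' @export
zero_early_samples <- function(rf, n = 50L) {
  if (n >= ncol(rf$data)) stop("n must be smaller than the sample count")
  if (n > 0) rf$data[, seq_len(n)] <- 0
  rf
}

#' Normalize each RF channel to zero mean and unit standard deviation
#'
#' Channels with zero variance are left identically zero and flagged in
#' `meta$degenerate_channels`.
#'
#' @param rf an [rf_frame()].
#' @return The normalized [rf_frame()].
#' @export
normalize_channels <- function(rf) {
  m <- rowMeans(rf$data)
  s <- apply(rf$data, 1, sd)
  bad <- !is.finite(s) | s == 0
  s[bad] <- 1
  rf$data <- (rf$data - m) / s
  rf$data[bad, ] <- 0
  rf$meta$degenerate_channels <- which(bad)
  rf
}

#' Add white Gaussian (thermal) noise at a per-channel SNR
#'
#' Noise power on each channel is set relative to that channel's signal power
#' by `snr_db = 10*log10(P_signal / P_noise)`. When `snr_db` is `NULL` a value
#' is drawn uniformly from `snr_range` (one draw per frame). Passing
#' `snr_db = Inf` disables the stage.
#'
#' @param rf an [rf_frame()].
#' @param snr_db signal-to-noise ratio in dB, or `NULL` to draw one.
#' @param snr_range bounds of the uniform SNR law used when drawing. The
#'   acquisition protocol specifies a noise floor 40-80 dB below the signal.
#' @param seed integer seed.
#' @return The noisy [rf_frame()] with `meta$snr_db` recording the value used.
#' @export
add_thermal_noise <- function(rf, snr_db = NULL, snr_range = c(40, 80),
                              seed = 1L) {
  if (!is.null(snr_db) && is.infinite(snr_db)) return(rf)
  if (snr_range[1] > snr_range[2]) stop("inverted snr bounds")
  with_seed(substream_seed(seed, "thermal-noise"), {
    if (is.null(snr_db)) snr_db <- runif(1, snr_range[1], snr_range[2])
    p_sig <- rowMeans(rf$data^2)
    sd_noise <- sqrt(p_sig * 10^(-snr_db / 10))
    noise <- matrix(rnorm(length(rf$data)), nrow(rf$data)) * sd_noise
    rf$data <- rf$data + noise
    rf$meta$snr_db <- snr_db
    rf
  })
}

#' Synthetic system-noise bank
#'
#' Band-limited interference bursts confined to the early-sample window,
#' emulating the transmit-interference segments that real acquisitions show
#' in their first 50 samples. Real banks (matrices with one segment per row)
#' can be passed to [add_system_noise()] in place of this synthetic one.
#'
#' @param seed integer seed.
#' @param n_segments number of stored segments.
#' @param n_samples segment length in samples (default 50).
#' @param fs sampling rate the segments are generated at (default 20 MHz).
#' @param fc burst centre frequency in Hz.
#' @param rms root-mean-square amplitude of each segment.
#' @return A `n_segments x n_samples` matrix of class `noise_bank`.
#' @export
make_noise_bank <- function(seed = 1L, n_segments = 16L, n_samples = 50L,
                            fs = 20e6, fc = 7e6, rms = 1) {
  with_seed(substream_seed(seed, "noise-bank"), {
    t <- (seq_len(n_samples) - 1) / fs
    bank <- t(vapply(seq_len(n_segments), function(k) {
      f <- fc * runif(1, 0.7, 1.3)
      env <- exp(-((t - runif(1, 0.2, 0.8) * max(t)) /
                     (runif(1, 0.1, 0.3) * max(t)))^2)
      s <- env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
      s / sqrt(mean(s^2)) * rms
    }, numeric(n_samples)))
    structure(bank, class = c("noise_bank", "matrix", "array"))
  })
}

#' Add system (transmit-interference) noise to the early-sample window
#'
#' For each channel a segment is drawn from the bank and added to the first
#' samples (tiled if the segment is shorter than `window`).
#'
#' @param rf an [rf_frame()].
#' @param bank a matrix with one noise segment per row (see
#'   [make_noise_bank()]); `NULL` disables the stage.
#' @param seed integer seed.
#' @param window number of early samples receiving noise (default: segment
#'   length).
#' @param gain multiplicative scale applied to the segments.
#' @return The modified [rf_frame()].
#' @export
add_system_noise <- function(rf, bank, seed = 1L, window = NULL, gain = 1) {
  if (is.null(bank)) return(rf)
  if (!is.matrix(bank) || nrow(bank) == 0L) stop("noise bank is empty")
  window <- window %||% ncol(bank)
  window <- min(window, ncol(rf$data))
  with_seed(substream_seed(seed, "system-noise"), {
    for (i in seq_len(nrow(rf$data))) {
      seg <- bank[sample.int(nrow(bank), 1L), ]
      seg <- rep_len(seg, window)
      rf$data[i, seq_len(window)] <- rf$data[i, seq_len(window)] + gain * seg
    }
    rf$meta$system_noise <- TRUE
    rf
  })
}

#' Full RF conditioning chain
#'
#' Maps raw solver RF to a network-ready frame: time gain compensation and
#' downsampling on the clean RF, early-sample zeroing, then system noise
#' (which fills the zeroed transmit window, as in real acquisitions), thermal
#' noise, and finally per-channel normalization. The stage order is
#' configurable and recorded in the frame metadata.
#'
#' @param rf an [rf_frame()] at the solver rate.
#' @param order character vector of stage names among `"tgc"`,
#'   `"downsample"`, `"zero"`, `"system_noise"`, `"thermal_noise"`,
#'   `"normalize"`.
#' @param tgc_fc frequency (Hz) for the TGC gain law.
#' @param n_zero number of early samples zeroed.
#' @param noise_bank system-noise bank or `NULL` (stage skipped).
#' @param snr_db,snr_range thermal-noise settings (see
#'   [add_thermal_noise()]); `snr_db = Inf` skips the stage.
#' @param seed integer seed for the stochastic stages.
#' @return A conditioned 128 x 1024 [rf_frame()] with per-channel mean 0 and
#'   standard deviation 1.
#' @export
condition_rf <- function(rf,
                         order = c("tgc", "downsample", "zero",
                                   "system_noise", "thermal_noise",
                                   "normalize"),
                         tgc_fc = 7e6, n_zero = 50L, noise_bank = NULL,
                         snr_db = NULL, snr_range = c(40, 80), seed = 1L) {
  stages <- list(
    tgc = function(x) apply_tgc(x, fc = tgc_fc),
    downsample = downsample_to_20mhz,
    zero = function(x) zero_early_samples(x, n_zero),
    system_noise = function(x) add_system_noise(x, noise_bank, seed = seed),
    thermal_noise = function(x) {
      if (!is.null(snr_db) && is.infinite(snr_db)) return(x)
      add_thermal_noise(x, snr_db = snr_db, snr_range = snr_range,
                        seed = seed)
    },
    normalize = normalize_channels
  )
  unknown <- setdiff(order, names(stages))
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  for (nm in order) rf <- stages[[nm]](rf)
  rf$meta$stage_order <- order
  rf
}

#' Delay-and-sum B-mode image
#'
#' Plane-wave delay-and-sum with dynamic receive delays at an assumed sound
#' speed: for a pixel at `(x, z)` the two-way delay at element `e` is
#' `(z + sqrt(z^2 + (x - x_e)^2)) / c` plus the transmit pulse-centre delay.
#' The beamformed channels are summed, envelope-detected and log-compressed,
#' and the top 2 mm are zeroed to mirror the usual display convention.
#'
#' @param rf an [rf_frame()] of plane-wave RF (any rate).
#' @param c assumed sound speed in m/s (warned against outside
#'   `[1300, 1700]`).
#' @param probe a [probe_geometry()].
#' @param pixel_mm image pixel size in mm.
#' @param depth_mm imaged depth in mm.
#' @param pulse_delay transmit pulse-centre delay in seconds (default: half
#'   the 2-cycle burst at the probe frequency).
#' @param dynamic_range_db display dynamic range for log compression.
#' @param zero_top_mm top margin zeroed in the display.
#' @return A list with the dB image (`image`), the linear envelope
#'   (`envelope`) and the pixel axes in mm (`x`, `z`).
#' @export
das_bmode <- function(rf, c = 1540, probe = probe_geometry(),
                      pixel_mm = 0.1, depth_mm = 38.4,
                      pulse_delay = 1 / probe$center_frequency,
                      dynamic_range_db = 50, zero_top_mm = 2) {
  if (c < 1300 || c > 1700) {
    warning("assumed sound speed ", c, " m/s is outside [1300, 1700]")
  }
  fs <- rf$sample_rate
  n_el <- nrow(rf$data)
  xe <- (seq_len(n_el) - (n_el + 1) / 2) * probe$pitch * 1e-3
  zs <- seq(pixel_mm / 2, depth_mm, by = pixel_mm) * 1e-3
  xs <- seq(xe[1], xe[n_el], by = pixel_mm * 1e-3)
  n_t <- ncol(rf$data)
  img <- matrix(0, length(zs), length(xs))
  for (jj in seq_along(xs)) {
    x <- xs[jj]
    acc <- numeric(length(zs))
    for (e in seq_len(n_el)) {
      tau <- (zs + sqrt(zs^2 + (x - xe[e])^2)) / c + pulse_delay
      si <- tau * fs + 1
      i0 <- floor(si)
      w <- si - i0
      ok <- i0 >= 1 & i0 < n_t
      v <- numeric(length(zs))
      v[ok] <- (1 - w[ok]) * rf$data[e, i0[ok]] +
        w[ok] * rf$data[e, i0[ok] + 1L]
      acc <- acc + v
    }
    img[, jj] <- acc
  }
  env <- apply(img, 2, envelope)
  env[zs * 1e3 <= zero_top_mm, ] <- 0
  mx <- max(env)
  db <- if (mx > 0) 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20))) else
    matrix(-dynamic_range_db, nrow(env), ncol(env))
  list(image = db, envelope = env, x = xs * 1e3, z = zs * 1e3,
       c = c, pixel_mm = pixel_mm)
}
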