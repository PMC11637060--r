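# Autofocus baseline: select a single global sound speed by maximizing an
# image sharpness metric over a candidate sweep of reconstructions.

#' Image sharpness
#'
#' Two metrics on the normalized intensity `I` in `[0, 1]`:
#' `"normalized_power"` is `sum(I^4) / (sum(I^2))^2`, invariant to global
#' intensity scaling and maximal for concentrated energy; `"brenner"` is the
#' Brenner gradient `sum((J[i+2,j] - J[i,j])^2 + (J[i,j+2] - J[i,j])^2)`
#' evaluated on the energy-normalized intensity `J = I / sqrt(sum(I^2))`,
#' making both metrics invariant to global intensity scaling.
#'
#' @param img a [pa_image()] or matrix.
#' @param metric `"normalized_power"` (default) or `"brenner"`.
#' @return A non-negative scalar (0 with a warning for all-zero images).
#' @export
sharpness <- function(img, metric = c("normalized_power", "brenner")) {
  metric <- match.arg(metric)
  I <- pa_intensity(img)
  if (all(I == 0)) {
    warning("all-zero image: sharpness is 0")
    return(0)
  }
  if (metric == "normalized_power") {
    sum(I^4) / sum(I^2)^2
  } else {
    J <- I / sqrt(sum(I^2))
    n <- nrow(J); m <- ncol(J)
    sum((J[3:n, ] - J[1:(n - 2), ])^2) + sum((J[, 3:m] - J[, 1:(m - 2)])^2)
  }
}

#' Autofocus sound-speed selection
#'
#' Reconstructs the PA frame at each candidate sound speed over a grid sweep,
#' scores each reconstruction with a sharpness metric, and returns the
#' maximizer (ties broken toward 1540 m/s) together with the full sweep
#' table.
#'
#' @param rf_raw 128 x 1024 [rf_frame()] (or matrix) at 20 MHz.
#' @param probe a [probe_geometry()].
#' @param c_range sweep bounds in m/s.
#' @param step sweep step in m/s (> 0).
#' @param grid a [recon_grid()]; candidates must satisfy its stability bound.
#' @param metric sharpness metric (see [sharpness()]).
#' @param n_zero leading samples zeroed before reconstruction.
#' @param t_max optional recording horizon in seconds passed to
#'   [reconstruct()] (shortens sweeps when all sources are shallow).
#' @return A list with `c_opt` (m/s) and `sweep`, a data.frame of candidate
#'   sound speeds and sharpness scores.
#' @export
autofocus_sos <- function(rf_raw, probe = probe_geometry(),
                          c_range = c(1400, 1600), step = 5,
                          grid = recon_grid(), metric = "normalized_power",
                          n_zero = 150L, t_max = NULL) {
  if (step <= 0) stop("step must be positive")
  if (c_range[1] > c_range[2]) stop("empty candidate range")
  cands <- seq(c_range[1], c_range[2], by = step)
  scores <- vapply(cands, function(cc) {
    img <- reconstruct(rf_raw, cc, probe, grid, n_zero = n_zero,
                       sos_source = "autofocus", t_max = t_max)
    sharpness(img, metric)
  }, numeric(1))
  best <- max(scores)
  ties <- which(scores >= best * (1 - 1e-12))
  c_opt <- cands[ties[which.min(abs(cands[ties] - 1540))]]
  list(c_opt = c_opt,
       sweep = data.frame(c = cands, sharpness = scores, metric = metric))
}
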