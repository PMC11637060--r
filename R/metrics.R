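# Quantitative evaluation: SoS RMSE, region SSIM, lateral FWHM, SNR, and the
# evaluation harness comparing the constant-1540, autofocus and learned
# estimators.

#' Root mean square error between SoS fields
#'
#' `sqrt(mean((est - gt)^2))` over the (optionally masked) pixel set. Scalar
#' estimates (the constant-assumption and autofocus rows of an evaluation
#' table) are broadcast as constant fields.
#'
#' @param est estimated SoS: matrix or scalar (m/s).
#' @param gt ground-truth SoS matrix (m/s).
#' @param mask optional logical matrix selecting the evaluated region.
#' @return RMSE in m/s.
#' @export
rmse_sos <- function(est, gt, mask = NULL) {
  gt <- as.matrix(gt)
  if (length(est) == 1L) est <- matrix(est, nrow(gt), ncol(gt))
  est <- as.matrix(est)
  stopifnot(all(dim(est) == dim(gt)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gt), ncol(gt))
  if (!any(mask)) stop("empty mask")
  sqrt(mean((est[mask] - gt[mask])^2))
}

#' Region structural similarity (SSIM)
#'
#' Single-window SSIM evaluated over a masked pixel set:
#' `((2*mu_x*mu_y + C1) * (2*sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1) * (sigma_x^2 + sigma_y^2 + C2))`
#' with `C1 = (0.01 L)^2 = 1e-4` and `C2 = (0.03 L)^2 = 9e-4` for `L = 1`,
#' the dynamic range of images normalized to `[0, 1]`. Statistics are computed over the region as a whole (no sliding
#' window), matching per-structure evaluation of reconstructions.
#'
#' @param x,y images normalized to `[0, 1]` (matrices or [pa_image()]s, which
#'   are converted via [pa_intensity()]).
#' @param mask optional logical matrix selecting the region.
#' @param L dynamic range (default 1).
#' @return SSIM value in `[-1, 1]`.
#' @export
region_ssim <- function(x, y, mask = NULL, L = 1) {
  if (inherits(x, "pa_image")) x <- pa_intensity(x)
  if (inherits(y, "pa_image")) y <- pa_intensity(y)
  stopifnot(all(dim(x) == dim(y)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  if (!any(mask)) stop("empty mask")
  xv <- x[mask]; yv <- y[mask]
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mx <- mean(xv); my <- mean(yv)
  n <- length(xv)
  vx <- sum((xv - mx)^2) / n
  vy <- sum((yv - my)^2) / n
  vxy <- sum((xv - mx) * (yv - my)) / n
  ((2 * mx * my + C1) * (2 * vxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Lateral full width at half maximum of a point source
#'
#' Extracts the lateral (X) intensity profile through a peak and measures the
#' width between the half-maximum crossings, located by linear interpolation.
#'
#' @param img a [pa_image()] or intensity matrix.
#' @param peak `c(row, col)` pixel of the local maximum, or `NULL` to use the
#'   global intensity maximum.
#' @param pixel_mm pixel size in mm (default from the image).
#' @return FWHM in mm, or `NA` (flagged "unresolved") when the profile never
#'   falls below half maximum on either side.
#' @export
lateral_fwhm <- function(img, peak = NULL, pixel_mm = NULL) {
  I <- pa_intensity(img)
  pixel_mm <- pixel_mm %||%
    (if (inherits(img, "pa_image")) img$pixel_size else 1)
  if (is.null(peak)) {
    peak <- which(I == max(I), arr.ind = TRUE)[1, ]
  }
  profile_fwhm(I[peak[1], ], peak[2]) * pixel_mm
}

# FWHM of a 1D profile around index ipk, in samples (linear interpolation)
profile_fwhm <- function(p, ipk = which.max(p)) {
  half <- p[ipk] / 2
  n <- length(p)
  right <- NA_real_
  if (ipk < n) {
    for (i in ipk:(n - 1L)) {
      if (p[i + 1L] < half) {
        right <- i + (p[i] - half) / (p[i] - p[i + 1L])
        break
      }
    }
  }
  left <- NA_real_
  if (ipk > 1L) {
    for (i in ipk:2L) {
      if (p[i - 1L] < half) {
        left <- i - (p[i] - half) / (p[i] - p[i - 1L])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    warning("profile never falls below half maximum: unresolved")
    return(NA_real_)
  }
  right - left
}

#' Signal-to-noise ratio of a PA image
#'
#' `20 * log10(mu / sigma)` where `mu` is the mean intensity of signal pixels
#' (intensity >= `threshold`) and `sigma` the standard deviation of
#' background pixels (intensity < `threshold`), on the normalized intensity.
#'
#' @param img a [pa_image()] or matrix (normalized to `[0, 1]` via
#'   [pa_intensity()]).
#' @param threshold signal/background intensity split (default 0.35).
#' @return SNR in dB, or `NA` (flagged) when there are no signal pixels or
#'   the background is degenerate.
#' @export
snr_db <- function(img, threshold = 0.35) {
  I <- pa_intensity(img)
  sig <- I[I >= threshold]
  bg <- I[I < threshold]
  if (length(sig) == 0L || length(bg) < 2L) {
    warning("degenerate signal/background split")
    return(NA_real_)
  }
  s <- sd(bg)
  if (s == 0) {
    warning("zero background deviation")
    return(NA_real_)
  }
  20 * log10(mean(sig) / s)
}

#' Per-region masks of a phantom on the label grid
#'
#' @param medium an [acoustic_medium()].
#' @param size mask side length (default 384, the label resolution).
#' @return A named list of logical matrices (`background`, `region_1`, ...)
#'   that partition the medium.
#' @export
region_masks <- function(medium, size = 384L) {
  rid <- medium$region_id
  f <- nrow(rid) / size
  if (f >= 1 && nrow(rid) %% size == 0) {
    # majority vote within blocks via block mean of indicators
    ids <- sort(unique(as.vector(rid)))
    votes <- lapply(ids, function(k) block_mean((rid == k) * 1, f,
                                                ncol(rid) %/% size))
    best <- Reduce(function(a, b) pmax(a, b), votes)
    lab <- matrix(ids[1], size, size)
    for (i in seq_along(ids)) lab[votes[[i]] >= best] <- ids[i]
  } else {
    idx_z <- pmin(pmax(rnd((seq_len(size) - 0.5) * nrow(rid) / size + 0.5), 1),
                  nrow(rid))
    idx_x <- pmin(pmax(rnd((seq_len(size) - 0.5) * ncol(rid) / size + 0.5), 1),
                  ncol(rid))
    lab <- rid[idx_z, idx_x]
  }
  ids <- sort(unique(as.vector(lab)))
  masks <- lapply(ids, function(k) lab == k)
  names(masks) <- ifelse(ids == 0, "background", paste0("region_", ids))
  masks
}

#' Square regions of interest around known point sources
#'
#' @param coords matrix of `(x, z)` source positions in mm (probe-relative).
#' @param shape image shape `c(nz, nx)`.
#' @param pixel_mm image pixel size in mm.
#' @param side ROI side length in mm (default 2).
#' @return A logical matrix, the union of the per-source square windows.
#' @export
point_source_roi <- function(coords, shape, pixel_mm, side = 2) {
  mask <- matrix(FALSE, shape[1], shape[2])
  coords <- matrix(as.numeric(coords), ncol = 2L)
  h <- side / 2 / pixel_mm
  for (k in seq_len(nrow(coords))) {
    i0 <- coords[k, 2] / pixel_mm
    j0 <- shape[2] / 2 + coords[k, 1] / pixel_mm
    ii <- max(1, floor(i0 - h)):min(shape[1], ceiling(i0 + h))
    jj <- max(1, floor(j0 - h)):min(shape[2], ceiling(j0 + h))
    mask[ii, jj] <- TRUE
  }
  mask
}

#' Evaluate SoS estimation and aberration correction over a phantom batch
#'
#' For each phantom the harness computes per-region and global SoS RMSE for
#' the requested methods (constant 1540 m/s assumption, autofocus, learned
#' estimator) and, when PA sources are simulated, the point-source SSIM of
#' each reconstruction against the reference reconstruction that uses the
#' true SoS field.
#'
#' @param phantoms list of [phantom_spec()]s.
#' @param methods subset of `c("conventional", "autofocus", "dl")`.
#' @param model optional trained [build_sosnet()] model for the `"dl"` column
#'   (omitted with a message when missing).
#' @param sim a list of simulation settings as produced by [desk_profile()].
#' @param pa_sources optional matrix of `(x, z)` point-source positions in mm;
#'   when supplied, PA forward simulation + reconstruction metrics are added.
#' @param seed integer seed.
#' @return A data.frame with one row per phantom x method x region, columns
#'   `phantom`, `pattern`, `method`, `region`, `rmse`, and (for PA runs)
#'   per-phantom `ssim` and `fwhm_mm` on the point-source ROI.
#' @export
evaluate_suite <- function(phantoms, methods = c("conventional", "autofocus",
                                                 "dl"),
                           model = NULL, sim = desk_profile(),
                           pa_sources = NULL, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("conventional", "autofocus", "dl"))
  if ("dl" %in% methods && is.null(model)) {
    message("no model supplied: dl column omitted")
    methods <- setdiff(methods, "dl")
  }
  if ("autofocus" %in% methods && is.null(pa_sources)) {
    message("autofocus selects its SoS on PA reconstructions: supply ",
            "pa_sources; column omitted")
    methods <- setdiff(methods, "autofocus")
  }
  rows <- list()
  for (pi in seq_along(phantoms)) {
    spec <- phantoms[[pi]]
    prep <- simulate_phantom_rf(spec, sim,
                                seed = substream_seed(seed, paste0("ev", pi)),
                                pa_sources = pa_sources)
    gt <- prep$label
    masks <- region_masks(prep$medium, size = nrow(gt))
    est <- list()
    if ("conventional" %in% methods) est$conventional <- 1540
    if ("autofocus" %in% methods && !is.null(pa_sources)) {
      af <- autofocus_sos(prep$pa_rf, sim$probe, step = sim$autofocus_step,
                          grid = sim$recon, n_zero = sim$n_zero_pa)
      est$autofocus <- af$c_opt
    }
    if ("dl" %in% methods) {
      est$dl <- predict_sos(model, prep$rf)
    }
    row <- function(method, region, rmse = NA_real_, ssim = NA_real_,
                    fwhm = NA_real_) {
      data.frame(phantom = pi, pattern = spec$pattern_id, method = method,
                 region = region, rmse = rmse, ssim = ssim, fwhm_mm = fwhm)
    }
    for (m in names(est)) {
      e <- est[[m]]
      ev <- if (inherits(e, "sos_map") || is.matrix(e)) {
        resize_field(as.matrix(unclass(e)), nrow(gt), ncol(gt))
      } else e
      for (rn in names(masks)) {
        rows[[length(rows) + 1L]] <- row(m, rn, rmse_sos(ev, gt, masks[[rn]]))
      }
      rows[[length(rows) + 1L]] <- row(m, "global", rmse_sos(ev, gt))
    }
    if (!is.null(pa_sources)) {
      recs <- reconstruct_with_methods(prep, est, pa_sources, sim)
      for (m in names(recs$ssim)) {
        rows[[length(rows) + 1L]] <- row(m, "pa_roi", ssim = recs$ssim[[m]],
                                         fwhm = recs$fwhm[[m]])
      }
    }
  }
  do.call(rbind, rows)
}

# reconstruct PA images under each method's SoS and score vs the true-SoS
# reference
reconstruct_with_methods <- function(prep, est, pa_sources, sim) {
  ref <- reconstruct(prep$pa_rf, prep$sos_field_recon, sim$probe, sim$recon,
                     n_zero = sim$n_zero_pa, sos_source = "ground_truth")
  roi <- point_source_roi(pa_sources, dim(ref$values), ref$pixel_size)
  ssim <- list(); fwhm <- list()
  for (m in names(est)) {
    e <- est[[m]]
    img <- reconstruct(prep$pa_rf, if (is.numeric(e) && length(e) == 1L) e
                       else e, sim$probe, sim$recon, n_zero = sim$n_zero_pa)
    ssim[[m]] <- region_ssim(pa_intensity(img), pa_intensity(ref), roi)
    fwhm[[m]] <- lateral_fwhm(img)
  }
  list(ssim = ssim, fwhm = fwhm)
}
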