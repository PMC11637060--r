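# Rasterization of phantom specs onto acoustic simulation grids, speckle and
# echogenicity fields, ground-truth SoS labels and PA initial-pressure maps.

#' Gridded acoustic medium
#'
#' Holds the pixel-wise sound speed (m/s), mass density (kg/m^3) and
#' attenuation (dB/(MHz cm)) fields of a rasterized phantom. `sos_bulk` keeps
#' the piecewise-constant per-region sound speed before any speckle or
#' echogenicity perturbation: ground-truth labels are derived from it.
#' `region_id` labels each pixel (0 = background, then layers, then ellipses
#' in listing order, later inclusions overwriting earlier ones).
#'
#' @param sos matrix of sound speeds in m/s.
#' @param density matrix (or scalar) density in kg/m^3 (default 1020).
#' @param attenuation matrix (or scalar) in dB/(MHz cm) (default 0.5).
#' @param dx grid spacing in mm.
#' @param sos_bulk,region_id optional bulk-SoS and region-label matrices.
#' @param spec the originating [phantom_spec()], if any.
#' @return An object of class `acoustic_medium`.
#' @export
acoustic_medium <- function(sos, density = 1020, attenuation = 0.5, dx,
                            sos_bulk = sos, region_id = NULL, spec = NULL) {
  stopifnot(is.matrix(sos), all(is.finite(sos)), all(sos > 0), dx > 0)
  if (length(density) == 1L) {
    density <- matrix(density, nrow(sos), ncol(sos))
  }
  if (length(attenuation) == 1L) {
    attenuation <- matrix(attenuation, nrow(sos), ncol(sos))
  }
  if (is.null(region_id)) region_id <- matrix(0L, nrow(sos), ncol(sos))
  structure(list(sos = sos, density = density, attenuation = attenuation,
                 dx = dx, shape = dim(sos), sos_bulk = sos_bulk,
                 region_id = region_id, spec = spec),
            class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> %d x %d at %.4g mm; SoS [%.1f, %.1f] m/s\n",
              x$shape[1], x$shape[2], x$dx, min(x$sos), max(x$sos)))
  invisible(x)
}

# pixel-centre coordinate vectors of a grid (z depth from the top edge,
# x lateral with 0 at the centre), in mm
grid_coords <- function(nz, nx, dx) {
  list(z = (seq_len(nz) - 0.5) * dx,
       x = (seq_len(nx) - 0.5) * dx - nx * dx / 2)
}

#' Rasterize a phantom spec onto a simulation grid
#'
#' Membership is decided per pixel centre. Layers are painted first (each
#' layer claims all pixels below its possibly sine-deformed upper boundary),
#' then ellipses in listing order, later entries overwriting earlier ones.
#' Density and attenuation are uniform (1020 kg/m^3, 0.5 dB/(MHz cm)).
#'
#' @param spec a [phantom_spec()].
#' @param grid a [sim_grid()] whose extent is 38.4 mm per side, or `c(n, dx)`.
#' @return An [acoustic_medium()] carrying the bulk SoS field and region map.
#' @export
rasterize_medium <- function(spec, grid) {
  if (is.numeric(grid)) grid <- sim_grid(grid[1], grid[2])
  ext <- c(grid$nz * grid$dx, grid$nx * grid$dx)
  if (any(abs(ext - spec$extent_mm) > 1e-6)) {
    stop("grid extent (", paste(signif(ext, 6), collapse = " x "),
         " mm) does not match the 38.4 mm phantom extent")
  }
  co <- grid_coords(grid$nz, grid$nx, grid$dx)
  sos <- matrix(spec$background_sos, grid$nz, grid$nx)
  region <- matrix(0L, grid$nz, grid$nx)
  rid <- 0L
  for (lay in spec$layers %||% list()) {
    rid <- rid + 1L
    zb <- lay$z_top + lay$amplitude *
      sin(2 * pi * lay$periods * (co$x + spec$extent_mm / 2) /
            spec$extent_mm + lay$phase)
    for (j in seq_len(grid$nx)) {
      below <- co$z >= zb[j]
      sos[below, j] <- lay$sos
      region[below, j] <- rid
    }
  }
  if (length(spec$inclusions) > 0L) {
    X <- matrix(co$x, grid$nz, grid$nx, byrow = TRUE)
    Z <- matrix(co$z, grid$nz, grid$nx)
    for (inc in spec$inclusions) {
      rid <- rid + 1L
      dxm <- X - inc$center[1]
      dzm <- Z - inc$center[2]
      u <- dxm * cos(inc$orientation) + dzm * sin(inc$orientation)
      v <- -dxm * sin(inc$orientation) + dzm * cos(inc$orientation)
      inside <- (u / inc$semi_axes[1])^2 + (v / inc$semi_axes[2])^2 <= 1
      sos[inside] <- inc$sos
      region[inside] <- rid
    }
  }
  acoustic_medium(sos = sos, dx = grid$dx, sos_bulk = sos,
                  region_id = region, spec = spec)
}

# echogenicity of region rid under a spec (regions are numbered layers first,
# then ellipses, matching rasterize_medium)
region_echogenicity <- function(spec, rid) {
  if (rid == 0L) return("isoechoic")
  n_lay <- length(spec$layers %||% list())
  if (rid <= n_lay) return(spec$layers[[rid]]$echogenicity)
  spec$inclusions[[rid - n_lay]]$echogenicity
}

#' Apply hyperechoic speckle-SoS contrast inside inclusions
#'
#' For every hyperechoic region, approximately 10 % of its interior grid
#' points receive sound-speed increments of 7-11 % relative to the
#' background, raising the backscatter contrast without changing the region's
#' bulk SoS label. Isoechoic and hypoechoic regions are left untouched here
#' (hypoechoic contrast is realized by scaling scatterer amplitudes in
#' [sprinkle_scatterers()]).
#'
#' @param medium an [acoustic_medium()] from [rasterize_medium()].
#' @param spec the originating [phantom_spec()] (defaults to `medium$spec`).
#' @param seed integer seed (defaults to the spec's `rng_seed`).
#' @param fraction fraction of interior points modified (default 0.1).
#' @param increment bounds of the fractional SoS elevation (default 7-11 %).
#' @return The medium with elevated-SoS speckle points in `sos`.
#' @export
apply_echogenicity <- function(medium, spec = medium$spec, seed = NULL,
                               fraction = 0.1, increment = c(0.07, 0.11)) {
  if (is.null(spec)) stop("no phantom spec available")
  seed <- seed %||% spec$rng_seed
  with_seed(substream_seed(seed, "echogenicity"), {
    rids <- setdiff(sort(unique(as.vector(medium$region_id))), 0L)
    for (rid in rids) {
      if (region_echogenicity(spec, rid) != "hyperechoic") next
      idx <- which(medium$region_id == rid)
      if (length(idx) == 0L) next
      n_mod <- rpois(1, fraction * length(idx))
      n_mod <- min(n_mod, length(idx))
      if (n_mod == 0L) next
      pick <- sample(idx, n_mod)
      medium$sos[pick] <- spec$background_sos *
        (1 + runif(n_mod, increment[1], increment[2]))
    }
    medium
  })
}

#' Sprinkle sub-resolution scatterers into a medium
#'
#' Scatterer count is Poisson with mean `density * area / lambda^2`, where
#' `lambda` is the transmit wavelength at the background sound speed.
#' Scatterer amplitudes are drawn from `U[-0.03, 0.03]` and applied as
#' fractional perturbations of the mass density (`rho * (1 + a)`), which
#' produces backscatter while leaving the SoS label clean. Within hypoechoic
#' regions the amplitudes are scaled by a factor drawn from `U[0.1, 0.5]`.
#'
#' @param medium an [acoustic_medium()].
#' @param density mean scatterers per squared wavelength (default from spec).
#' @param seed integer seed (default derived from the spec's `rng_seed`).
#' @param fc transmit centre frequency in Hz (default 7 MHz).
#' @param amplitude bounds of the uniform amplitude law.
#' @return A list with the perturbed `medium` and the `scatterers` field
#'   (data.frame of grid indices and amplitudes).
#' @export
sprinkle_scatterers <- function(medium, density = NULL, seed = NULL,
                                fc = 7e6, amplitude = c(-0.03, 0.03)) {
  spec <- medium$spec
  density <- density %||% (if (!is.null(spec)) spec$scatterer_density else 3)
  if (density < 0) stop("scatterer density must be non-negative")
  seed <- seed %||% (if (!is.null(spec)) spec$rng_seed else 1L)
  if (density == 0) {
    return(list(medium = medium,
                scatterers = data.frame(index = integer(), amplitude = numeric())))
  }
  bg <- if (!is.null(spec)) spec$background_sos else median(medium$sos)
  lambda_mm <- bg / fc * 1e3
  area_mm2 <- prod(medium$shape) * medium$dx^2
  mean_n <- density * area_mm2 / lambda_mm^2
  with_seed(substream_seed(seed, "scatterers"), {
    n <- rpois(1, mean_n)
    idx <- sample.int(prod(medium$shape), n, replace = TRUE)
    amp <- runif(n, amplitude[1], amplitude[2])
    if (!is.null(spec)) {
      rids <- medium$region_id[idx]
      for (rid in setdiff(unique(rids), 0L)) {
        if (region_echogenicity(spec, rid) == "hypoechoic") {
          scale <- runif(1, 0.1, 0.5)
          amp[rids == rid] <- amp[rids == rid] * scale
        }
      }
    }
    medium$density[idx] <- medium$density[idx] * (1 + amp)
    list(medium = medium,
         scatterers = data.frame(index = idx, amplitude = amp))
  })
}

#' Ground-truth SoS label from a rasterized medium
#'
#' Labels are the bulk per-region sound speed (free of speckle and
#' echogenicity perturbations), reduced to 384 x 384 pixels at 0.1 mm. When
#' the medium side length is an integer multiple of 384 the reduction is an
#' exact block mean (4 x 4 for the 1536^2 reference grid); otherwise the bulk
#' field is resampled bilinearly.
#'
#' @param medium an [acoustic_medium()].
#' @param size output side length (default 384).
#' @param method `"auto"`, `"block"` or `"interp"`.
#' @return An object of class `sos_map` (matrix with `pixel_size` attribute,
#'   role `"ground_truth"`).
#' @export
label_from_medium <- function(medium, size = 384L, method = "auto") {
  method <- match.arg(method, c("auto", "block", "interp"))
  src <- medium$sos_bulk
  nz <- nrow(src); nx <- ncol(src)
  if (method == "auto") {
    method <- if (nz %% size == 0 && nx %% size == 0) "block" else "interp"
  }
  if (method == "block") {
    if (nz %% size != 0 || nx %% size != 0) {
      stop("medium shape ", nz, " x ", nx,
           " is not divisible into ", size, " x ", size, " blocks")
    }
    f <- nz %/% size
    vals <- block_mean(src, f, nx %/% size)
  } else {
    vals <- resize_field(src, size, size)
  }
  sos_map(vals, pixel_size = medium$dx * nz / size, role = "ground_truth")
}

block_mean <- function(m, fz, fx = fz) {
  nz <- nrow(m) %/% fz; nx <- ncol(m) %/% fx
  a <- array(m, dim = c(fz, nz, fx, nx))
  out <- apply(a, c(2, 4), mean)
  matrix(out, nz, nx)
}

#' Bilinear resize of a gridded field
#'
#' Pixel-centre bilinear interpolation, used to move SoS fields and images
#' between grid resolutions. Constant fields are preserved exactly and no
#' overshoot is introduced.
#'
#' @param m numeric matrix.
#' @param nz,nx output dimensions.
#' @return An `nz x nx` matrix.
#' @export
resize_field <- function(m, nz, nx) {
  x <- array(m, dim = c(dim(m), 1L))
  .resize_bilinear_forward(x, as.integer(nz), as.integer(nx))[, , 1]
}

#' Pixel-wise sound-speed map
#'
#' @param values matrix of sound speeds in m/s.
#' @param pixel_size pixel size in mm (0.1 mm for the standard 384 x 384 map).
#' @param role `"ground_truth"` or `"estimate"`.
#' @return An object of class `sos_map`.
#' @export
sos_map <- function(values, pixel_size = 0.1, role = "estimate") {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(values, pixel_size = pixel_size, role = role,
            class = c("sos_map", "matrix", "array"))
}

#' @export
print.sos_map <- function(x, ...) {
  cat(sprintf("<sos_map:%s> %d x %d at %.3g mm; [%.1f, %.1f] m/s\n",
              attr(x, "role"), nrow(x), ncol(x), attr(x, "pixel_size"),
              min(x), max(x)))
  invisible(x)
}

#' Initial-pressure field with point or disk absorbers
#'
#' Builds a PA source map that is zero everywhere except at the listed
#' coordinates, which receive a constant initial pressure of 1. With
#' `radius_mm = 0` each coordinate activates a single pixel (point mode);
#' a positive radius rasterizes a disk (pencil-lead mode: diameter 0.5 mm).
#'
#' @param coords matrix or list of `(x, z)` positions in mm (x lateral from
#'   the aperture centre, z depth below the probe row).
#' @param grid a [sim_grid()].
#' @param probe_row grid row of the transducer line (default `pml + 1`).
#' @param radius_mm absorber radius in mm (0 = single pixel).
#' @param smooth_sigma optional Gaussian smoothing width in grid cells
#'   applied after rasterization (0 = none); smoothed fields are rescaled to
#'   a unit maximum. Smoothing keeps point sources band-limited on coarse
#'   simulation grids.
#' @return A `nz x nx` matrix with values in `[0, 1]` (binary when
#'   `smooth_sigma = 0`).
#' @export
place_point_absorbers <- function(coords, grid, probe_row = grid$pml + 1L,
                                  radius_mm = 0, smooth_sigma = 0) {
  p0 <- matrix(0, grid$nz, grid$nx)
  if (is.null(coords) || length(coords) == 0L) return(p0)
  finish <- function(m) {
    if (smooth_sigma > 0 && any(m > 0)) {
      m <- smooth_field(m, smooth_sigma)
      m <- m / max(m)
    }
    m
  }
  if (is.list(coords) && !is.data.frame(coords)) {
    coords <- do.call(rbind, coords)
  }
  coords <- matrix(as.numeric(coords), ncol = 2L)
  for (k in seq_len(nrow(coords))) {
    idx <- grid_index(grid, probe_row, coords[k, 1], coords[k, 2])
    if (radius_mm <= 0) {
      p0[idx] <- 1
    } else {
      i0 <- (idx - 1L) %% grid$nz + 1L
      j0 <- (idx - 1L) %/% grid$nz + 1L
      r <- radius_mm / grid$dx
      di <- seq(-ceiling(r), ceiling(r))
      for (jj in di) for (ii in di) {
        if (ii^2 + jj^2 <= r^2) {
          i <- i0 + ii; j <- j0 + jj
          if (i >= 1 && i <= grid$nz && j >= 1 && j <= grid$nx) p0[i, j] <- 1
        }
      }
    }
  }
  finish(p0)
}
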