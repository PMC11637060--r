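# Digital tissue phantoms: parametric specifications and their samplers.
#
# Training phantoms follow a randomized ellipse model: a homogeneous
# background with SoS ~ U[1400, 1600] m/s and elliptical inclusions whose SoS
# sits 1-7 % above the background, with hyperechoic speckle contrast.
# Evaluation phantoms use three held-out patterns: layered structures with
# curved or straight boundaries and a homogeneous background with hypoechoic
# ellipses.

MEDIUM_EXTENT_MM <- 38.4

#' Elliptical inclusion of a digital phantom
#'
#' @param center `c(x, z)` centre in mm; x in `[-19.2, 19.2]` (0 = aperture
#'   centre), z in `[0, 38.4]` (depth).
#' @param semi_axes `c(a, b)` semi-axes in mm (long axis <= 38.4 x 2 mm,
#'   short axis <= 19.2 x 2 mm).
#' @param orientation rotation in radians.
#' @param sos sound speed inside the inclusion in m/s.
#' @param echogenicity `"hyperechoic"`, `"hypoechoic"` or `"isoechoic"`.
#' @return An object of class `ellipse_inclusion`.
#' @export
ellipse_inclusion <- function(center, semi_axes, orientation = 0, sos,
                              echogenicity = "hyperechoic") {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes > 0), sos > 0)
  if (2 * max(semi_axes) > 2 * MEDIUM_EXTENT_MM ||
      2 * min(semi_axes) > MEDIUM_EXTENT_MM) {
    stop("ellipse axes exceed the allowed range")
  }
  echogenicity <- match.arg(echogenicity,
                            c("hyperechoic", "hypoechoic", "isoechoic"))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = orientation, sos = sos,
                 echogenicity = echogenicity),
            class = "ellipse_inclusion")
}

#' Horizontal tissue layer with an optionally curved upper boundary
#'
#' Layers partition the medium in depth. The upper boundary of a layer sits
#' at `z_top` mm and may be deformed by a sine perturbation
#' `z(x) = z_top + amplitude * sin(2*pi*periods*(x + 19.2)/38.4 + phase)`.
#'
#' @param z_top nominal upper boundary depth in mm.
#' @param sos sound speed of the layer in m/s.
#' @param amplitude,periods,phase sine deformation of the boundary
#'   (amplitude in mm; `amplitude = 0` gives a straight boundary).
#' @param echogenicity relative speckle brightness of the layer.
#' @return An object of class `layer_inclusion`.
#' @export
layer_inclusion <- function(z_top, sos, amplitude = 0, periods = 1,
                            phase = 0, echogenicity = "isoechoic") {
  stopifnot(z_top >= 0, z_top <= MEDIUM_EXTENT_MM, sos > 0, amplitude >= 0)
  echogenicity <- match.arg(echogenicity,
                            c("hyperechoic", "hypoechoic", "isoechoic"))
  structure(list(z_top = z_top, sos = sos, amplitude = amplitude,
                 periods = periods, phase = phase,
                 echogenicity = echogenicity),
            class = "layer_inclusion")
}

#' Parametric description of a digital tissue phantom
#'
#' @param background_sos background sound speed in m/s, in `[1400, 1600]`.
#' @param inclusions list of [ellipse_inclusion()] objects; later inclusions
#'   overwrite earlier ones where they overlap.
#' @param layers optional list of [layer_inclusion()] objects (ordered by
#'   increasing `z_top`); layers are rasterized before ellipses.
#' @param scatterer_density mean sub-resolution scatterer count per squared
#'   wavelength of the transmit pulse.
#' @param pattern_id `"training"`, `"pattern1_layered_curved"`,
#'   `"pattern2_layered_straight"` or `"pattern3_ellipse_hypoechoic"`.
#' @param rng_seed integer seed recorded with the spec; scatterer and
#'   echogenicity substreams are derived from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(background_sos, inclusions = list(), layers = NULL,
                         scatterer_density = 3, pattern_id = "training",
                         rng_seed = 1L) {
  if (background_sos < 1400 || background_sos > 1600) {
    stop("background_sos must lie in [1400, 1600] m/s")
  }
  stopifnot(scatterer_density >= 0)
  pattern_id <- match.arg(pattern_id,
                          c("training", "pattern1_layered_curved",
                            "pattern2_layered_straight",
                            "pattern3_ellipse_hypoechoic"))
  if (pattern_id == "training") {
    for (inc in inclusions) {
      if (inc$sos < background_sos) {
        stop("training inclusion SoS must not be below the background SoS")
      }
    }
  }
  structure(list(background_sos = background_sos, inclusions = inclusions,
                 layers = layers, scatterer_density = scatterer_density,
                 pattern_id = pattern_id, rng_seed = as.integer(rng_seed),
                 extent_mm = MEDIUM_EXTENT_MM),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s: background %.1f m/s, %d ellipse(s), %d layer(s), %.3g scatterers/lambda^2, seed %d\n",
              x$pattern_id, x$background_sos, length(x$inclusions),
              length(x$layers %||% list()), x$scatterer_density, x$rng_seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generation bounds for randomized training phantoms
#'
#' @param sos_background bounds of the uniform background-SoS law (m/s).
#' @param inclusion_increment bounds of the fractional SoS elevation of
#'   inclusions relative to the background.
#' @param n_inclusions integer range of the inclusion count (drawn uniformly).
#' @param long_axis,short_axis bounds of the ellipse full axes in mm.
#' @param scatterer_density mean scatterers per squared wavelength.
#' @return A list of generation bounds for [sample_training_phantom()].
#' @export
phantom_gen_config <- function(sos_background = c(1400, 1600),
                               inclusion_increment = c(0.01, 0.07),
                               n_inclusions = c(1L, 5L),
                               long_axis = c(2, 2 * MEDIUM_EXTENT_MM),
                               short_axis = c(1, MEDIUM_EXTENT_MM),
                               scatterer_density = 3) {
  for (b in list(sos_background, inclusion_increment, n_inclusions,
                 long_axis, short_axis)) {
    if (length(b) != 2L || b[1] > b[2]) {
      stop("invalid generation bounds (min > max)")
    }
  }
  list(sos_background = sos_background,
       inclusion_increment = inclusion_increment,
       n_inclusions = n_inclusions, long_axis = long_axis,
       short_axis = short_axis, scatterer_density = scatterer_density)
}

#' Sample a randomized training phantom
#'
#' Background SoS is drawn from `U[1400, 1600]` m/s; each inclusion's SoS is
#' `background * (1 + u)` with `u ~ U[0.01, 0.07]`; ellipse centres,
#' dimensions and orientations are drawn uniformly within the configured
#' bounds. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param config generation bounds from [phantom_gen_config()].
#' @return A [phantom_spec()].
#' @export
sample_training_phantom <- function(seed, config = phantom_gen_config()) {
  with_seed(substream_seed(seed, "geometry"), {
    bg <- runif(1, config$sos_background[1], config$sos_background[2])
    n_inc <- if (config$n_inclusions[2] >= config$n_inclusions[1]) {
      sample(config$n_inclusions[1]:config$n_inclusions[2], 1L)
    } else 0L
    incs <- lapply(seq_len(n_inc), function(k) {
      long <- runif(1, config$long_axis[1], config$long_axis[2])
      short <- runif(1, config$short_axis[1], min(config$short_axis[2], long))
      u <- runif(1, config$inclusion_increment[1],
                 config$inclusion_increment[2])
      ellipse_inclusion(
        center = c(runif(1, -MEDIUM_EXTENT_MM / 2, MEDIUM_EXTENT_MM / 2),
                   runif(1, 0, MEDIUM_EXTENT_MM)),
        semi_axes = c(long / 2, short / 2),
        orientation = runif(1, 0, pi),
        sos = bg * (1 + u),
        echogenicity = "hyperechoic"
      )
    })
    phantom_spec(background_sos = bg, inclusions = incs,
                 scatterer_density = config$scatterer_density,
                 pattern_id = "training", rng_seed = as.integer(seed))
  })
}

#' Sample an evaluation phantom (held-out patterns)
#'
#' The three evaluation patterns are structurally distinct from the training
#' distribution: pattern 1 is a two-layer medium with a sine-deformed (curved)
#' boundary and uniform echogenicity; pattern 2 has straight isoechoic layers
#' (2-3 layers); pattern 3 is a homogeneous background with hypoechoic
#' elliptical inclusions. SoS values reuse the training bounds
#' `U[1400, 1600]`, and layer SoS may fall below the background.
#'
#' @param pattern 1, 2, 3 or the corresponding `pattern_id` string.
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
make_evaluation_phantom <- function(pattern, seed) {
  ids <- c("pattern1_layered_curved", "pattern2_layered_straight",
           "pattern3_ellipse_hypoechoic")
  if (is.numeric(pattern)) {
    if (!pattern %in% 1:3) stop("unknown pattern id: ", pattern)
    pattern <- ids[pattern]
  }
  pattern <- match.arg(pattern, ids)
  with_seed(substream_seed(seed, paste0("eval-", pattern)), {
    bg <- runif(1, 1400, 1600)
    if (pattern == "pattern1_layered_curved") {
      lay <- list(layer_inclusion(
        z_top = runif(1, 12, 26), sos = runif(1, 1400, 1600),
        amplitude = runif(1, 1, 4), periods = sample(1:2, 1),
        phase = runif(1, 0, 2 * pi), echogenicity = "isoechoic"
      ))
      phantom_spec(bg, layers = lay, pattern_id = pattern,
                   rng_seed = as.integer(seed))
    } else if (pattern == "pattern2_layered_straight") {
      n_lay <- sample(1:2, 1)
      z <- sort(runif(n_lay, 8, 30))
      lay <- lapply(seq_len(n_lay), function(k) {
        layer_inclusion(z_top = z[k], sos = runif(1, 1400, 1600),
                        echogenicity = "isoechoic")
      })
      phantom_spec(bg, layers = lay, pattern_id = pattern,
                   rng_seed = as.integer(seed))
    } else {
      n_inc <- sample(1:3, 1)
      incs <- lapply(seq_len(n_inc), function(k) {
        long <- runif(1, 4, 16)
        ellipse_inclusion(
          center = c(runif(1, -12, 12), runif(1, 6, 32)),
          semi_axes = c(long / 2, runif(1, 2, long) / 2),
          orientation = runif(1, 0, pi),
          sos = runif(1, 1400, 1600) * runif(1, 1.0, 1.07),
          echogenicity = "hypoechoic"
        )
      })
      phantom_spec(bg, inclusions = incs, pattern_id = pattern,
                   rng_seed = as.integer(seed))
    }
  })
}

#' Generate a batch of evaluation phantoms
#'
#' @param n_per_pattern phantoms per pattern (the reference protocol uses 40
#'   per pattern, 120 in total).
#' @param seed integer seed.
#' @param patterns patterns to include (default all three).
#' @return A list of [phantom_spec()] objects of length
#'   `length(patterns) * n_per_pattern`.
#' @export
make_evaluation_batch <- function(n_per_pattern = 40L, seed = 1L,
                                  patterns = 1:3) {
  out <- list()
  for (p in patterns) {
    for (k in seq_len(n_per_pattern)) {
      out[[length(out) + 1L]] <-
        make_evaluation_phantom(p, substream_seed(seed, sprintf("p%d-%d", p, k)))
    }
  }
  out
}
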