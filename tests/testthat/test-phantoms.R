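# Digital phantom generation: sampling laws, rasterization geometry,
# echogenicity and scatterer fields, labels.

test_that("training phantom sampling follows the stated uniform laws", {
  specs <- lapply(1:400, function(s) sample_training_phantom(s))
  bgs <- vapply(specs, `[[`, numeric(1), "background_sos")
  expect_true(all(bgs >= 1400 & bgs <= 1600))
  expect_lt(abs(mean(bgs) - 1500), 10)
  # inclusion SoS sits 1-7 % above its background
  for (sp in specs[1:80]) {
    for (inc in sp$inclusions) {
      u <- inc$sos / sp$background_sos - 1
      expect_true(u >= 0.01 - 1e-12 && u <= 0.07 + 1e-12)
    }
  }
  # large-sample goodness of fit of the background law
  big <- with_seed(1, runif(1e5, 1400, 1600))  # reference uniform draw
  ks <- suppressWarnings(ks.test(bgs, function(q) punif(q, 1400, 1600)))
  expect_gt(ks$p.value, 1e-4)
  expect_true(all(big >= 1400 & big <= 1600))
})

test_that("phantom sampling is deterministic and validates bounds", {
  a <- sample_training_phantom(7)
  b <- sample_training_phantom(7)
  expect_identical(a, b)
  expect_error(phantom_gen_config(sos_background = c(1600, 1400)),
               "invalid generation bounds")
  expect_error(phantom_spec(1300), "1400")
})

test_that("rasterization matches analytic ellipse area and overwrite rule", {
  grid <- sim_grid(256)  # 0.15 mm
  spec <- phantom_spec(
    1500,
    inclusions = list(
      ellipse_inclusion(c(0, 19.2), c(5, 5), 0, 1550),
      ellipse_inclusion(c(0, 19.2), c(2, 2), 0, 1580)
    ),
    rng_seed = 1L
  )
  med <- rasterize_medium(spec, grid)
  r_px <- 5 / grid$dx
  n_in_circle <- sum(med$sos > 1500)
  expect_within(n_in_circle, pi * r_px^2, 2 * pi * r_px + 4)
  # later inclusion overwrites earlier one where they overlap
  expect_within(sum(med$sos == 1580), pi * (2 / grid$dx)^2,
                2 * pi * (2 / grid$dx) + 4)
  # homogeneous spec rasterizes to a constant field
  flat <- rasterize_medium(phantom_spec(1540), grid)
  expect_true(all(flat$sos == 1540))
  expect_equal(dim(flat$sos), c(256L, 256L))
  # grid extent must be 38.4 mm
  expect_error(rasterize_medium(spec, sim_grid(c(128, 256), dx = 0.15)),
               "extent")
})

test_that("full-scale grid arithmetic: 1536 x 0.025 mm spans 38.4 mm", {
  g <- sim_grid(1536, 0.025)
  expect_equal(g$nz * g$dx, 38.4)
  expect_equal(g$nx * g$dx, 38.4)
})

test_that("hyperechoic echogenicity modifies ~10% of interior points by 7-11%", {
  grid <- sim_grid(256)
  spec <- phantom_spec(1500,
                       inclusions = list(
                         ellipse_inclusion(c(0, 19.2), c(8, 8), 0, 1520,
                                           "hyperechoic")),
                       rng_seed = 3L)
  med0 <- rasterize_medium(spec, grid)
  med <- apply_echogenicity(med0)
  n_interior <- sum(med0$region_id == 1L)
  changed <- med$sos != med0$sos
  frac <- sum(changed) / n_interior
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
  vals <- med$sos[changed]
  expect_true(all(vals >= 1500 * 1.07 - 1e-9 & vals <= 1500 * 1.11 + 1e-9))
  # isoechoic inclusions are untouched
  spec_iso <- phantom_spec(1500,
                           inclusions = list(
                             ellipse_inclusion(c(0, 19.2), c(8, 8), 0, 1520,
                                               "isoechoic")),
                           rng_seed = 3L)
  med_iso <- apply_echogenicity(rasterize_medium(spec_iso, grid))
  expect_true(all(med_iso$sos == rasterize_medium(spec_iso, grid)$sos))
})

test_that("scatterer field matches density, amplitude law and carrier", {
  grid <- sim_grid(256)
  spec <- phantom_spec(1540, rng_seed = 5L)
  med <- rasterize_medium(spec, grid)
  res <- sprinkle_scatterers(med, density = 3, fc = 7e6)
  lambda_mm <- 1540 / 7e6 * 1e3
  expected <- 3 * 38.4^2 / lambda_mm^2
  expect_within(nrow(res$scatterers), expected, 3 * sqrt(expected))
  expect_true(all(abs(res$scatterers$amplitude) <= 0.03))
  # Kolmogorov-Smirnov check of the amplitude law at large n
  amps <- with_seed(9, {
    m <- sprinkle_scatterers(med, density = 10, fc = 7e6, seed = 9)
    m$scatterers$amplitude
  })
  ks <- suppressWarnings(ks.test(amps, function(q) punif(q, -0.03, 0.03)))
  expect_gt(ks$p.value, 1e-4)
  # density scattering perturbs mass density, not the SoS label
  expect_true(all(res$medium$sos == med$sos))
  expect_false(all(res$medium$density == med$density))
  # zero density is a no-op; negative density errors
  none <- sprinkle_scatterers(med, density = 0)
  expect_identical(none$medium$density, med$density)
  expect_error(sprinkle_scatterers(med, density = -1), "non-negative")
})

test_that("labels are block means of the bulk SoS, excluding perturbations", {
  grid <- sim_grid(1536, 0.025)
  # two-layer split at mid depth
  spec <- phantom_spec(1500,
                       layers = list(layer_inclusion(z_top = 19.2,
                                                     sos = 1550)),
                       rng_seed = 2L)
  med <- rasterize_medium(spec, grid)
  med <- apply_echogenicity(med)
  med <- sprinkle_scatterers(med, fc = 7e6)$medium
  lab <- label_from_medium(med)
  expect_equal(dim(lab), c(384L, 384L))
  expect_equal(attr(lab, "pixel_size"), 0.1)
  expect_true(all(lab[1:192, ] == 1500))
  expect_true(all(lab[193:384, ] == 1550))
  # constant medium -> constant label
  flat <- label_from_medium(
    acoustic_medium(sos = matrix(1540, 768, 768), dx = 0.05))
  expect_true(all(flat == 1540))
  # region-mean conservation away from boundaries
  expect_lt(abs(mean(lab[1:190, ]) - 1500), 0.5)
  expect_error(label_from_medium(
    acoustic_medium(sos = matrix(1540, 100, 100), dx = 0.1),
    method = "block"), "divisible")
})

test_that("evaluation phantoms cover the three held-out patterns", {
  p1 <- make_evaluation_phantom(1, 4)
  p2 <- make_evaluation_phantom(2, 4)
  p3 <- make_evaluation_phantom(3, 4)
  expect_equal(p1$pattern_id, "pattern1_layered_curved")
  expect_gt(p1$layers[[1]]$amplitude, 0)
  expect_equal(p2$pattern_id, "pattern2_layered_straight")
  expect_true(all(vapply(p2$layers, function(l) l$amplitude, 1) == 0))
  expect_equal(p3$pattern_id, "pattern3_ellipse_hypoechoic")
  expect_true(all(vapply(p3$inclusions, `[[`, "", "echogenicity") ==
                    "hypoechoic"))
  # training phantoms never carry evaluation layer geometries
  tr <- sample_training_phantom(1)
  expect_equal(tr$pattern_id, "training")
  expect_null(tr$layers)
  # batch protocol: 40 per pattern -> 120 specs
  batch <- make_evaluation_batch(n_per_pattern = 2, seed = 1)
  expect_length(batch, 6L)
  expect_error(make_evaluation_phantom(9, 1), "unknown pattern")
  # pattern 1 with identical layer SoS: constant field despite the boundary
  p1c <- p1
  p1c$layers[[1]]$sos <- p1$background_sos
  medc <- rasterize_medium(p1c, sim_grid(128))
  expect_true(all(medc$sos == p1$background_sos))
})

test_that("point absorbers rasterize points and disks", {
  grid <- sim_grid(128)
  expect_true(all(place_point_absorbers(NULL, grid) == 0))
  one <- place_point_absorbers(cbind(0, 20), grid)
  expect_equal(sum(one), 1)
  # 0.5 mm diameter disk at 0.05 mm pitch covers ~ pi * 5^2 pixels
  g05 <- sim_grid(768, 0.05)
  disk <- place_point_absorbers(cbind(0, 20), g05, radius_mm = 0.25)
  expect_within(sum(disk), pi * 5^2, 4)
  expect_error(place_point_absorbers(cbind(0, 100), grid), "outside")
})

test_that("phantom specs round-trip through JSON", {
  spec <- make_evaluation_phantom(1, 12)
  js <- spec_to_json(spec)
  back <- spec_from_json(js)
  expect_equal(back$background_sos, spec$background_sos)
  expect_equal(back$layers[[1]]$z_top, spec$layers[[1]]$z_top)
  expect_equal(back$pattern_id, spec$pattern_id)
})

test_that("datasets and simulation profiles round-trip through disk", {
  ds <- fx_tiny_dataset(6)
  path <- tempfile(fileext = ".rds")
  write_rf_dataset(ds, path)
  back <- read_rf_dataset(path)
  expect_equal(back$rf, ds$rf)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$specs[[2]]$background_sos,
               ds$specs[[2]]$background_sos)
  sim <- desk_profile(fc = 0.8e6, n_cycles = 3)
  yml <- tempfile(fileext = ".yaml")
  write_sim_profile(sim, yml)
  sim2 <- read_sim_profile(yml)
  expect_equal(sim2$fc, sim$fc)
  expect_equal(sim2$grid$dx, sim$grid$dx)
  expect_equal(sim2$n_cycles, 3)
})
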