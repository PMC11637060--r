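# Evaluation metrics against closed forms and independent brute-force
# evaluations.

test_that("SoS RMSE matches hand evaluations", {
  gt <- matrix(1500, 4, 4)
  expect_equal(rmse_sos(gt, gt), 0)
  expect_equal(rmse_sos(1540, gt), 40)
  expect_equal(rmse_sos(matrix(c(1500, 1520), 1), matrix(c(1510, 1540), 1)),
               sqrt(250))
  # masked evaluation and broadcast scalars on random fields vs brute force
  est <- with_seed(1, matrix(runif(64, 1400, 1600), 8))
  gt8 <- with_seed(2, matrix(runif(64, 1400, 1600), 8))
  mask <- with_seed(3, matrix(runif(64) > 0.4, 8))
  brute <- sqrt(sum((est[mask] - gt8[mask])^2) / sum(mask))
  expect_equal(rmse_sos(est, gt8, mask), brute, tolerance = 1e-12)
  expect_error(rmse_sos(est, gt8, mask & FALSE), "empty mask")
})

test_that("region SSIM matches the single-window formula", {
  x <- with_seed(4, matrix(runif(64), 8))
  expect_equal(region_ssim(x, x), 1)
  # x = 0 vs y = 1: closed form C1 / (1 + C1)
  z <- matrix(0, 8, 8); o <- matrix(1, 8, 8)
  expect_equal(region_ssim(z, o), 1e-4 / (1 + 1e-4), tolerance = 1e-12)
  # independent brute-force evaluation on random 8x8 fields
  y <- 0.5 * x
  n <- 64
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  vxy <- sum((x - mx) * (y - my)) / n
  C1 <- 1e-4; C2 <- 9e-4
  brute <- ((2 * mx * my + C1) * (2 * vxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(region_ssim(x, y), brute, tolerance = 1e-10)
  expect_true(abs(region_ssim(x, y)) <= 1)
  expect_equal(region_ssim(z, z), 1)
})

test_that("lateral FWHM matches analytic profiles", {
  # Gaussian profile, sigma = 0.5 mm -> FWHM = 2 sqrt(2 ln 2) * 0.5
  px <- 0.05
  xs <- seq(-5, 5, by = px)
  g <- exp(-xs^2 / (2 * 0.5^2))
  img <- pa_image(rbind(0 * g, g, 0 * g), pixel_size = px)
  expect_within(lateral_fwhm(img, peak = c(2, which.max(g))),
                2 * sqrt(2 * log(2)) * 0.5, 0.01)
  # single-pixel impulse at 0.05 mm pitch -> interpolated width <= 0.1 mm
  imp <- matrix(0, 3, 41); imp[2, 21] <- 1
  expect_lte(lateral_fwhm(pa_image(imp, pixel_size = px)), 0.1)
  # rectangular profile of width 1 mm -> 1.0 +- 0.05 mm
  rect <- matrix(0, 3, 101)
  rect[2, 41:60] <- 1  # 20 px x 0.05 mm
  expect_within(lateral_fwhm(pa_image(rect, pixel_size = px)), 1.0, 0.05)
  # unresolved profiles are flagged
  flat <- matrix(1, 3, 5); flat[2, 3] <- 1.1
  expect_warning(v <- lateral_fwhm(pa_image(flat, pixel_size = 1)),
                 "unresolved")
  expect_true(is.na(v))
})

test_that("SNR follows 20 log10(mu/sigma) with the 0.35 intensity split", {
  with_seed(5, {
    img <- matrix(abs(rnorm(300 * 300, 0, 0.02)), 300)
    img[1:50, 1:50] <- 1.0
    img[img >= 0.35 & row(img) > 50] <- 0.3
    meas <- snr_db(pa_image(img, 0.05))
    bg <- img[img < 0.35]
    expect_equal(meas, 20 * log10(mean(img[img >= 0.35]) / sd(bg)),
                 tolerance = 1e-12)
  })
  # signal 1.0 over background alternating 0 / 0.2 (sd -> 0.1): 20 dB, and
  # the same ratio at signal 0.5 over 0 / 0.1
  mk <- function(sig, bg_hi, n = 200) {
    m <- matrix(rep(c(0, bg_hi), length.out = n * n), n)
    m[1:40, 1:40] <- sig
    m
  }
  expect_within(snr_db(mk(1, 0.2), 0.35), 20, 0.05)
  expect_within(snr_db(mk(0.5, 0.1), 0.35), 20, 0.05)
  expect_warning(snr_db(matrix(0.01, 4, 4)), "degenerate")
})

test_that("region masks partition the phantom on the label grid", {
  spec <- phantom_spec(1500,
                       inclusions = list(
                         ellipse_inclusion(c(0, 19.2), c(6, 4), 0.3, 1550)),
                       rng_seed = 1L)
  med <- rasterize_medium(spec, sim_grid(1536, 0.025))
  masks <- region_masks(med)
  expect_named(masks, c("background", "region_1"))
  total <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_true(all(total == 1))
  lab <- label_from_medium(med)
  expect_lt(rmse_sos(1550, lab, masks$region_1), 5)
})

test_that("sharpness metrics prefer concentrated energy", {
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  spread <- matrix(0, 16, 16); spread[8, 7:10] <- 0.5  # same energy, 4 px
  for (m in c("normalized_power", "brenner")) {
    expect_gt(sharpness(imp, m), sharpness(spread, m))
  }
  # uniform image scores lowest among equal-energy images
  unif <- matrix(1 / 16, 16, 16)
  expect_lt(sharpness(unif), sharpness(spread))
  # scale invariance of the normalized-power metric
  expect_equal(sharpness(imp), sharpness(pa_image(imp * 7, 0.05)))
  # direct formula evaluation
  I <- with_seed(7, matrix(runif(64), 8))
  In <- I / max(I)
  expect_equal(sharpness(I), sum(In^4) / sum(In^2)^2, tolerance = 1e-12)
  expect_warning(s0 <- sharpness(matrix(0, 4, 4)), "all-zero")
  expect_equal(s0, 0)
})

test_that("the evaluation harness assembles per-region method comparisons", {
  sim <- desk_profile()
  sim$autofocus_step <- 50   # coarse sweep keeps the baseline column cheap
  ph <- list(make_evaluation_phantom(3, 6))
  model <- build_sosnet(fx_tiny_cfg(), seed = 1)
  tab <- evaluate_suite(ph, methods = c("conventional", "dl"), model = model,
                        sim = sim, pa_sources = rbind(c(-4, 10), c(4, 22)),
                        seed = 2)
  expect_s3_class(tab, "data.frame")
  expect_setequal(unique(tab$method), c("conventional", "dl"))
  expect_true(all(c("background", "global", "pa_roi") %in% tab$region))
  rmse_rows <- tab[tab$region != "pa_roi", ]
  expect_true(all(is.finite(rmse_rows$rmse)))
  pa_rows <- tab[tab$region == "pa_roi", ]
  expect_true(all(is.finite(pa_rows$ssim)))
  # a phantom whose background is exactly 1540 gives zero background RMSE
  # for the conventional column
  ph1540 <- phantom_spec(1540, rng_seed = 9L)
  tab2 <- evaluate_suite(list(ph1540), methods = "conventional", sim = sim,
                         seed = 3)
  expect_equal(tab2$rmse[tab2$region == "background"], 0)
})
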