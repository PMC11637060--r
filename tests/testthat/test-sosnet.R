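# Encoder-decoder SoS regression network: construction, gradients, training
# mechanics and transfer learning.

test_that("network maps 128x1024 frames to finite 384x384 maps, deterministically", {
  cfg <- fx_tiny_cfg()
  m <- build_sosnet(cfg, seed = 3)
  x <- matrix(0, 128, 1024)
  p <- predict_sos(m, x)
  expect_equal(dim(p), c(384L, 384L))
  expect_true(all(is.finite(p)))
  # identical seeds give identical initial parameters and predictions
  m2 <- build_sosnet(cfg, seed = 3)
  expect_identical(m$ops, m2$ops)
  m3 <- build_sosnet(cfg, seed = 4)
  expect_false(identical(m$ops, m3$ops))
  # kernel-width progressions: encoder 3x15 -> 3x3, decoder 3x3 -> 3x11
  expect_equal(cfg$enc_kw, c(15L, 13L, 11L, 9L, 7L, 5L, 3L))
  expect_equal(cfg$dec_kw, c(3L, 5L, 7L, 9L, 11L))
  expect_error(predict_sos(m, matrix(0, 64, 1024)), "expected")
})

test_that("parameter count matches closed-form layer arithmetic", {
  cfg <- sosnet_config_small(width_scale = 16)
  m <- build_sosnet(cfg, seed = 1)
  # independent count: conv = cout*(cin*kh*kw + 1), BN adds 2*cout
  w <- cfg$enc_widths; d <- cfg$dec_widths
  cin <- c(1, w[-7])
  enc <- sum(w * (cin * 3 * cfg$enc_kw + 1)) + sum(2 * w)
  dec_cin <- c(w[7] + w[6], d[1] + w[5], d[2], d[3], d[4])
  dec <- sum(d * (dec_cin * 3 * cfg$dec_kw + 1)) + sum(2 * d[1:4])
  head <- cfg$head_width * (d[5] * 9 + 1) + 2 * cfg$head_width +
    1 * (cfg$head_width + 1)
  expect_equal(count_params(m), enc + dec + head)
})

test_that("backpropagation matches finite differences", {
  cfg <- fx_tiny_cfg()
  m <- build_sosnet(cfg, seed = 7)
  xs <- with_seed(1, lapply(1:2, function(i) {
    array(rnorm(128 * 1024), c(128, 1024, 1))
  }))
  ts <- with_seed(2, lapply(1:2, function(i) {
    array(rnorm(384 * 384, 0, 0.5), c(384, 384, 1))
  }))
  loss_fn <- function(model) {
    fwd <- pasos:::model_forward_full(model, xs, training = TRUE)
    pasos:::mse_internal(fwd$y, ts)
  }
  fwd <- pasos:::model_forward_full(m, xs, training = TRUE)
  npx <- prod(dim(fwd$y[[1]]))
  gys <- Map(function(y, t) 2 * (y - t) / (npx * length(xs)), fwd$y, ts)
  bw <- pasos:::net_backward(m$ops, fwd$fw, xs, gys, m$cfg$lrelu_slope)
  refs <- pasos:::collect_trainable(m$ops)
  picks <- with_seed(42, sample(length(refs), 8))
  for (ri in picks) {
    ref <- refs[[ri]]
    p <- pasos:::get_param(m$ops, ref)
    g <- pasos:::grad_of(bw$pgrads, ref)
    i <- with_seed(ri, sample(length(p), 1))
    eps <- 1e-5
    bump <- function(sign) {
      mm <- m
      q <- p; q[i] <- q[i] + sign * eps
      mm$ops <- pasos:::set_param(mm$ops, ref, q)
      loss_fn(mm)
    }
    num <- (bump(1) - bump(-1)) / (2 * eps)
    expect_lt(abs(g[i] - num), 5e-3 * max(abs(num), 1e-3))
  }
})

test_that("zero learning rate leaves parameters unchanged; training learns", {
  ds <- fx_tiny_dataset(6)
  cfg <- fx_tiny_cfg()
  m <- build_sosnet(cfg, seed = 2)
  frozen <- train_sosnet(m, ds, train_config(lr = 1e-30, epochs = 1,
                                             batch = 3, seed = 1))
  expect_equal(frozen$model$ops[[1]]$params$W, m$ops[[1]]$params$W,
               tolerance = 1e-12)
  fit <- train_sosnet(m, ds, train_config(lr = 0.02, epochs = 4, batch = 3,
                                          momentum = 0.9, seed = 1))
  expect_lt(tail(fit$history$train_rmse, 1), fit$history$train_rmse[1])
  expect_true(all(is.finite(fit$history$train_rmse)))
})

test_that("the network can overfit identical copies of one frame", {
  ds0 <- fx_tiny_dataset(6)
  ds <- list(rf = ds0$rf[rep(1, 5), , ], labels = ds0$labels[rep(1, 5), , ])
  cfg <- fx_tiny_cfg()
  m <- build_sosnet(cfg, seed = 6)
  fit <- train_sosnet(m, ds, train_config(lr = 0.05, epochs = 25, batch = 5,
                                          momentum = 0.9, seed = 3))
  expect_lt(min(fit$history$train_rmse), 5)
})

test_that("residual head starts near zero and fine-tuning freezes the base", {
  ds <- fx_tiny_dataset(6)
  cfg <- fx_tiny_cfg()
  base <- build_sosnet(cfg, seed = 2)
  aug <- attach_residual_head(base, width = 4, seed = 5)
  x <- ds$rf[1, , ]
  expect_lt(max(abs(predict_sos(aug, x) - predict_sos(base, x))), 1e-3)
  # head is small relative to a full-width base
  big <- build_sosnet(sosnet_config_small(width_scale = 4), seed = 1)
  big_aug <- attach_residual_head(big, width = 8, seed = 1)
  expect_lt(count_params(big_aug, head_only = TRUE),
            0.05 * count_params(big))
  # fine-tuning updates only the head; the 20-epoch cap is honored
  ft <- fine_tune(aug, ds, train_config(lr = 0.05, epochs = 3, batch = 3,
                                        momentum = 0.9, seed = 4))
  expect_identical(ft$model$ops, aug$ops)
  expect_false(identical(ft$model$head$ops, aug$head$ops))
  expect_lte(nrow(ft$history), 3)
  expect_error(fine_tune(base, ds), "attach_residual_head")
})

test_that("prediction warns on unconditioned input and training rejects NaN", {
  cfg <- fx_tiny_cfg()
  m <- build_sosnet(cfg, seed = 1)
  x <- matrix(rnorm(128 * 1024, mean = 5), 128)
  expect_warning(predict_sos(m, x), "conditioned")
  bad <- list(rf = array(NaN, c(2, 128, 1024)),
              labels = array(1500, c(2, 384, 384)))
  expect_error(train_sosnet(m, bad, train_config(lr = 1e-4, epochs = 1,
                                                 batch = 2)),
               "non-finite")
})

test_that("checkpoints round-trip through disk", {
  cfg <- fx_tiny_cfg()
  m <- build_sosnet(cfg, seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- matrix(0, 128, 1024)
  expect_identical(unclass(predict_sos(m, x)), unclass(predict_sos(m2, x)))
  expect_true(file.exists(paste0(path, ".json")))
})
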