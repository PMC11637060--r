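# The SoS regression network: a fully convolutional encoder-decoder mapping
# a conditioned 128 x 1024 RF frame to a 384 x 384 pixel-wise SoS map.
#
# Encoder: seven stages with non-square kernels whose width shrinks from
# 3 x 15 to 3 x 3 in steps of two. The first four stages are strided
# convolutions (the 1024-sample time axis contracts faster than the
# 128-channel axis) each followed by LeakyReLU and BatchNorm; the next three
# stages add 2 x 2 max pooling between the LeakyReLU and the BatchNorm.
# Decoder: five resize-convolutions (nearest x2 upsampling + convolution)
# with kernel widths growing from 3 x 3 to 3 x 11, a bilinear Resizing stage
# to 384 x 384 after the fifth convolution, a 3 x 3 convolution with
# BatchNorm, and a final 1 x 1 convolution. The outputs of encoder stages 5
# and 6 are concatenated to the matching-resolution decoder stages (encoder
# stage 7 is the decoder input). Weights are Xavier-initialized.
#
# The network regresses the standardized sound speed (SoS - 1500)/100
# internally; predictions are mapped back to m/s.

SOS_CENTER <- 1500
SOS_SCALE <- 100

#' Network configuration
#'
#' @param enc_widths channel widths of the seven encoder stages.
#' @param dec_widths channel widths of the five decoder resize-convolutions.
#' @param head_width channel width of the post-resize 3 x 3 convolution.
#' @param input_shape RF frame shape (channels, samples).
#' @param output_shape SoS map shape.
#' @param lrelu_slope negative slope of the LeakyReLU activations.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @return A `sosnet_config` list. The default widths give the full-scale
#'   model; narrow-width instances of the same topology are used for
#'   desk-scale studies.
#' @export
sosnet_config <- function(enc_widths = c(32, 64, 128, 256, 256, 256, 256),
                          dec_widths = c(256, 256, 128, 64, 32),
                          head_width = 32,
                          input_shape = c(128L, 1024L),
                          output_shape = c(384L, 384L),
                          lrelu_slope = 0.1, bn_momentum = 0.9) {
  stopifnot(length(enc_widths) == 7L, length(dec_widths) == 5L)
  structure(list(enc_widths = enc_widths, dec_widths = dec_widths,
                 head_width = head_width,
                 input_shape = as.integer(input_shape),
                 output_shape = as.integer(output_shape),
                 enc_kw = c(15L, 13L, 11L, 9L, 7L, 5L, 3L),
                 dec_kw = c(3L, 5L, 7L, 9L, 11L),
                 enc_stride = list(c(1L, 4L), c(1L, 2L), c(2L, 2L),
                                   c(2L, 2L), c(1L, 1L), c(1L, 1L),
                                   c(1L, 1L)),
                 skips = list(c(enc = 6L, dec = 1L), c(enc = 5L, dec = 2L)),
                 lrelu_slope = lrelu_slope, bn_momentum = bn_momentum,
                 bn_eps = 1e-5),
            class = "sosnet_config")
}

#' Narrow-width configuration for desk-scale experiments
#'
#' Same topology as [sosnet_config()] with few channels per stage, sized for
#' single-CPU training studies.
#'
#' @param width_scale channels per stage are the full widths divided by this.
#' @return A `sosnet_config`.
#' @export
sosnet_config_small <- function(width_scale = 16) {
  cfg <- sosnet_config()
  sosnet_config(enc_widths = pmax(2, cfg$enc_widths / width_scale),
                dec_widths = pmax(2, cfg$dec_widths / width_scale),
                head_width = max(2, cfg$head_width / width_scale))
}

new_conv_op <- function(id, input, cin, cout, kh, kw, sh, sw, act = TRUE,
                        bn = TRUE, pool = FALSE) {
  list(id = id, type = "conv", input = input,
       cfg = list(kh = kh, kw = kw, sh = sh, sw = sw,
                  ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L,
                  cin = cin, cout = cout),
       act = act, bn = bn, pool = pool)
}

#' Build the SoS regression network
#'
#' Constructs the encoder-decoder with Xavier-initialized convolutions.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [sosnet_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `sosnet`.
#' @export
build_sosnet <- function(cfg = sosnet_config(), seed = 1L) {
  ops <- list()
  id <- 0L
  add <- function(op) {
    ops[[op$id]] <<- op
  }
  # encoder
  cin <- 1L
  enc_out <- integer(7)
  prev <- 0L
  for (s in 1:7) {
    id <- id + 1L
    st <- cfg$enc_stride[[s]]
    add(new_conv_op(id, prev, cin, cfg$enc_widths[s], 3L, cfg$enc_kw[s],
                    st[1], st[2], act = TRUE, bn = TRUE, pool = s >= 5))
    enc_out[s] <- id
    prev <- id
    cin <- cfg$enc_widths[s]
  }
  # decoder resize-convs with skip concatenations
  for (d in 1:5) {
    id <- id + 1L
    up_id <- id
    ops[[up_id]] <- list(id = up_id, type = "upsample2", input = prev)
    prev <- up_id
    cin_d <- cin
    skip <- Filter(function(sk) sk["dec"] == d, cfg$skips)
    if (length(skip)) {
      src <- enc_out[skip[[1]]["enc"]]
      id <- id + 1L
      ops[[id]] <- list(id = id, type = "concat", input = prev, skip = src)
      cin_d <- cin + cfg$enc_widths[skip[[1]]["enc"]]
      prev <- id
    }
    id <- id + 1L
    add(new_conv_op(id, prev, cin_d, cfg$dec_widths[d], 3L, cfg$dec_kw[d],
                    1L, 1L, act = TRUE, bn = d < 5, pool = FALSE))
    if (d == 5) ops[[id]]$act <- FALSE  # stage 5: convolution + resizing only
    prev <- id
    cin <- cfg$dec_widths[d]
  }
  # resizing stage to the output shape
  id <- id + 1L
  ops[[id]] <- list(id = id, type = "resize", input = prev,
                    out = cfg$output_shape)
  prev <- id
  # 3x3 convolution + BN, then the final 1x1 convolution
  id <- id + 1L
  add(new_conv_op(id, prev, cin, cfg$head_width, 3L, 3L, 1L, 1L,
                  act = TRUE, bn = TRUE))
  prev <- id
  id <- id + 1L
  add(new_conv_op(id, prev, cfg$head_width, 1L, 1L, 1L, 1L, 1L,
                  act = FALSE, bn = FALSE))

  model <- structure(list(ops = ops, cfg = cfg, seed = seed, head = NULL),
                     class = "sosnet")
  init_params(model, seed)
}

init_params <- function(model, seed) {
  with_seed(substream_seed(seed, "init"), {
    for (i in seq_along(model$ops)) {
      op <- model$ops[[i]]
      if (op$type != "conv") next
      p <- conv_init(op$cfg$kh, op$cfg$kw, op$cfg$cin, op$cfg$cout)
      op$params <- p
      if (op$bn) {
        op$bn_params <- list(gamma = rep(1, op$cfg$cout),
                             beta = numeric(op$cfg$cout),
                             rmean = numeric(op$cfg$cout),
                             rvar = rep(1, op$cfg$cout))
      }
      model$ops[[i]] <- op
    }
    model
  })
}

#' @export
print.sosnet <- function(x, ...) {
  cat(sprintf("<sosnet> %d ops, %s parameters%s\n", length(x$ops),
              format(count_params(x), big.mark = ","),
              if (!is.null(x$head)) " + residual head" else ""))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `sosnet`.
#' @param head_only count only the residual head.
#' @return Integer parameter count (convolution weights and biases plus
#'   BatchNorm scales and shifts).
#' @export
count_params <- function(model, head_only = FALSE) {
  cnt <- function(ops) {
    n <- 0
    for (op in ops) {
      if (op$type != "conv") next
      n <- n + length(op$params$W) + length(op$params$b)
      if (isTRUE(op$bn)) {
        n <- n + length(op$bn_params$gamma) + length(op$bn_params$beta)
      }
    }
    n
  }
  if (head_only) {
    if (is.null(model$head)) return(0L)
    return(cnt(model$head$ops))
  }
  cnt(model$ops) + if (!is.null(model$head)) cnt(model$head$ops) else 0L
}

# forward pass over a batch (list of (H,W,1) arrays); returns activations and
# caches for backward. training toggles BN batch statistics.
net_forward <- function(ops, xs, slope, bn_eps, training = FALSE) {
  acts <- vector("list", length(ops))
  caches <- vector("list", length(ops))
  get_in <- function(idx) if (idx == 0L) xs else acts[[idx]]
  for (op in ops) {
    xin <- get_in(op$input)
    if (op$type == "conv") {
      ys <- lapply(xin, function(x) conv_fwd(x, op$params, op$cfg))
      cache <- list(x = xin)
      if (op$act) {
        lr <- lapply(ys, lrelu_fwd, slope = slope)
        ys <- lapply(lr, `[[`, "y")
        cache$lrelu_mask <- lapply(lr, `[[`, "mask")
      }
      if (isTRUE(op$pool)) {
        mp <- lapply(ys, .maxpool2_forward)
        cache$pool_in_dim <- dim(ys[[1]])
        ys <- lapply(mp, `[[`, "y")
        cache$pool_idx <- lapply(mp, `[[`, "idx")
      }
      if (isTRUE(op$bn)) {
        bnp <- op$bn_params
        bn <- bn_fwd(ys, bnp$gamma, bnp$beta, bn_eps, training,
                     bnp$rmean, bnp$rvar)
        ys <- bn$y
        cache$bn <- bn[c("xhat", "mu", "var", "inv_sd", "dim")]
      }
      acts[[op$id]] <- ys
      caches[[op$id]] <- cache
    } else if (op$type == "upsample2") {
      acts[[op$id]] <- lapply(xin, .upsample2_forward)
    } else if (op$type == "concat") {
      skip <- acts[[op$skip]]
      acts[[op$id]] <- Map(concat_channels, xin, skip)
      caches[[op$id]] <- list(n_main = dim(xin[[1]])[3])
    } else if (op$type == "resize") {
      caches[[op$id]] <- list(in_dim = dim(xin[[1]]))
      acts[[op$id]] <- lapply(xin, function(x) {
        .resize_bilinear_forward(x, op$out[1], op$out[2])
      })
    } else {
      stop("unknown op type: ", op$type)
    }
  }
  list(acts = acts, caches = caches)
}

# backward pass: gys is the gradient at the final op's output.
# Returns per-op parameter gradients and (optionally) the gradient at the
# network input.
net_backward <- function(ops, fw, xs, gys, slope, want_input_grad = FALSE) {
  grads <- vector("list", length(ops))      # gradient w.r.t. each op output
  pgrads <- vector("list", length(ops))     # parameter gradients
  grads[[length(ops)]] <- gys
  gx_input <- NULL
  add_grad <- function(idx, gs) {
    if (idx == 0L) {
      if (want_input_grad) {
        gx_input <<- if (is.null(gx_input)) gs else Map(`+`, gx_input, gs)
      }
      return(invisible())
    }
    grads[[idx]] <<- if (is.null(grads[[idx]])) gs else
      Map(`+`, grads[[idx]], gs)
  }
  for (k in rev(seq_along(ops))) {
    op <- ops[[k]]
    g <- grads[[op$id]]
    if (is.null(g)) next
    if (op$type == "conv") {
      cache <- fw$caches[[op$id]]
      if (isTRUE(op$bn)) {
        bb <- bn_bwd(g, cache$bn, op$bn_params$gamma)
        g <- bb$gx
        pgrads[[op$id]]$dgamma <- bb$dgamma
        pgrads[[op$id]]$dbeta <- bb$dbeta
      }
      if (isTRUE(op$pool)) {
        d <- cache$pool_in_dim
        g <- Map(function(gy, idx) .maxpool2_backward(gy, idx, d[1], d[2]),
                 g, cache$pool_idx)
      }
      if (op$act) {
        g <- Map(function(gy, m) lrelu_bwd(gy, m, slope), g,
                 cache$lrelu_mask)
      }
      gw <- NULL; gb <- NULL; gxs <- vector("list", length(g))
      for (i in seq_along(g)) {
        bw <- conv_bwd(cache$x[[i]], op$params, g[[i]], op$cfg)
        gw <- if (is.null(gw)) bw$gw else gw + bw$gw
        gb <- if (is.null(gb)) bw$gb else gb + bw$gb
        gxs[[i]] <- bw$gx
      }
      pgrads[[op$id]]$dW <- gw
      pgrads[[op$id]]$db <- gb
      add_grad(op$input, gxs)
    } else if (op$type == "upsample2") {
      add_grad(op$input, lapply(g, .upsample2_backward))
    } else if (op$type == "concat") {
      nm <- fw$caches[[op$id]]$n_main
      add_grad(op$input, lapply(g, function(gg) {
        gg[, , seq_len(nm), drop = FALSE]
      }))
      add_grad(op$skip, lapply(g, function(gg) {
        gg[, , -seq_len(nm), drop = FALSE]
      }))
    } else if (op$type == "resize") {
      d <- fw$caches[[op$id]]$in_dim
      add_grad(op$input, lapply(g, function(gg) {
        .resize_bilinear_backward(gg, d[1], d[2])
      }))
    }
  }
  list(pgrads = pgrads, gx_input = gx_input)
}

# forward through base (+ head if present); eval mode unless training
model_forward_full <- function(model, xs, training = FALSE,
                               train_head_only = FALSE) {
  base_training <- training && !train_head_only
  fw <- net_forward(model$ops, xs, model$cfg$lrelu_slope, model$cfg$bn_eps,
                    training = base_training)
  base_out <- fw$acts[[length(model$ops)]]
  if (is.null(model$head)) {
    return(list(y = base_out, fw = fw, base_out = base_out))
  }
  hf <- net_forward(model$head$ops, base_out, model$cfg$lrelu_slope,
                    model$cfg$bn_eps, training = training)
  y <- Map(`+`, base_out, hf$acts[[length(model$head$ops)]])
  list(y = y, fw = fw, head_fw = hf, base_out = base_out)
}

#' Predict a SoS map from a conditioned RF frame
#'
#' @param model a trained `sosnet`.
#' @param rf a conditioned 128 x 1024 [rf_frame()] or matrix (per-channel
#'   mean 0, sd 1). A warning is issued when channels look unconditioned.
#' @return A [sos_map()] (384 x 384, m/s, role `"estimate"`).
#' @export
predict_sos <- function(model, rf) {
  x <- if (inherits(rf, "rf_frame")) rf$data else rf
  if (!all(dim(x) == model$cfg$input_shape)) {
    stop("expected a ", paste(model$cfg$input_shape, collapse = " x "),
         " frame")
  }
  ch_mean <- rowMeans(x)
  if (any(abs(ch_mean) > 0.1 & apply(x, 1, sd) > 0)) {
    warning("RF frame does not look conditioned (|channel mean| > 0.1); ",
            "run condition_rf() first")
  }
  xs <- list(array(x, dim = c(dim(x), 1L)))
  out <- model_forward_full(model, xs, training = FALSE)$y[[1]]
  sos_map(SOS_CENTER + SOS_SCALE * out[, , 1],
          pixel_size = 38.4 / model$cfg$output_shape[1], role = "estimate")
}

#' Attach a residual refinement head for transfer learning
#'
#' Augments a pre-trained model with a small residual block on top of its
#' output: `y = base(x) + head(base(x))`, where the head is a pair of 3 x 3
#' convolutions with a LeakyReLU between. The head's output convolution is
#' initialized near zero so the augmented model initially reproduces the base
#' to within 1e-3 m/s. During fine-tuning only head parameters are updated.
#'
#' @param model a `sosnet`.
#' @param width head channel width.
#' @param seed integer seed.
#' @return The augmented model.
#' @export
attach_residual_head <- function(model, width = 8L, seed = 1L) {
  with_seed(substream_seed(seed, "head-init"), {
    op1 <- new_conv_op(1L, 0L, 1L, width, 3L, 3L, 1L, 1L, act = TRUE,
                       bn = FALSE)
    op1$params <- conv_init(3L, 3L, 1L, width)
    op2 <- new_conv_op(2L, 1L, width, 1L, 3L, 3L, 1L, 1L, act = FALSE,
                       bn = FALSE)
    op2$params <- conv_init(3L, 3L, width, 1L)
    # near-zero output so the augmented model starts at the base prediction
    op2$params$W <- op2$params$W * 1e-5
    model$head <- list(ops = list(op1, op2), width = width)
    model
  })
}
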