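# Training loop (SGD on mean-square error) and frozen-base transfer learning.

#' Training configuration
#'
#' @param lr learning rate of stochastic gradient descent (reference value
#'   1e-4).
#' @param batch mini-batch size (reference value 10).
#' @param epochs number of epochs.
#' @param split training fraction of the train/validation split (0.9),
#'   applied per phantom so no frame leaks across the split.
#' @param momentum SGD momentum (0 = plain SGD; desk-scale runs use 0.9).
#' @param seed integer seed controlling the split and shuffling.
#' @param patience early-stopping patience in epochs on the validation RMSE
#'   (`NULL` disables early stopping; fine-tuning runs stop when the MSE has
#'   not decreased for this many epochs).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch = 10L, epochs = 20L, split = 0.9,
                         momentum = 0, seed = 1L, patience = NULL) {
  stopifnot(lr > 0 || epochs == 0, split > 0, split < 1, batch >= 1)
  list(lr = lr, batch = as.integer(batch), epochs = as.integer(epochs),
       split = split, momentum = momentum, seed = as.integer(seed),
       patience = patience)
}

dataset_to_lists <- function(dataset) {
  if (any(!is.finite(dataset$rf)) || any(!is.finite(dataset$labels))) {
    stop("non-finite values in the dataset")
  }
  n <- dim(dataset$rf)[1]
  xs <- lapply(seq_len(n), function(i) {
    array(dataset$rf[i, , ], dim = c(dim(dataset$rf)[2:3], 1L))
  })
  ts <- lapply(seq_len(n), function(i) {
    array((dataset$labels[i, , ] - SOS_CENTER) / SOS_SCALE,
          dim = c(dim(dataset$labels)[2:3], 1L))
  })
  list(xs = xs, ts = ts, n = n)
}

mse_internal <- function(ys, ts) {
  s <- 0
  for (i in seq_along(ys)) s <- s + mean((ys[[i]] - ts[[i]])^2)
  s / length(ys)
}

# evaluate RMSE in m/s over a set of samples (eval mode); with a cache of
# frozen-base outputs only the head is recomputed
eval_rmse <- function(model, xs, ts, batch = 8L, base_cache = NULL) {
  if (length(xs) == 0L) return(NA_real_)
  tot <- 0
  idx <- split(seq_along(xs), ceiling(seq_along(xs) / batch))
  for (ii in idx) {
    ys <- if (is.null(base_cache)) {
      model_forward_full(model, xs[ii], training = FALSE)$y
    } else {
      hf <- net_forward(model$head$ops, base_cache[ii],
                        model$cfg$lrelu_slope, model$cfg$bn_eps,
                        training = FALSE)
      Map(`+`, base_cache[ii], hf$acts[[length(model$head$ops)]])
    }
    for (k in seq_along(ii)) {
      tot <- tot + mean((ys[[k]] - ts[[ii[k]]])^2)
    }
  }
  SOS_SCALE * sqrt(tot / length(xs))
}

collect_trainable <- function(ops) {
  out <- list()
  for (op in ops) {
    if (op$type != "conv") next
    out[[length(out) + 1L]] <- list(id = op$id, what = "W")
    out[[length(out) + 1L]] <- list(id = op$id, what = "b")
    if (isTRUE(op$bn)) {
      out[[length(out) + 1L]] <- list(id = op$id, what = "gamma")
      out[[length(out) + 1L]] <- list(id = op$id, what = "beta")
    }
  }
  out
}

get_param <- function(ops, ref) {
  op <- ops[[ref$id]]
  switch(ref$what, W = op$params$W, b = op$params$b,
         gamma = op$bn_params$gamma, beta = op$bn_params$beta)
}

set_param <- function(ops, ref, value) {
  if (ref$what == "W") ops[[ref$id]]$params$W <- value
  else if (ref$what == "b") ops[[ref$id]]$params$b <- value
  else if (ref$what == "gamma") ops[[ref$id]]$bn_params$gamma <- value
  else ops[[ref$id]]$bn_params$beta <- value
  ops
}

grad_of <- function(pgrads, ref) {
  g <- pgrads[[ref$id]]
  switch(ref$what, W = g$dW, b = g$db, gamma = g$dgamma, beta = g$dbeta)
}

#' Train the SoS network
#'
#' Stochastic gradient descent on the mean-square error between predicted and
#' ground-truth standardized SoS maps. The per-phantom train/validation split
#' and shuffling derive from the config seed; per-epoch train and validation
#' RMSE are logged in m/s and the best-validation parameters are retained.
#'
#' @param model a `sosnet` from [build_sosnet()].
#' @param dataset an `rf_dataset` from [simulate_rf_dataset()] (>= 2 frames),
#'   or a list with `rf` and `labels` arrays.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch RMSE.
#' @return A list with `model` (best-validation parameters), `history`
#'   (data.frame of epoch, train_rmse, valid_rmse in m/s) and `best_epoch`.
#' @export
train_sosnet <- function(model, dataset, cfg = train_config(),
                         verbose = FALSE) {
  d <- dataset_to_lists(dataset)
  if (d$n < 2L) stop("need at least 2 samples to train")
  idx <- with_seed(substream_seed(cfg$seed, "split"), sample(d$n))
  n_tr <- max(1L, min(d$n - 1L, ceiling(cfg$split * d$n)))
  tr <- idx[seq_len(n_tr)]
  va <- idx[-seq_len(n_tr)]
  run_sgd(model, d, tr, va, cfg, head_only = FALSE, verbose = verbose)
}

run_sgd <- function(model, d, tr, va, cfg, head_only, verbose,
                    base_cache = NULL) {
  refs <- if (head_only) collect_trainable(model$head$ops)
          else collect_trainable(model$ops)
  vel <- lapply(refs, function(r) {
    p <- if (head_only) get_param(model$head$ops, r)
         else get_param(model$ops, r)
    p * 0
  })
  history <- data.frame(epoch = integer(), train_rmse = numeric(),
                        valid_rmse = numeric())
  best <- list(valid = Inf, model = model, epoch = 0L)
  no_improve <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(substream_seed(cfg$seed, paste0("shuffle", ep)),
                     sample(tr))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      ii <- batches[[bi]]
      xs <- d$xs[ii]; ts <- d$ts[ii]
      if (head_only && !is.null(base_cache)) {
        base_out <- base_cache[ii]
        head_fw <- net_forward(model$head$ops, base_out,
                               model$cfg$lrelu_slope, model$cfg$bn_eps,
                               training = TRUE)
        fwd <- list(y = Map(`+`, base_out,
                            head_fw$acts[[length(model$head$ops)]]),
                    head_fw = head_fw, base_out = base_out)
      } else {
        fwd <- model_forward_full(model, xs, training = TRUE,
                                  train_head_only = head_only)
      }
      loss <- mse_internal(fwd$y, ts)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep, ", batch ", bi,
             " (lr too high or degenerate inputs)")
      }
      ep_loss <- ep_loss + loss * length(ii)
      npx <- prod(dim(fwd$y[[1]]))
      gys <- Map(function(y, t) 2 * (y - t) / (npx * length(xs)), fwd$y, ts)
      if (head_only) {
        bw <- net_backward(model$head$ops, fwd$head_fw, fwd$base_out, gys,
                           model$cfg$lrelu_slope)
        ops <- model$head$ops
      } else {
        if (!is.null(model$head)) {
          hbw <- net_backward(model$head$ops, fwd$head_fw, fwd$base_out, gys,
                              model$cfg$lrelu_slope, want_input_grad = TRUE)
          gys <- Map(`+`, gys, hbw$gx_input)
        }
        bw <- net_backward(model$ops, fwd$fw, xs, gys, model$cfg$lrelu_slope)
        ops <- model$ops
      }
      for (k in seq_along(refs)) {
        g <- grad_of(bw$pgrads, refs[[k]])
        if (is.null(g)) next
        vel[[k]] <- cfg$momentum * vel[[k]] - cfg$lr * g
        ops <- set_param(ops, refs[[k]], get_param(ops, refs[[k]]) + vel[[k]])
      }
      if (head_only) model$head$ops <- ops else model$ops <- ops
      if (!head_only) {
        model$ops <- update_bn_running(model$ops, fwd$fw,
                                       model$cfg$bn_momentum)
      }
    }
    tr_rmse <- SOS_SCALE * sqrt(ep_loss / length(tr))
    va_rmse <- if (is.null(base_cache)) {
      eval_rmse(model, d$xs[va], d$ts[va])
    } else {
      eval_rmse(model, d$xs[va], d$ts[va], base_cache = base_cache[va])
    }
    history <- rbind(history, data.frame(epoch = ep, train_rmse = tr_rmse,
                                         valid_rmse = va_rmse))
    if (verbose) {
      cat(sprintf("epoch %3d: train %.2f m/s, valid %.2f m/s\n", ep,
                  tr_rmse, va_rmse))
    }
    score <- if (length(va)) va_rmse else tr_rmse
    if (is.finite(score) && score < best$valid) {
      best <- list(valid = score, model = model, epoch = ep)
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (!is.null(cfg$patience) && no_improve >= cfg$patience) break
    }
  }
  list(model = best$model, history = history, best_epoch = best$epoch)
}

update_bn_running <- function(ops, fw, momentum) {
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (op$type == "conv" && isTRUE(op$bn)) {
      bn <- fw$caches[[op$id]]$bn
      op$bn_params$rmean <- momentum * op$bn_params$rmean +
        (1 - momentum) * bn$mu
      op$bn_params$rvar <- momentum * op$bn_params$rvar +
        (1 - momentum) * bn$var
      ops[[i]] <- op
    }
  }
  ops
}

#' Fine-tune the residual head on a small domain-shifted dataset
#'
#' Updates only the residual-head parameters (the pre-trained base stays
#' frozen, including its BatchNorm statistics) by SGD on the MSE, with the
#' train/validation split of [train_config()]. Training stops at the epoch
#' cap (reference protocol: 20 epochs on 48 samples) or earlier when the
#' validation MSE plateaus (`cfg$patience`).
#'
#' @param model a `sosnet` with an attached residual head
#'   ([attach_residual_head()]).
#' @param dataset a small `rf_dataset`-like list.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch RMSE.
#' @return A list with `model`, `history`, `best_epoch`.
#' @export
fine_tune <- function(model, dataset, cfg = train_config(epochs = 20L),
                      verbose = FALSE) {
  if (is.null(model$head)) stop("attach_residual_head() first")
  d <- dataset_to_lists(dataset)
  if (d$n < 1L) stop("empty dataset")
  idx <- with_seed(substream_seed(cfg$seed, "ft-split"), sample(d$n))
  n_tr <- max(1L, min(d$n - 1L, ceiling(cfg$split * d$n)))
  if (d$n == 1L) n_tr <- 1L
  tr <- idx[seq_len(n_tr)]
  va <- if (d$n > 1L) idx[-seq_len(n_tr)] else integer()
  # the base is frozen: compute its outputs once and train the head on them
  base_cache <- vector("list", d$n)
  for (ii in split(seq_len(d$n), ceiling(seq_len(d$n) / cfg$batch))) {
    fw <- net_forward(model$ops, d$xs[ii], model$cfg$lrelu_slope,
                      model$cfg$bn_eps, training = FALSE)
    base_cache[ii] <- fw$acts[[length(model$ops)]]
  }
  run_sgd(model, d, tr, va, cfg, head_only = TRUE, verbose = verbose,
          base_cache = base_cache)
}
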