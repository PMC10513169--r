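#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + s) / (sum(pred) + sum(target) + s)` with
#' smoothing constant `s` in both numerator and denominator. The Dice loss
#' is the training criterion of choice under the extreme class imbalance of
#' balloon segmentation (the balloon covers well under 1% of the image);
#' the smoothing keeps the loss defined — and exactly zero — when both
#' prediction and target are empty, which matters because a tenth of the
#' training frames carry no balloon at all.
#'
#' @param pred Numeric matrix/vector of probabilities in `[0, 1]`.
#' @param target Binary matrix/vector of the same shape.
#' @param smooth Smoothing constant (default 1).
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(0, 4, 4); m[2, 2] <- 1
#' dice_loss(m, m)            # perfect overlap -> 0
#' dice_loss(0 * m, m)        # no overlap -> close to 1
dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target)) {
    abort("`pred` and `target` must have identical shape.")
  }
  if (any(pred < 0 | pred > 1)) {
    abort("`pred` values must lie in [0, 1].")
  }
  inter <- sum(pred * target)
  1 - (2 * inter + smooth) / (sum(pred) + sum(target) + smooth)
}

# batch mean dice loss and its gradient w.r.t. pred, with per-image sums
dice_loss_batch <- function(pred, target, group, smooth = 1) {
  inter <- rowsum(pred * target, group)
  sp <- rowsum(pred, group)
  st <- rowsum(target, group)
  denom <- sp + st + smooth
  loss_i <- 1 - (2 * inter + smooth) / denom
  # d/dp_i of -(2I+s)/(Sp+St+s): -(2 t (D) - (2I+s)) / D^2
  gi <- cbind((2 * inter + smooth) / denom^2)[group]
  ti <- (2 / denom)[group] * target
  grad <- (gi - ti) / nrow(loss_i)
  list(loss = mean(loss_i), grad = grad)
}

#' First epoch achieving the minimum validation loss
#'
#' @param val_loss_history Numeric vector of per-epoch validation losses.
#' @return The 1-based index of the global minimum; ties resolve to the
#'   earliest epoch.
#' @export
#' @examples
#' select_best_epoch(c(0.9, 0.4, 0.6))  # 2
select_best_epoch <- function(val_loss_history) {
  stopifnot(length(val_loss_history) >= 1)
  which.min(val_loss_history)
}

adam_init <- function(layers) {
  purrr::map(layers, function(l) {
    list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(grads)) {
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[nm]]$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[nm]]$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[nm]]$db
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[nm]]$db^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + eps)
    state[[nm]] <- st
  }
  list(layers = layers, state = state)
}

# normalize every frame once up front; batches are then row gathers
precompute_frames <- function(frames) {
  H <- nrow(frames[[1]]$image); W <- ncol(frames[[1]]$image)
  list(X = assemble_batch(purrr::map(frames, "image")),
       target = unlist(purrr::map(frames, ~ as.numeric(.x$gt_mask))),
       H = H, W = W, npix = H * W, n = length(frames))
}

batch_rows <- function(chunk, npix) {
  rep((chunk - 1L) * npix, each = npix) + rep.int(seq_len(npix),
                                                  length(chunk))
}

eval_loss <- function(layers, pre, batch_size, smooth) {
  losses <- numeric(0)
  idx <- seq_len(pre$n)
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    sel <- batch_rows(chunk, pre$npix)
    fwd <- unet_forward(layers, pre$X[sel, , drop = FALSE],
                        pre$H, pre$W, length(chunk))
    d <- dice_loss_batch(fwd$prob, pre$target[sel],
                         rep(seq_along(chunk), each = pre$npix), smooth)
    losses <- c(losses, rep(d$loss, length(chunk)))
  }
  mean(losses)
}

#' Train the balloon segmentation network
#'
#' Mini-batch training with the Dice loss and the ADAM optimizer. Per-epoch
#' mean training loss and validation loss are recorded; the returned model
#' carries the weights of the epoch with the lowest validation loss (the
#' global minimum; ties resolve to the earliest epoch), kept as a running
#' best so only one weight snapshot is ever stored.
#'
#' @param train_frames,val_frames Lists of [annotated_frame()] objects with
#'   identical image shapes (height and width multiples of 4).
#' @param config A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return A trained `catheter_model` with `best_epoch`,
#'   `train_loss_history` and `val_loss_history` filled in.
#' @export
train <- function(train_frames, val_frames, config = training_config(),
                  verbose = FALSE) {
  if (length(train_frames) == 0 || length(val_frames) == 0) {
    abort("Training and validation sets must be nonempty.")
  }
  H <- nrow(train_frames[[1]]$image); W <- ncol(train_frames[[1]]$image)
  if (H %% 4L != 0L || W %% 4L != 0L) {
    abort("Frame height and width must be multiples of 4 for training.")
  }
  model <- build_model(config)
  layers <- model$layers
  state <- adam_init(layers)
  n <- length(train_frames)
  pre_tr <- precompute_frames(train_frames)
  pre_val <- precompute_frames(val_frames)
  tr_hist <- val_hist <- numeric(config$n_epochs)
  best <- list(loss = Inf, layers = layers, epoch = NA_integer_)
  t_step <- 0L
  with_rng(derive_seed(config$rng_seed, 7L), {
    for (epoch in seq_len(config$n_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (chunk in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        sel <- batch_rows(chunk, pre_tr$npix)
        bt <- list(X = pre_tr$X[sel, , drop = FALSE],
                   target = pre_tr$target[sel],
                   group = rep(seq_along(chunk), each = pre_tr$npix),
                   H = pre_tr$H, W = pre_tr$W, B = length(chunk))
        fwd <- unet_forward(layers, bt$X, bt$H, bt$W, bt$B, keep = TRUE)
        d <- dice_loss_batch(fwd$prob, bt$target, bt$group,
                             config$dice_smooth)
        batch_losses <- c(batch_losses, d$loss)
        grads <- unet_backward(layers, fwd, d$grad)
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, config$learning_rate, t_step)
        layers <- upd$layers
        state <- upd$state
      }
      tr_hist[epoch] <- mean(batch_losses)
      val_hist[epoch] <- eval_loss(layers, pre_val, config$batch_size,
                                   config$dice_smooth)
      if (val_hist[epoch] < best$loss) {
        best <- list(loss = val_hist[epoch], layers = layers, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        tr_hist[epoch], val_hist[epoch]))
      }
    }
  })
  model$layers <- best$layers
  model$best_epoch <- best$epoch
  model$train_loss_history <- tr_hist
  model$val_loss_history <- val_hist
  model
}

#' Per-epoch loss curves of a trained model
#'
#' @param x A trained `catheter_model`.
#' @return A tibble with columns `epoch`, `train_loss`, `val_loss`.
#' @export
loss_history <- function(x) {
  stopifnot(inherits(x, "catheter_model"))
  tibble::tibble(epoch = seq_along(x$train_loss_history),
                 train_loss = x$train_loss_history,
                 val_loss = x$val_loss_history)
}
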