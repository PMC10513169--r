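#' Training configuration for the segmentation network
#'
#' Defaults follow the reference training recipe for the full-scale
#' semi-artificial dataset: Dice loss, ADAM, learning rate 1e-5, batch size
#' 64, 200 epochs, and a fixed prediction threshold of 0.5 on the sigmoid
#' output. The scaled-down demonstration recipe used throughout the package
#' examples and tests raises the learning rate to the common ADAM default
#' (1e-3) and shortens training; see the methods vignette.
#'
#' @param learning_rate ADAM learning rate (> 0).
#' @param batch_size Frames per optimization step.
#' @param n_epochs Number of training epochs (>= 1).
#' @param base_channels Channel width of the first encoder stage; deeper
#'   stages double it twice.
#' @param prediction_threshold Fixed at 0.5: a sigmoid activation greater
#'   than or equal to 0.5 is classed as balloon signal.
#' @param dice_smooth Smoothing constant of the Dice loss (see
#'   [dice_loss()]).
#' @param rng_seed Seed controlling weight initialization and data order.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-5, batch_size = 64L,
                            n_epochs = 200L, base_channels = 8L,
                            prediction_threshold = 0.5, dice_smooth = 1,
                            rng_seed = 1L) {
  stopifnot(learning_rate > 0, n_epochs >= 1, batch_size >= 1,
            base_channels >= 2)
  if (prediction_threshold != 0.5) {
    abort("`prediction_threshold` is fixed at 0.5.")
  }
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         n_epochs = as.integer(n_epochs),
         base_channels = as.integer(base_channels),
         prediction_threshold = prediction_threshold,
         dice_smooth = dice_smooth, rng_seed = as.integer(rng_seed)),
    class = "training_config"
  )
}

layer_spec <- function(C) {
  list(
    stem  = c(3L, C, 3L),
    enc2  = c(C, 2L * C, 3L),
    res2a = c(2L * C, 2L * C, 3L),
    res2b = c(2L * C, 2L * C, 3L),
    enc3  = c(2L * C, 4L * C, 3L),
    res3a = c(4L * C, 4L * C, 3L),
    res3b = c(4L * C, 4L * C, 3L),
    dec1  = c(6L * C, 2L * C, 3L),
    dec2  = c(3L * C, C, 1L),
    out   = c(C, 1L, 1L)
  )
}

#' Build an untrained segmentation model
#'
#' Constructs a compact residual encoder-decoder for binary segmentation:
#' a three-stage encoder whose two deeper stages carry identity-skip
#' residual blocks, nearest-neighbour upsampling decoder stages with
#' U-Net-style skip concatenations from the encoder (the full-resolution
#' stage fuses the upsampled features with the stem skip through a 1x1
#' projection), and a single-channel sigmoid output head at input
#' resolution. Weights are He-initialized from
#' the configuration seed. Input height and width must be padded to a
#' multiple of 4 (the encoder downsampling factor); [predict_mask()] pads
#' reflectively and crops back automatically.
#'
#' @param config A [training_config()].
#' @return An object of class `catheter_model` holding the weights and the
#'   configuration.
#' @export
build_model <- function(config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  specs <- layer_spec(config$base_channels)
  layers <- with_rng(derive_seed(config$rng_seed, 97L), {
    purrr::map(specs, function(s) {
      fan_in <- s[1] * s[3]^2
      list(W = matrix(rnorm(fan_in * s[2], sd = sqrt(2 / fan_in)),
                      fan_in, s[2]),
           b = rep(0, s[2]),
           Cin = s[1], Cout = s[2],
           type = if (s[3] == 1L) "conv1" else "conv3")
    })
  })
  structure(list(layers = layers, config = config, best_epoch = NA_integer_,
                 train_loss_history = numeric(0),
                 val_loss_history = numeric(0)),
            class = "catheter_model")
}

#' @export
print.catheter_model <- function(x, ...) {
  np <- sum(purrr::map_dbl(x$layers, ~ length(.x$W) + length(.x$b)))
  cat(sprintf("<catheter_model> %d parameters, base width %d",
              np, x$config$base_channels))
  if (!is.na(x$best_epoch)) {
    cat(sprintf(", trained (best epoch %d of %d)",
                x$best_epoch, length(x$val_loss_history)))
  }
  cat("\n")
  invisible(x)
}

# forward pass on a normalized batch X0 ((H*W*B) x 3); returns sigmoid
# probabilities and, if keep = TRUE, the intermediates needed for backward
unet_forward <- function(layers, X0, H, W, B, keep = FALSE) {
  g1 <- nn_geom(H, W, B)
  g2 <- nn_geom(H %/% 2L, W %/% 2L, B)
  g3 <- nn_geom(H %/% 4L, W %/% 4L, B)

  z_stem <- conv_fwd(X0, layers$stem, g1);  a_stem <- relu(z_stem)
  p1 <- maxpool_fwd(a_stem, g1)
  z_enc2 <- conv_fwd(p1, layers$enc2, g2);  a_enc2 <- relu(z_enc2)
  z_r2a <- conv_fwd(a_enc2, layers$res2a, g2); a_r2a <- relu(z_r2a)
  z_r2b <- conv_fwd(a_r2a, layers$res2b, g2)
  a_res2 <- relu(a_enc2 + z_r2b)
  p2 <- maxpool_fwd(a_res2, g2)
  z_enc3 <- conv_fwd(p2, layers$enc3, g3);  a_enc3 <- relu(z_enc3)
  z_r3a <- conv_fwd(a_enc3, layers$res3a, g3); a_r3a <- relu(z_r3a)
  z_r3b <- conv_fwd(a_r3a, layers$res3b, g3)
  a_res3 <- relu(a_enc3 + z_r3b)
  u1 <- upsample_fwd(a_res3, g2)
  z_dec1 <- conv_fwd(cbind(u1, a_res2), layers$dec1, g2)
  a_dec1 <- relu(z_dec1)
  u2 <- upsample_fwd(a_dec1, g1)
  z_dec2 <- conv_fwd(cbind(u2, a_stem), layers$dec2, g1)
  a_dec2 <- relu(z_dec2)
  z_out <- conv_fwd(a_dec2, layers$out, g1)
  prob <- sigmoid(as.vector(z_out))

  if (!keep) return(list(prob = prob))
  list(prob = prob, g1 = g1, g2 = g2, g3 = g3,
       z_stem = z_stem, p1 = p1, z_enc2 = z_enc2, a_enc2 = a_enc2,
       z_r2a = z_r2a, z_r2b = z_r2b, a_res2 = a_res2, p2 = p2,
       z_enc3 = z_enc3, a_enc3 = a_enc3, z_r3a = z_r3a, z_r3b = z_r3b,
       a_res3 = a_res3, z_dec1 = z_dec1, a_dec1 = a_dec1,
       z_dec2 = z_dec2, a_dec2 = a_dec2, z_out = z_out)
}

# backward pass: dprob is dLoss/dprob (vector); returns per-layer gradients
unet_backward <- function(layers, fwd, dprob) {
  g1 <- fwd$g1; g2 <- fwd$g2; g3 <- fwd$g3
  grads <- list()
  dz_out <- matrix(dprob * fwd$prob * (1 - fwd$prob), ncol = 1L)
  bo <- conv_bwd(dz_out, layers$out, g1, attr(fwd$z_out, "cache"))
  grads$out <- bo
  d_a_dec2 <- bo$dX * (fwd$z_dec2 > 0)
  b2 <- conv_bwd(d_a_dec2, layers$dec2, g1, attr(fwd$z_dec2, "cache"))
  grads$dec2 <- b2
  C <- layers$stem$Cout
  d_u2 <- b2$dX[, seq_len(2L * C), drop = FALSE]
  d_a_stem <- b2$dX[, 2L * C + seq_len(C), drop = FALSE]
  d_a_dec1 <- upsample_bwd(d_u2, g1) * (fwd$z_dec1 > 0)
  b1 <- conv_bwd(d_a_dec1, layers$dec1, g2, attr(fwd$z_dec1, "cache"))
  grads$dec1 <- b1
  d_u1 <- b1$dX[, seq_len(4L * C), drop = FALSE]
  d_a_res2 <- b1$dX[, 4L * C + seq_len(2L * C), drop = FALSE]
  d_a_res3 <- upsample_bwd(d_u1, g2)
  # residual block 3
  d_pre3 <- d_a_res3 * ((fwd$a_enc3 + fwd$z_r3b) > 0)
  br3b <- conv_bwd(d_pre3, layers$res3b, g3, attr(fwd$z_r3b, "cache"))
  grads$res3b <- br3b
  d_a_r3a <- br3b$dX * (fwd$z_r3a > 0)
  br3a <- conv_bwd(d_a_r3a, layers$res3a, g3, attr(fwd$z_r3a, "cache"))
  grads$res3a <- br3a
  d_a_enc3 <- (d_pre3 + br3a$dX) * (fwd$z_enc3 > 0)
  be3 <- conv_bwd(d_a_enc3, layers$enc3, g3, attr(fwd$z_enc3, "cache"))
  grads$enc3 <- be3
  d_a_res2 <- d_a_res2 +
    maxpool_bwd(be3$dX, g2, attr(fwd$p2, "amax"), nrow(fwd$a_res2))
  # residual block 2
  d_pre2 <- d_a_res2 * ((fwd$a_enc2 + fwd$z_r2b) > 0)
  br2b <- conv_bwd(d_pre2, layers$res2b, g2, attr(fwd$z_r2b, "cache"))
  grads$res2b <- br2b
  d_a_r2a <- br2b$dX * (fwd$z_r2a > 0)
  br2a <- conv_bwd(d_a_r2a, layers$res2a, g2, attr(fwd$z_r2a, "cache"))
  grads$res2a <- br2a
  d_a_enc2 <- (d_pre2 + br2a$dX) * (fwd$z_enc2 > 0)
  be2 <- conv_bwd(d_a_enc2, layers$enc2, g2, attr(fwd$z_enc2, "cache"))
  grads$enc2 <- be2
  d_a_stem <- d_a_stem +
    maxpool_bwd(be2$dX, g1, attr(fwd$p1, "amax"), nrow(fwd$z_stem))
  d_a_stem <- d_a_stem * (fwd$z_stem > 0)
  grads$stem <- conv_bwd(d_a_stem, layers$stem, g1,
                         attr(fwd$z_stem, "cache"))
  grads
}

# reflect-pad a 2D image so both dimensions are multiples of `m`
pad_to_multiple <- function(image, m = 4L) {
  H <- nrow(image); W <- ncol(image)
  ph <- (m - H %% m) %% m
  pw <- (m - W %% m) %% m
  if (ph > 0) image <- rbind(image, image[H - seq_len(ph) + 1L, , drop = FALSE])
  if (pw > 0) image <- cbind(image, image[, W - seq_len(pw) + 1L, drop = FALSE])
  list(image = image, H = H, W = W)
}

# stack a list of 2D grayscale images into a normalized network input batch
assemble_batch <- function(images) {
  mats <- purrr::map(images, function(im) {
    arr <- normalize_image(im)
    matrix(arr, nrow(im) * ncol(im), 3L)
  })
  do.call(rbind, mats)
}

#' Per-pixel balloon probabilities for one image
#'
#' Runs the network forward in evaluation mode. The image is normalized
#' ([normalize_image()]) and reflect-padded to a multiple of the encoder
#' downsampling factor, and the padding is cropped from the output.
#'
#' @param model A trained [build_model()] object.
#' @param image 2D numeric matrix.
#' @return A matrix of sigmoid activations in `(0, 1)`, same shape as
#'   `image`.
#' @export
predict_prob <- function(model, image) {
  stopifnot(inherits(model, "catheter_model"))
  assert_matrix2d(image)
  pd <- pad_to_multiple(image, 4L)
  X0 <- assemble_batch(list(pd$image))
  fwd <- unet_forward(model$layers, X0, nrow(pd$image), ncol(pd$image), 1L)
  prob <- matrix(fwd$prob, nrow(pd$image), ncol(pd$image))
  prob[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
}

#' Predicted binary balloon mask for one image
#'
#' Thresholds the sigmoid output at the fixed prediction threshold: an
#' activation greater than or equal to 0.5 is classed as balloon signal.
#'
#' @inheritParams predict_prob
#' @return An integer matrix (1 = balloon), same shape as `image`.
#' @export
predict_mask <- function(model, image) {
  threshold_prob(predict_prob(model, image),
                 model$config$prediction_threshold)
}

#' Threshold a probability grid into a binary mask
#'
#' @param prob Matrix of per-pixel probabilities.
#' @param threshold Inclusive threshold (default 0.5): values `>= threshold`
#'   are classed as balloon.
#' @return Integer matrix of 0/1.
#' @export
threshold_prob <- function(prob, threshold = 0.5) {
  matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
}
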