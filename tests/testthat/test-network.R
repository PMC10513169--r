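test_that("analytic gradients match finite differences through the whole network", {
  set.seed(1)
  cfg <- training_config(base_channels = 2, rng_seed = 3)
  m <- build_model(cfg)
  H <- 8L; W <- 8L; B <- 2L
  X0 <- matrix(rnorm(H * W * B * 3), H * W * B, 3)
  tgt <- as.numeric(runif(H * W * B) < 0.2)
  grp <- rep(1:B, each = H * W)
  loss_fn <- function(layers) {
    fwd <- cathtrack:::unet_forward(layers, X0, H, W, B)
    cathtrack:::dice_loss_batch(fwd$prob, tgt, grp)$loss
  }
  fwd <- cathtrack:::unet_forward(m$layers, X0, H, W, B, keep = TRUE)
  d <- cathtrack:::dice_loss_batch(fwd$prob, tgt, grp)
  gr <- cathtrack:::unet_backward(m$layers, fwd, d$grad)
  eps <- 1e-6
  for (nm in names(gr)) {
    nw <- length(m$layers[[nm]]$W)
    for (i in sample(nw, min(4, nw))) {
      lp <- m$layers; lp[[nm]]$W[i] <- lp[[nm]]$W[i] + eps
      lm <- m$layers; lm[[nm]]$W[i] <- lm[[nm]]$W[i] - eps
      num <- (loss_fn(lp) - loss_fn(lm)) / (2 * eps)
      expect_equal(gr[[nm]]$dW[i], num, tolerance = 1e-3,
                   info = paste("weight grad", nm))
    }
    lp <- m$layers; lp[[nm]]$b[1] <- lp[[nm]]$b[1] + eps
    lm <- m$layers; lm[[nm]]$b[1] <- lm[[nm]]$b[1] - eps
    num <- (loss_fn(lp) - loss_fn(lm)) / (2 * eps)
    expect_equal(gr[[nm]]$db[1], num, tolerance = 1e-3,
                 info = paste("bias grad", nm))
  }
})

test_that("the network output honours the segmentation contract", {
  m <- build_model(training_config(base_channels = 4, rng_seed = 2))
  img <- flat_background(32, 32)
  pr <- predict_prob(m, img)
  expect_identical(dim(pr), dim(img))
  expect_true(all(pr > 0 & pr < 1)) # sigmoid range
  # evaluation-mode determinism
  expect_identical(pr, predict_prob(m, img))
  expect_identical(predict_mask(m, img), predict_mask(m, img))
})

test_that("inputs not divisible by the downsampling factor are padded and cropped back", {
  m <- build_model(training_config(base_channels = 4, rng_seed = 2))
  img <- flat_background(33, 38)
  pr <- predict_prob(m, img)
  expect_identical(dim(pr), c(33L, 38L))
})

test_that("thresholding is inclusive at 0.5", {
  pr <- matrix(c(0.49999, 0.5, 0.50001, 0.2), 2, 2)
  mk <- threshold_prob(pr, 0.5)
  expect_identical(mk, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  # all-below gives an empty mask
  expect_identical(sum(threshold_prob(matrix(0.49, 4, 4))), 0L)
})

test_that("best-epoch selection takes the first global minimum", {
  expect_identical(select_best_epoch(c(0.9, 0.4, 0.6)), 2L)
  expect_identical(select_best_epoch(c(0.5, 0.3, 0.3)), 2L)
  expect_identical(select_best_epoch(c(0.7)), 1L)
  # equals a brute-force scan on random histories
  set.seed(9)
  for (i in 1:20) {
    h <- round(runif(sample(3:30, 1)), 3)
    brute <- min(which(h == min(h)))
    expect_identical(select_best_epoch(h), brute)
  }
})

test_that("a short training run reduces the loss and records histories", {
  frames <- tiny_frames(40, H = 32, W = 32, seed = 8)
  val <- tiny_frames(10, H = 32, W = 32, seed = 9)
  cfg <- training_config(learning_rate = 1e-3, batch_size = 20,
                         n_epochs = 4, base_channels = 4, rng_seed = 1)
  m <- train(frames, val, cfg)
  expect_length(m$train_loss_history, 4)
  expect_length(m$val_loss_history, 4)
  expect_lt(m$train_loss_history[4], m$train_loss_history[1])
  expect_identical(m$best_epoch, select_best_epoch(m$val_loss_history))
  expect_error(train(list(), val, cfg), "nonempty")
})
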