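# Batched tensor primitives for the segmentation network.
#
# Feature maps live in matrices of shape (H*W*B) x C: pixels of each image in
# column-major order, images stacked along rows, one column per channel. All
# convolutions are 3x3 (zero-padded, stride 1) or 1x1, expressed as GEMMs per
# kernel offset so the heavy lifting happens in BLAS; index tables per
# (H, W, B) are precomputed and cached.

nn_geom <- function(H, W, B) {
  key <- paste(H, W, B, sep = "x")
  hit <- .cathtrack_cache[[key]]
  if (!is.null(hit)) return(hit)
  npix <- H * W
  batch_off <- function(idx, stride) {
    rep(idx, B) + rep((seq_len(B) - 1L) * stride, each = length(idx))
  }
  g <- list(H = H, W = W, B = B, npix = npix)
  if (H %% 2L == 0L && W %% 2L == 0L) {
    h2 <- H %/% 2L; w2 <- W %/% 2L
    r2 <- rep(seq_len(h2), w2)
    c2 <- rep(seq_len(w2), each = h2)
    child <- vector("list", 4L)
    k <- 0L
    for (dc in 1:2) {
      for (dr in 1:2) {
        k <- k + 1L
        child[[k]] <- batch_off((2L * c2 - 3L + dc) * H + 2L * r2 - 2L + dr,
                                npix)
      }
    }
    g$pool_child <- child
  }
  .cathtrack_cache[[key]] <- g
  g
}

conv_fwd <- function(X, layer, g) {
  if (layer$type == "conv1") {
    Y <- X %*% layer$W
    for (co in seq_along(layer$b)) {
      if (layer$b[co] != 0) Y[, co] <- Y[, co] + layer$b[co]
    }
    attr(Y, "cache") <- X
    return(Y)
  }
  res <- .conv3_fwd(X, layer$W, layer$b, g$H, g$W, g$B)
  Y <- res$Y
  attr(Y, "cache") <- res$Xpad
  Y
}

conv_bwd <- function(dY, layer, g, cache) {
  if (layer$type == "conv1") {
    return(list(dX = tcrossprod(dY, layer$W),
                dW = crossprod(cache, dY),
                db = colSums(dY)))
  }
  .conv3_bwd(dY, layer$W, cache, g$H, g$W, g$B)
}

maxpool_fwd <- function(X, g) {
  ci <- g$pool_child
  Y <- X[ci[[1]], , drop = FALSE]
  amax <- matrix(1L, nrow(Y), ncol(Y))
  for (k in 2:4) {
    Mk <- X[ci[[k]], , drop = FALSE]
    upd <- Mk > Y
    Y[upd] <- Mk[upd]
    amax[upd] <- k
  }
  attr(Y, "amax") <- amax
  Y
}

maxpool_bwd <- function(dY, g, amax, n_in) {
  ci <- g$pool_child
  C <- ncol(dY)
  n_out <- nrow(dY)
  dX <- matrix(0, n_in, C)
  for (k in 1:4) {
    pos <- which(amax == k)
    if (length(pos)) {
      i <- (pos - 1L) %% n_out + 1L
      ch <- (pos - 1L) %/% n_out
      tgt <- ch * n_in + ci[[k]][i]
      dX[tgt] <- dX[tgt] + dY[pos]
    }
  }
  dX
}

# nearest-neighbour 2x upsampling: children of each coarse pixel (the pool
# child table of the fine grid) receive its value; backward sums them
upsample_fwd <- function(X, g_fine) {
  ci <- g_fine$pool_child
  C <- ncol(X)
  Y <- matrix(0, g_fine$npix * g_fine$B, C)
  for (k in 1:4) Y[ci[[k]], ] <- X
  Y
}

upsample_bwd <- function(dY, g_fine) {
  ci <- g_fine$pool_child
  dY[ci[[1]], , drop = FALSE] + dY[ci[[2]], , drop = FALSE] +
    dY[ci[[3]], , drop = FALSE] + dY[ci[[4]], , drop = FALSE]
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))
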