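# separable Gaussian blur used to give the phantom a smooth, MR-like texture
blur2d <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
  conv_cols <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), ]
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

# soft-edged ellipse indicator centred at (cr, cc), semi-axes (ar, ac),
# rotated by th radians
soft_ellipse <- function(shape, cr, cc, ar, ac, th = 0, edge = 1.5) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rows - cr; dc <- cols - cc
  u <- cos(th) * dc + sin(th) * dr
  v <- -sin(th) * dc + cos(th) * dr
  d <- sqrt((u / ac)^2 + (v / ar)^2)
  1 / (1 + exp((d - 1) * (max(ar, ac) / edge)))
}

#' Generate a procedural cardiac-like phantom background
#'
#' Produces a synthetic grayscale background that emulates the salient
#' features of a real-time cardiac MR magnitude image for training-data
#' simulation: a low-intensity noisy background, mid-intensity blood-pool
#' structures (elliptical chambers plus a curved tubular vessel), and a
#' hyper-intense subcutaneous fat-like band near the image border. The fat
#' band provides the bright confounder against which false-positive
#' robustness of the segmentation network is exercised. It does not model
#' MR physics (banding, coil profiles, undersampling artifacts).
#'
#' @param shape Integer `c(rows, cols)`, each at least 64.
#' @param rng_seed Integer seed; the output is bit-reproducible for a fixed
#'   seed.
#' @return A non-negative `rows x cols` intensity matrix, with an attribute
#'   `"placement_mask"`: a logical matrix marking blood-pool pixels suitable
#'   for catheter placement (used by [build_dataset()]).
#' @export
#' @examples
#' ph <- generate_phantom(c(64, 64), rng_seed = 1)
#' range(ph)
generate_phantom <- function(shape, rng_seed = 1L) {
  stopifnot(length(shape) == 2)
  if (any(shape < 64)) {
    abort("Phantom shape must be at least 64x64 pixels.")
  }
  H <- shape[1]; W <- shape[2]
  with_rng(rng_seed, {
    # smooth low-intensity tissue background
    img <- 0.08 + 0.06 * pmax(0, blur2d(matrix(rnorm(H * W), H, W), 4)) * 4
    chambers <- matrix(0, H, W)

    # 2-3 elliptical cardiac-chamber-like blood pools
    n_ch <- sample(2:3, 1)
    for (i in seq_len(n_ch)) {
      cr <- runif(1, 0.30 * H, 0.70 * H)
      cc <- runif(1, 0.30 * W, 0.70 * W)
      ar <- runif(1, 0.10 * H, 0.18 * H)
      ac <- runif(1, 0.10 * W, 0.18 * W)
      chambers <- pmax(chambers, soft_ellipse(c(H, W), cr, cc, ar, ac,
                                              th = runif(1, 0, pi)))
    }

    # one curved tubular vessel crossing the field of view; the tube is a
    # soft indicator of the distance to a sampled center-line
    t_par <- seq(0, 1, length.out = 96)
    vr <- (0.15 + 0.7 * t_par) * H
    vc <- (0.5 + 0.3 * sin(2 * pi * t_par * runif(1, 0.5, 1.2) +
                             runif(1, 0, 2 * pi))) * W
    wpx <- runif(1, 2.5, 4)
    pixr <- rep(seq_len(H), W)
    pixc <- rep(seq_len(W), each = H)
    d2 <- outer(pixr, vr, "-")^2 + outer(pixc, vc, "-")^2
    dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
    tube <- matrix(1 / (1 + exp((dmin - wpx) / 0.8)), H, W)
    chambers <- pmax(chambers, tube)
    img <- img + runif(1, 0.28, 0.42) * chambers

    # hyper-intense fat-like band hugging one border
    side <- sample(1:4, 1)
    off <- runif(1, 3, 7)
    width <- runif(1, 2, 4)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    d_border <- switch(side,
      rows - 1, H - rows, cols - 1, W - cols)
    wob <- 1.5 * sin(2 * pi * (if (side <= 2) cols / W else rows / H) *
                       runif(1, 1, 2))
    band <- exp(-((d_border - off - wob)^2) / (2 * width^2))
    img <- img + runif(1, 0.75, 0.95) * band

    # mild acquisition-like pixel noise; keep intensities non-negative
    img <- pmax(img + 0.01 * matrix(rnorm(H * W), H, W), 0)

    attr(img, "placement_mask") <- chambers > 0.6
    img
  })
}

# sample catheter placements inside blood-pool structures, with a safety
# margin from the border so the full balloon support stays in-frame
sample_placements <- function(phantom, n, margin = 8) {
  mask <- attr(phantom, "placement_mask")
  if (is.null(mask)) mask <- phantom > stats::quantile(phantom, 0.75)
  H <- nrow(phantom); W <- ncol(phantom)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  ok <- mask & rows > margin & rows <= H - margin &
    cols > margin & cols <= W - margin & phantom > 0
  idx <- which(ok)
  if (length(idx) == 0) abort("No valid catheter placement pixels in phantom.")
  picks <- idx[sample.int(length(idx), n, replace = n > length(idx))]
  cbind(row = (picks - 1L) %% H + 1L, col = (picks - 1L) %/% H + 1L)
}
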