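# shared fixtures: small images, masks and oracles built in code

# brute-force mask oracle: per-pixel rotated-covariance Mahalanobis scan,
# written independently of make_gt_mask (explicit rotation matrix algebra)
brute_force_mask <- function(sigma_x, sigma_y, theta_deg, center, shape,
                             radius_sd = 1.5) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  S <- R %*% diag(c(sigma_x^2, sigma_y^2)) %*% t(R)
  Sinv <- solve(S)
  out <- matrix(0L, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (cl in seq_len(shape[2])) {
      v <- c(cl - center[2], r - center[1]) # (x, y) = (col, row) offsets
      if (drop(t(v) %*% Sinv %*% v) <= radius_sd^2) out[r, cl] <- 1L
    }
  }
  out
}

# a flat background with a little texture, valid for catheter placement
flat_background <- function(H = 32, W = 32, level = 0.4, seed = 42) {
  set.seed(seed)
  matrix(level + 0.01 * rnorm(H * W), H, W)
}

# quick annotated frames on small flat backgrounds (multiple of 4 sized)
tiny_frames <- function(n, H = 32, W = 32, seed = 1, p_negative = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    bg <- matrix(0.3 + 0.02 * rnorm(H * W), H, W)
    if (runif(1) < p_negative) {
      annotated_frame(bg, subject_id = "tiny")
    } else {
      p <- sample_catheter_params(c(sample(8:(H - 8), 1),
                                    sample(8:(W - 8), 1)))
      f <- simulate_catheter(bg, p)
      f$subject_id <- "tiny"
      f
    }
  })
}

# region tibble stub with given centroids (for classification tests)
region_stub <- function(centroids) {
  if (length(centroids) == 0) {
    return(tibble::tibble(centroid_row = numeric(0),
                          centroid_col = numeric(0)))
  }
  m <- do.call(rbind, centroids)
  tibble::tibble(centroid_row = m[, 1], centroid_col = m[, 2])
}
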