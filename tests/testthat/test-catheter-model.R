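test_that("gaussian profile matches the closed form and a brute-force rotated covariance", {
  # isotropic: exp(-d^2/2) with d = r/sigma, independent of theta
  for (th in c(0L, 77L, 191L)) {
    p <- catheter_params(64, 64, sigma_x = 1.5, sigma_y = 1.5, theta_deg = th)
    expect_equal(gaussian_profile(p, 64, 64), 1.0)
    expect_equal(gaussian_profile(p, 64 + 2.25, 64), exp(-1.125),
                 tolerance = 1e-12)
    expect_equal(gaussian_profile(p, 64, 64 - 2.25), exp(-1.125),
                 tolerance = 1e-12)
  }
  # anisotropic, rotated: compare against explicit covariance algebra
  set.seed(11)
  for (i in 1:20) {
    sx <- sample(c(1.5, 2.5), 1); sy <- sample(c(1.5, 2.5), 1)
    th <- sample(0:359, 1)
    p <- catheter_params(20, 30, sigma_x = sx, sigma_y = sy, theta_deg = th)
    r <- runif(1, 10, 30); cl <- runif(1, 20, 40)
    rot <- th * pi / 180
    R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2,
                byrow = TRUE)
    Sinv <- solve(R %*% diag(c(sx^2, sy^2)) %*% t(R))
    v <- c(cl - 30, r - 20)
    expect_equal(gaussian_profile(p, r, cl),
                 exp(-drop(t(v) %*% Sinv %*% v) / 2), tolerance = 1e-10)
  }
})

test_that("90-degree rotation swaps the roles of the two axes", {
  p0 <- catheter_params(50, 50, sigma_x = 2.5, sigma_y = 1.5, theta_deg = 0L)
  p90 <- catheter_params(50, 50, sigma_x = 2.5, sigma_y = 1.5,
                         theta_deg = 90L)
  for (k in c(0.5, 1, 2, 3.7)) {
    expect_equal(gaussian_profile(p90, 50, 50 + k),
                 gaussian_profile(p0, 50 + k, 50), tolerance = 1e-12)
  }
})

test_that("ground-truth mask equals the brute-force Mahalanobis oracle on the full parameter grid", {
  shape <- c(40, 40)
  for (sx in c(1.5, 2.5)) {
    for (sy in c(1.5, 2.5)) {
      for (th in seq(0L, 330L, by = 30L)) {
        p <- catheter_params(20, 21, sigma_x = sx, sigma_y = sy,
                             theta_deg = th)
        expect_identical(make_gt_mask(p, shape),
                         brute_force_mask(sx, sy, th, c(20, 21), shape),
                         info = sprintf("sx=%g sy=%g th=%d", sx, sy, th))
      }
    }
  }
})

test_that("mask pixel counts behave as the ellipse geometry dictates", {
  iso <- catheter_params(64, 64, sigma_x = 1.5, sigma_y = 1.5)
  expect_identical(sum(make_gt_mask(iso, c(128, 128))), 21L)
  # isotropic case is rotation invariant
  rot <- catheter_params(64, 64, sigma_x = 1.5, sigma_y = 1.5,
                         theta_deg = 137L)
  expect_identical(make_gt_mask(iso, c(128, 128)),
                   make_gt_mask(rot, c(128, 128)))
  # strictly larger sigma gives strictly more pixels
  big <- catheter_params(64, 64, sigma_x = 2.5, sigma_y = 2.5)
  expect_gt(sum(make_gt_mask(big, c(128, 128))),
            sum(make_gt_mask(iso, c(128, 128))))
  # mask contains the center pixel
  expect_identical(make_gt_mask(iso, c(128, 128))[64, 64], 1L)
})

test_that("catheter insertion is additive with peak scaled to the center-pixel intensity", {
  bg <- flat_background(32, 32, level = 0.4)
  bg[16, 16] <- 0.4
  p <- catheter_params(16, 16, amplitude_pct = 200)
  f <- simulate_catheter(bg, p)
  expect_s3_class(f, "annotated_frame")
  expect_true(f$has_catheter)
  expect_equal(f$image[16, 16], 0.4 + 2 * 0.4, tolerance = 1e-12)
  # the added signal is exactly A * G, recovered to machine precision
  added <- f$image - bg
  expect_equal(added, 0.8 * gaussian_field(p, c(32, 32)), tolerance = 1e-14)
  expect_true(all(added >= 0))
  # amplitude 400% doubles every added pixel relative to 200%
  p4 <- catheter_params(16, 16, amplitude_pct = 400)
  f4 <- simulate_catheter(bg, p4)
  expect_equal(f4$image - bg, 2 * added, tolerance = 1e-12)
})

test_that("placement on a zero-intensity center is rejected", {
  bg <- flat_background(32, 32)
  bg[16, 16] <- 0
  expect_error(simulate_catheter(bg, catheter_params(16, 16)),
               class = "cathtrack_invalid_placement")
  expect_error(simulate_catheter(bg, catheter_params(1, 16)), "inside")
})

test_that("parameter sampling covers its support with the right frequencies", {
  set.seed(123)
  draws <- replicate(10000, sample_catheter_params(c(10, 10)),
                     simplify = FALSE)
  sx <- purrr::map_dbl(draws, "sigma_x")
  # binomial 3-sigma bound at n = 10000 is ~0.015
  expect_lt(abs(mean(sx == 1.5) - 0.5), 0.02)
  expect_setequal(unique(purrr::map_dbl(draws, "amplitude_pct")),
                  c(200, 300, 400))
  th <- purrr::map_int(draws, "theta_deg")
  expect_true(all(th >= 0L & th <= 359L))
  # fixed seed reproduces the identical parameter sequence
  set.seed(77)
  a <- replicate(20, sample_catheter_params(c(5, 5)), simplify = FALSE)
  set.seed(77)
  b <- replicate(20, sample_catheter_params(c(5, 5)), simplify = FALSE)
  expect_identical(a, b)
})

test_that("parameter validation rejects out-of-grid values", {
  expect_error(catheter_params(5, 5, sigma_x = 2.0), "1.5")
  expect_error(catheter_params(5, 5, theta_deg = 360), "359")
  expect_error(catheter_params(5, 5, amplitude_pct = 250), "200")
})
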