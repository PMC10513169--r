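#' Parameters of the artificial catheter-balloon signal
#'
#' The balloon of a gadolinium-filled wedge catheter appears on T1-weighted
#' MR magnitude images as a compact hyper-intense blob. The package emulates
#' it as a 2D anisotropic Gaussian: per-axis standard deviations drawn from
#' \{1.5, 2.5\} px, an integer rotation in 0-359 degrees, and a peak amplitude
#' of 200-400% (step 100%) of the underlying image intensity at the chosen
#' center pixel. The ground-truth mask is the set of pixels within 1.5
#' standard deviations of the profile (a rotated ellipse with semi-axes
#' `1.5 * sigma_x`, `1.5 * sigma_y`).
#'
#' @param center_row,center_col Center pixel (1-based row/column indices).
#' @param sigma_x,sigma_y Standard deviations in pixels, each one of
#'   `c(1.5, 2.5)`. `sigma_x` runs along columns at `theta_deg = 0`.
#' @param theta_deg Integer rotation in degrees, in `[0, 359]`,
#'   counter-clockwise about the center in (row, col) image space.
#' @param amplitude_pct Peak amplitude as a percentage of the underlying
#'   center-pixel intensity; one of `c(200, 300, 400)`.
#' @param mask_radius_sd Mask radius in standard deviations (fixed at 1.5).
#'
#' @return An object of class `catheter_params`.
#' @seealso [gaussian_profile()], [make_gt_mask()], [simulate_catheter()]
#' @export
#' @examples
#' catheter_params(32, 32, sigma_x = 1.5, sigma_y = 2.5, theta_deg = 45,
#'                 amplitude_pct = 300)
catheter_params <- function(center_row, center_col,
                            sigma_x = 1.5, sigma_y = 1.5,
                            theta_deg = 0L, amplitude_pct = 200,
                            mask_radius_sd = 1.5) {
  stopifnot(length(center_row) == 1, length(center_col) == 1)
  if (!sigma_x %in% c(1.5, 2.5) || !sigma_y %in% c(1.5, 2.5)) {
    abort("`sigma_x` and `sigma_y` must each be one of {1.5, 2.5} px.")
  }
  theta_deg <- as.integer(theta_deg)
  if (is.na(theta_deg) || theta_deg < 0L || theta_deg > 359L) {
    abort("`theta_deg` must be an integer in [0, 359].")
  }
  if (!amplitude_pct %in% c(200, 300, 400)) {
    abort("`amplitude_pct` must be one of {200, 300, 400}.")
  }
  structure(
    list(center_row = as.numeric(center_row),
         center_col = as.numeric(center_col),
         sigma_x = sigma_x, sigma_y = sigma_y,
         theta_deg = theta_deg, amplitude_pct = amplitude_pct,
         mask_radius_sd = mask_radius_sd),
    class = "catheter_params"
  )
}

#' @export
print.catheter_params <- function(x, ...) {
  cat(sprintf(
    "<catheter_params> center=(%g,%g) sigma=(%g,%g) px theta=%d deg amp=%d%%\n",
    x$center_row, x$center_col, x$sigma_x, x$sigma_y,
    x$theta_deg, x$amplitude_pct))
  invisible(x)
}

# squared Mahalanobis distance of pixel offsets from the Gaussian center
# under the rotated diagonal covariance diag(sigma_x^2, sigma_y^2)
mahalanobis_sq <- function(params, drow, dcol) {
  th <- params$theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # x along columns, y along rows; rotate offsets back into axis frame
  u1 <- ct * dcol + st * drow
  u2 <- -st * dcol + ct * drow
  (u1 / params$sigma_x)^2 + (u2 / params$sigma_y)^2
}

#' Unit-peak anisotropic Gaussian profile of the balloon signal
#'
#' Evaluates `exp(-d^2 / 2)` at the given pixels, where `d` is the
#' Mahalanobis distance of the pixel from the Gaussian center under the
#' rotated diagonal covariance `diag(sigma_x^2, sigma_y^2)`. The value is 1
#' at the center and strictly decreasing in `d`.
#'
#' @param params A [catheter_params()] object.
#' @param row,col Pixel coordinates (vectors of equal length, recycled).
#' @return Profile values in `[0, 1]`, same length as the inputs.
#' @export
#' @examples
#' p <- catheter_params(10, 10)
#' gaussian_profile(p, 10, 10)  # 1 at the center
gaussian_profile <- function(params, row, col) {
  stopifnot(inherits(params, "catheter_params"))
  d2 <- mahalanobis_sq(params, row - params$center_row,
                       col - params$center_col)
  exp(-d2 / 2)
}

#' Full-field Gaussian profile
#'
#' Evaluates [gaussian_profile()] over every pixel of an image grid.
#'
#' @param params A [catheter_params()] object.
#' @param shape Integer vector `c(rows, cols)`.
#' @return A `rows x cols` matrix of profile values in `[0, 1]`.
#' @export
gaussian_field <- function(params, shape) {
  stopifnot(length(shape) == 2)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  matrix(gaussian_profile(params, as.vector(rows), as.vector(cols)),
         shape[1], shape[2])
}

#' Ground-truth balloon mask
#'
#' Marks every pixel within `mask_radius_sd` (1.5) standard deviations of
#' the Gaussian profile, i.e. the rotated ellipse with semi-axes
#' `1.5 * sigma_x` and `1.5 * sigma_y` around the center.
#'
#' @inheritParams gaussian_field
#' @return An integer `rows x cols` matrix with 1 = balloon, 0 = background.
#' @export
#' @examples
#' p <- catheter_params(64, 64)
#' sum(make_gt_mask(p, c(128, 128)))  # 21 pixels for isotropic sigma = 1.5
make_gt_mask <- function(params, shape) {
  stopifnot(inherits(params, "catheter_params"), length(shape) == 2)
  if (params$center_row < 1 || params$center_row > shape[1] ||
      params$center_col < 1 || params$center_col > shape[2]) {
    abort("Gaussian center must lie inside the image bounds.")
  }
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d2 <- mahalanobis_sq(params, as.vector(rows) - params$center_row,
                       as.vector(cols) - params$center_col)
  matrix(as.integer(d2 <= params$mask_radius_sd^2), shape[1], shape[2])
}

#' Insert an artificial balloon signal into an image
#'
#' Adds a scaled Gaussian profile to the image: the peak increment is
#' `amplitude_pct / 100` times the image intensity at the center pixel, so
#' the balloon always stands out relative to its local background. The
#' background texture under the balloon is preserved (additive composition).
#'
#' @param image A 2D numeric matrix with non-negative intensities.
#' @param params A [catheter_params()] object; the center must lie strictly
#'   inside the image and the center-pixel intensity must be positive.
#' @return An `annotated_frame`: a list with elements `image` (the composite
#'   image), `gt_mask` (from [make_gt_mask()]), `has_catheter = TRUE`, and
#'   the `params` used.
#' @export
simulate_catheter <- function(image, params) {
  assert_matrix2d(image)
  stopifnot(inherits(params, "catheter_params"))
  shape <- dim(image)
  cr <- params$center_row; cc <- params$center_col
  if (cr <= 1 || cr >= shape[1] || cc <= 1 || cc >= shape[2]) {
    abort("Catheter center must lie strictly inside the image.")
  }
  base <- image[round_px(cr), round_px(cc)]
  if (!is.finite(base) || base <= 0) {
    abort("Cannot place catheter: center-pixel intensity is zero.",
          class = "cathtrack_invalid_placement")
  }
  amp <- params$amplitude_pct / 100 * base
  out <- image + amp * gaussian_field(params, shape)
  annotated_frame(image = out, gt_mask = make_gt_mask(params, shape),
                  params = params)
}

#' Construct an annotated frame
#'
#' One 2D grayscale image together with its binary ground-truth balloon
#' mask and bookkeeping labels.
#'
#' @param image 2D numeric matrix.
#' @param gt_mask Binary matrix of identical shape.
#' @param subject_id Opaque subject label.
#' @param slice_index,dynamic_index Integer indices.
#' @param params Optional [catheter_params()] used to create the frame.
#' @return An object of class `annotated_frame`.
#' @export
annotated_frame <- function(image, gt_mask = NULL, subject_id = NA_character_,
                            slice_index = NA_integer_,
                            dynamic_index = NA_integer_, params = NULL) {
  assert_matrix2d(image)
  # keep frames free of generator-side attributes (placement masks etc.)
  attributes(image) <- list(dim = dim(image))
  if (is.null(gt_mask)) gt_mask <- matrix(0L, nrow(image), ncol(image))
  assert_same_shape(image, gt_mask, "image and gt_mask")
  structure(
    list(image = image, gt_mask = gt_mask,
         has_catheter = any(gt_mask > 0),
         subject_id = subject_id,
         slice_index = as.integer(slice_index),
         dynamic_index = as.integer(dynamic_index),
         params = params),
    class = "annotated_frame"
  )
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame> %dx%d subject=%s catheter=%s\n",
              nrow(x$image), ncol(x$image), x$subject_id,
              if (x$has_catheter) "yes" else "no"))
  invisible(x)
}

#' Draw random catheter parameters for a placement
#'
#' Samples the balloon-shape parameters the way the training simulator
#' varies them: `sigma_x` and `sigma_y` independently and uniformly from
#' \{1.5, 2.5\} px, an integer rotation uniform on 0-359 degrees, and an
#' amplitude uniform on \{200, 300, 400\}%.
#'
#' @param placement Numeric `c(row, col)` center pixel.
#' @return A [catheter_params()] object. Uses the current RNG stream, so
#'   wrap in `set.seed()` for reproducibility.
#' @export
sample_catheter_params <- function(placement) {
  stopifnot(length(placement) == 2)
  catheter_params(
    center_row = placement[1], center_col = placement[2],
    sigma_x = sample(c(1.5, 2.5), 1),
    sigma_y = sample(c(1.5, 2.5), 1),
    theta_deg = sample(0:359, 1),
    amplitude_pct = sample(c(200, 300, 400), 1)
  )
}
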