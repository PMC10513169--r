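#' Channel statistics used for input standardization
#'
#' The widely published per-channel means and standard deviations of the
#' ImageNet dataset, used to standardize network inputs after the grayscale
#' image has been rescaled to `[0, 1]` and replicated to three channels.
#' Stored as named constants so they can be overridden.
#'
#' @return A list with numeric vectors `mean` and `sd` of length 3.
#' @export
imagenet_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Normalize a grayscale image for the segmentation network
#'
#' Three steps: (1) affine rescale of the image to `[0, 1]` using its own
#' min and max; (2) replication of the single grayscale channel to three
#' channels (the encoder consumes 3-channel inputs); (3) per-channel
#' standardization by the ImageNet channel means and standard deviations.
#' A constant image (max equal to min) maps to all-zeros in step 1, with a
#' warning.
#'
#' @param image 2D numeric matrix.
#' @param stats A list with `mean` and `sd` vectors of length 3; defaults
#'   to [imagenet_stats()].
#' @return A `rows x cols x 3` numeric array.
#' @export
#' @examples
#' x <- matrix(c(10, 12, 15, 20), 2, 2)
#' normalize_image(x)[ , , 1]
normalize_image <- function(image, stats = imagenet_stats()) {
  assert_matrix2d(image)
  rng <- range(image)
  if (rng[2] > rng[1]) {
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
  } else {
    warn("Constant image: range normalization yields all zeros.")
    scaled <- matrix(0, nrow(image), ncol(image))
  }
  out <- array(0, c(dim(image), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (scaled - stats$mean[ch]) / stats$sd[ch]
  }
  out
}
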