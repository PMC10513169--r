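# label connected components of a binary mask (8-connectivity) by BFS over
# foreground pixels; masks are small so this is plenty fast
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask > 0)
  if (length(fg) == 0) return(lab)
  if (connectivity == 8L) {
    dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      r0 <- (q - 1L) %% H + 1L
      c0 <- (q - 1L) %/% H + 1L
      for (k in seq_along(dr)) {
        r <- r0 + dr[k]; cl <- c0 + dc[k]
        if (r >= 1L && r <= H && cl >= 1L && cl <= W) {
          q2 <- (cl - 1L) * H + r
          if (mask[q2] > 0 && lab[q2] == 0L) {
            lab[q2] <- cur
            queue <- c(queue, q2)
          }
        }
      }
    }
  }
  lab
}

#' Connected regions of a predicted mask
#'
#' Splits a binary mask into connected components (8-connectivity by
#' default: balloon blobs are compact, and diagonal splits are
#' thresholding artifacts) and scores each region by the underlying image
#' intensity over its pixels.
#'
#' @param mask Binary matrix.
#' @param image Underlying grayscale image of identical shape.
#' @param slice_index Integer slice label attached to every region.
#' @param connectivity 4 or 8 (default 8).
#' @param scoring `"mean"` (default; mean image intensity over the region,
#'   robust to region size) or `"peak"` (maximum intensity).
#' @return A tibble with one row per region: `slice_index`, `n_pixels`,
#'   `centroid_row`, `centroid_col` (unweighted means of pixel
#'   coordinates), `intensity_score`, and a `pixels` list-column of
#'   `(row, col)` matrices. Empty mask gives zero rows.
#' @export
#' @examples
#' m <- matrix(0L, 8, 8); m[5, 5] <- m[5, 6] <- m[6, 5] <- 1L
#' extract_regions(m, matrix(1, 8, 8))
extract_regions <- function(mask, image, slice_index = 1L,
                            connectivity = 8L, scoring = c("mean", "peak")) {
  assert_same_shape(mask, image, "mask and image")
  scoring <- match.arg(scoring)
  lab <- label_components(mask, connectivity)
  n_reg <- max(lab)
  if (n_reg == 0L) {
    return(tibble::tibble(slice_index = integer(0), n_pixels = integer(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          intensity_score = numeric(0), pixels = list()))
  }
  H <- nrow(mask)
  purrr::map_dfr(seq_len(n_reg), function(i) {
    p <- which(lab == i)
    rows <- (p - 1L) %% H + 1L
    cols <- (p - 1L) %/% H + 1L
    vals <- image[p]
    tibble::tibble(
      slice_index = as.integer(slice_index),
      n_pixels = length(p),
      centroid_row = mean(rows),
      centroid_col = mean(cols),
      intensity_score = if (scoring == "mean") mean(vals) else max(vals),
      pixels = list(cbind(row = rows, col = cols))
    )
  })
}

#' Construct a dynamic triplet
#'
#' One time point (dynamic) of the tracking acquisition: three contiguous
#' slices, optionally with their predicted masks.
#'
#' @param slices List of exactly 3 matrices of identical shape.
#' @param masks Optional list of 3 binary matrices of the same shape.
#' @param dynamic_index Integer label.
#' @return An object of class `dynamic_triplet`.
#' @export
dynamic_triplet <- function(slices, masks = NULL, dynamic_index = NA_integer_) {
  if (length(slices) != 3) abort("A dynamic consists of exactly 3 slices.")
  purrr::walk(slices, assert_matrix2d, name = "slice")
  for (s in slices[-1]) assert_same_shape(slices[[1]], s, "slices")
  if (!is.null(masks)) {
    if (length(masks) != 3) abort("Need exactly 3 masks.")
    for (m in masks) assert_same_shape(slices[[1]], m, "slices and masks")
  }
  structure(list(slices = slices, masks = masks,
                 dynamic_index = as.integer(dynamic_index)),
            class = "dynamic_triplet")
}

#' Unique tip estimate for one dynamic
#'
#' Pools the connected regions of all three per-slice masks and keeps only
#' the region with the highest signal intensity — the disambiguation rule
#' that guarantees a unique catheter-tip estimate even when balloon signal
#' appears in two adjacent slices (the slice containing most of the balloon
#' wins). Ties resolve deterministically: lowest slice index, then largest
#' region, then smallest (row, col) centroid.
#'
#' @param triplet A [dynamic_triplet()] with `masks` present.
#' @param connectivity,scoring Passed to [extract_regions()].
#' @return A one-row tibble: `dynamic_index`, `present`, `slice_index`,
#'   `tip_row`, `tip_col`, `intensity_score`. When no region exists,
#'   `present` is `FALSE` and the remaining fields are `NA`.
#' @export
select_candidate <- function(triplet, connectivity = 8L,
                             scoring = c("mean", "peak")) {
  stopifnot(inherits(triplet, "dynamic_triplet"))
  if (is.null(triplet$masks)) {
    abort("Triplet carries no masks; run the segmentation model first.")
  }
  scoring <- match.arg(scoring)
  regions <- purrr::map_dfr(1:3, function(s) {
    extract_regions(triplet$masks[[s]], triplet$slices[[s]],
                    slice_index = s, connectivity = connectivity,
                    scoring = scoring)
  })
  absent <- tibble::tibble(dynamic_index = triplet$dynamic_index,
                           present = FALSE, slice_index = NA_integer_,
                           tip_row = NA_real_, tip_col = NA_real_,
                           intensity_score = NA_real_)
  if (nrow(regions) == 0) return(absent)
  win <- regions |>
    dplyr::arrange(dplyr::desc(.data$intensity_score), .data$slice_index,
                   dplyr::desc(.data$n_pixels), .data$centroid_row,
                   .data$centroid_col) |>
    dplyr::slice(1)
  tibble::tibble(dynamic_index = triplet$dynamic_index, present = TRUE,
                 slice_index = win$slice_index, tip_row = win$centroid_row,
                 tip_col = win$centroid_col,
                 intensity_score = win$intensity_score)
}

#' Track the catheter tip through a sequence of dynamics
#'
#' For each dynamic independently: segment the three slices with the
#' trained network, split the predicted masks into connected regions, and
#' keep the single highest-intensity region as the tip estimate. No state
#' is carried between dynamics.
#'
#' @param dynamics A list (or `dynamic_set`) of [dynamic_triplet()]s.
#' @param model A trained `catheter_model`.
#' @param connectivity,scoring Passed to [extract_regions()].
#' @return A tibble with one row per dynamic, in input order, with the
#'   columns of [select_candidate()].
#' @export
track_sequence <- function(dynamics, model, connectivity = 8L,
                           scoring = c("mean", "peak")) {
  scoring <- match.arg(scoring)
  if (length(dynamics) == 0) {
    return(tibble::tibble(dynamic_index = integer(0), present = logical(0),
                          slice_index = integer(0), tip_row = numeric(0),
                          tip_col = numeric(0), intensity_score = numeric(0)))
  }
  purrr::map_dfr(dynamics, function(dyn) {
    stopifnot(inherits(dyn, "dynamic_triplet"))
    dyn$masks <- purrr::map(dyn$slices, ~ predict_mask(model, .x))
    select_candidate(dyn, connectivity = connectivity, scoring = scoring)
  })
}
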