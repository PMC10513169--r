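test_that("connected components use 8-connectivity with correct centroid and score", {
  m <- matrix(0L, 10, 10)
  m[5, 5] <- m[5, 6] <- m[6, 5] <- 1L
  img <- matrix(0, 10, 10)
  img[5, 5] <- 2; img[5, 6] <- 4; img[6, 5] <- 6
  reg <- extract_regions(m, img, slice_index = 2L)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$slice_index, 2L)
  expect_identical(reg$n_pixels, 3L)
  expect_equal(reg$centroid_row, 16 / 3)
  expect_equal(reg$centroid_col, 16 / 3)
  expect_equal(reg$intensity_score, 4.0)
  # diagonal-only touch merges under 8-connectivity...
  d <- matrix(0L, 6, 6); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_identical(nrow(extract_regions(d, matrix(1, 6, 6))), 1L)
  # ...but splits under 4-connectivity
  expect_identical(nrow(extract_regions(d, matrix(1, 6, 6),
                                        connectivity = 4L)), 2L)
})

test_that("empty masks yield no regions and shape mismatches fail", {
  expect_identical(nrow(extract_regions(matrix(0L, 5, 5), matrix(1, 5, 5))),
                   0L)
  expect_error(extract_regions(matrix(0L, 5, 5), matrix(1, 4, 4)), "shape")
})

test_that("peak scoring is selectable", {
  m <- matrix(0L, 6, 6); m[2:3, 2] <- 1L
  img <- matrix(0, 6, 6); img[2, 2] <- 1; img[3, 2] <- 9
  expect_equal(extract_regions(m, img)$intensity_score, 5)
  expect_equal(extract_regions(m, img, scoring = "peak")$intensity_score, 9)
})

make_triplet <- function(specs, H = 16, W = 16, dynamic_index = 1L) {
  # specs: list of per-slice lists of list(px = matrix, value = intensity)
  slices <- masks <- list()
  for (s in 1:3) {
    img <- matrix(0.1, H, W)
    msk <- matrix(0L, H, W)
    for (blob in specs[[s]]) {
      msk[blob$px] <- 1L
      img[blob$px] <- blob$value
    }
    slices[[s]] <- img; masks[[s]] <- msk
  }
  dynamic_triplet(slices, masks, dynamic_index = dynamic_index)
}

blob <- function(rows, cols, H = 16) {
  cbind(rep(rows, length(cols)), rep(cols, each = length(rows)))
}

test_that("the highest-intensity region wins across slices", {
  tri <- make_triplet(list(
    list(list(px = blob(3:4, 3:4), value = 0.8)),
    list(),
    list(list(px = blob(10:11, 10:11), value = 1.2))
  ))
  est <- select_candidate(tri)
  expect_true(est$present)
  expect_identical(est$slice_index, 3L)
  expect_equal(est$tip_row, 10.5)
  expect_equal(est$tip_col, 10.5)
  expect_equal(est$intensity_score, 1.2)
})

test_that("absence and tie-breaking behave deterministically", {
  none <- make_triplet(list(list(), list(), list()))
  est <- select_candidate(none)
  expect_false(est$present)
  expect_true(is.na(est$slice_index))
  # equal scores on slices 1 and 2 -> lowest slice index wins
  tie <- make_triplet(list(
    list(list(px = blob(3:4, 3:4), value = 1.0)),
    list(list(px = blob(8:9, 8:9), value = 1.0)),
    list()
  ))
  expect_identical(select_candidate(tie)$slice_index, 1L)
  # same slice, same score -> larger region wins
  tie2 <- make_triplet(list(
    list(list(px = blob(2:3, 2:3), value = 1.0),
         list(px = blob(9:12, 9:12), value = 1.0)),
    list(), list()
  ))
  expect_equal(select_candidate(tie2)$tip_row, 10.5)
})

test_that("candidate selection equals a brute-force maximum on random cases", {
  set.seed(21)
  for (i in 1:15) {
    specs <- purrr::map(1:3, function(s) {
      n <- sample(0:2, 1)
      purrr::map(seq_len(n), function(j) {
        r0 <- sample(2:12, 1); c0 <- sample(2:12, 1)
        list(px = blob(r0:(r0 + 1), c0:(c0 + 1)),
             value = round(runif(1, 0.2, 2), 3))
      })
    })
    tri <- make_triplet(specs)
    est <- select_candidate(tri)
    # brute force over the pooled per-slice regions
    pool <- purrr::map_dfr(1:3, function(s) {
      extract_regions(tri$masks[[s]], tri$slices[[s]], slice_index = s)
    })
    if (nrow(pool) == 0) {
      expect_false(est$present)
    } else {
      expect_equal(est$intensity_score, max(pool$intensity_score))
    }
  }
})

test_that("tracking is stateless across dynamics and handles empty input", {
  m <- build_model(training_config(base_channels = 4, rng_seed = 6))
  expect_identical(nrow(track_sequence(list(), m)), 0L)
  ph <- generate_phantom(c(64, 64), rng_seed = 12)
  tri1 <- dynamic_triplet(list(ph, ph, ph), dynamic_index = 1L)
  tri2 <- dynamic_triplet(list(ph * 1.1, ph, ph), dynamic_index = 2L)
  fwdA <- track_sequence(list(tri1, tri2), m)
  fwdB <- track_sequence(list(tri2, tri1), m)
  expect_identical(nrow(fwdA), 2L)
  expect_equal(fwdA[fwdA$dynamic_index == 1, ],
               fwdB[fwdB$dynamic_index == 1, ], ignore_attr = TRUE)
})

test_that("a triplet requires exactly three equally shaped slices", {
  ph <- matrix(1, 8, 8)
  expect_error(dynamic_triplet(list(ph, ph)), "3 slices")
  expect_error(dynamic_triplet(list(ph, ph, matrix(1, 6, 6))), "shape")
  expect_error(select_candidate(dynamic_triplet(list(ph, ph, ph))), "masks")
})
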