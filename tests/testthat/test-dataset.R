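cfg_small <- dataset_config(n_subjects_train = 3L, n_subjects_val = 2L,
                            frames_per_subject = 10L, rng_seed = 5L)

test_that("the negative-fraction contract holds exactly by construction", {
  ds <- build_dataset(cfg_small) # 30 training frames, 10% -> 3 negatives
  n_neg <- sum(!purrr::map_lgl(ds$train, "has_catheter"))
  expect_identical(n_neg, 3L)
  # rounding to the nearest count
  cfg2 <- dataset_config(n_subjects_train = 1L, n_subjects_val = 1L,
                         frames_per_subject = 25L,
                         negative_fraction = 0.1, rng_seed = 5L)
  ds2 <- build_dataset(cfg2)
  expect_identical(sum(!purrr::map_lgl(ds2$train, "has_catheter")),
                   as.integer(round(0.1 * 25)))
})

test_that("train and validation subject sets are disjoint with the configured sizes", {
  ds <- build_dataset(dataset_config(frames_per_subject = 2L, rng_seed = 1L))
  tr <- unique(purrr::map_chr(ds$train, "subject_id"))
  va <- unique(purrr::map_chr(ds$val, "subject_id"))
  expect_length(tr, 8)
  expect_length(va, 4)
  expect_length(intersect(tr, va), 0)
})

test_that("dataset generation is bit-reproducible under a fixed seed", {
  a <- build_dataset(cfg_small)
  b <- build_dataset(cfg_small)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$train[[7]]$image, b$train[[7]]$image)
  expect_identical(a$train[[7]]$gt_mask, b$train[[7]]$gt_mask)
  c2 <- build_dataset(dataset_config(n_subjects_train = 3L,
                                     n_subjects_val = 2L,
                                     frames_per_subject = 10L,
                                     rng_seed = 6L))
  expect_false(identical(a$train[[1]]$image, c2$train[[1]]$image))
})

test_that("frame invariants hold: has_catheter mirrors mask content", {
  ds <- build_dataset(cfg_small)
  for (f in c(ds$train, ds$val)) {
    expect_identical(dim(f$image), dim(f$gt_mask))
    expect_identical(f$has_catheter, any(f$gt_mask > 0))
    if (f$has_catheter) expect_gte(sum(f$gt_mask), 10)
  }
})

test_that("invalid negative fractions are rejected", {
  expect_error(dataset_config(negative_fraction = 1.2), "\\[0, 1\\]")
  expect_error(dataset_config(negative_fraction = -0.1), "\\[0, 1\\]")
})

test_that("evaluation dynamics carry consistent ground truth", {
  dyn <- build_dynamics(n_subjects = 2L, dynamics_per_subject = 6L,
                        negative_fraction = 0.25, rng_seed = 4L)
  expect_length(dyn, 12)
  n_neg <- 0
  for (d in dyn) {
    expect_s3_class(d, "dynamic_triplet")
    gt <- attr(d, "gt_masks")
    ts <- attr(d, "true_slice")
    if (is.na(ts)) {
      n_neg <- n_neg + 1
      expect_true(all(purrr::map_int(gt, sum) == 0L))
    } else {
      expect_gt(sum(gt[[ts]]), 0)
      tc <- attr(d, "true_center")
      expect_identical(gt[[ts]][round(tc[1]), round(tc[2])], 1L)
      # the true slice carries the strongest balloon signal
      ms <- make_multislice_gt(gt, d$slices)
      expect_identical(ms$slice_index, ts)
    }
  }
  expect_identical(n_neg, round(0.25 * 12))
  # reproducibility
  dyn2 <- build_dynamics(n_subjects = 2L, dynamics_per_subject = 6L,
                         negative_fraction = 0.25, rng_seed = 4L)
  expect_identical(dyn[[3]]$slices, dyn2[[3]]$slices)
})
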