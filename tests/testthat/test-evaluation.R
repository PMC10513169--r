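test_that("detection classification matches the exhaustive truth-table oracle", {
  gt_full <- matrix(0L, 12, 12); gt_full[5:7, 5:7] <- 1L
  gt_empty <- matrix(0L, 12, 12)
  inside <- c(6, 6); outside <- c(2, 2); outside2 <- c(10, 10)
  cases <- list(
    list(regions = list(), gt = gt_empty, expect = "TN"),
    list(regions = list(), gt = gt_full, expect = "FN"),
    list(regions = list(inside), gt = gt_empty, expect = "FP"),
    list(regions = list(outside), gt = gt_empty, expect = "FP"),
    list(regions = list(inside), gt = gt_full, expect = "TP"),
    list(regions = list(outside), gt = gt_full, expect = "FP"),
    list(regions = list(inside, outside), gt = gt_empty, expect = "FP"),
    list(regions = list(inside, outside), gt = gt_full, expect = "FP"),
    list(regions = list(outside, outside2), gt = gt_full, expect = "FP"),
    list(regions = list(outside, outside2), gt = gt_empty, expect = "FP")
  )
  for (cs in cases) {
    expect_identical(classify_detection(region_stub(cs$regions), cs$gt),
                     cs$expect,
                     info = paste(length(cs$regions), "regions, gt",
                                  if (any(cs$gt > 0)) "full" else "empty"))
  }
  # alternative convention: wrong-regions-only with catheter present -> FN
  expect_identical(
    classify_detection(region_stub(list(outside)), gt_full,
                       fn_if_missed = TRUE), "FN")
  expect_identical(
    classify_detection(region_stub(list(inside, outside)), gt_full,
                       fn_if_missed = TRUE), "FP")
})

test_that("centroid membership uses nearest-pixel rounding", {
  gt <- matrix(0L, 10, 10); gt[5, 5] <- 1L
  expect_identical(classify_detection(region_stub(list(c(5.4, 4.6))), gt),
                   "TP")
  expect_identical(classify_detection(region_stub(list(c(5.6, 5.0))), gt),
                   "FP")
})

test_that("the multi-slice ground truth keeps the highest-intensity region", {
  H <- 12
  gt1 <- matrix(0L, H, H); gt1[2:3, 2:3] <- 1L
  gt2 <- matrix(0L, H, H); gt2[8:9, 8:9] <- 1L
  img1 <- matrix(0.9, H, H); img2 <- matrix(1.4, H, H)
  ms <- make_multislice_gt(list(gt1, gt2, matrix(0L, H, H)),
                           list(img1, img2, img2))
  expect_identical(ms$slice_index, 2L)
  expect_identical(ms$mask, gt2)
  # single candidate
  ms1 <- make_multislice_gt(list(matrix(0L, H, H), gt1, matrix(0L, H, H)),
                            list(img1, img1, img1))
  expect_identical(ms1$slice_index, 2L)
  expect_identical(ms1$mask, gt1)
  # all empty
  ms0 <- make_multislice_gt(rep(list(matrix(0L, H, H)), 3),
                            rep(list(img1), 3))
  expect_true(is.na(ms0$slice_index))
  expect_identical(sum(ms0$mask), 0L)
})

test_that("detection metrics follow the standard formulas", {
  out <- c(rep("TP", 19), rep("FN", 3), rep("TN", 60))
  m <- compute_metrics(out)
  expect_equal(m$sensitivity, 100 * 19 / 22, tolerance = 1e-12)
  expect_equal(round(m$sensitivity, 1), 86.4)
  expect_equal(m$specificity, 100)
  expect_equal(round(m$accuracy, 1), 96.3)
  sym <- compute_metrics(c("TP", "FP", "TN", "FN"))
  expect_equal(c(sym$accuracy, sym$sensitivity, sym$specificity),
               c(50, 50, 50))
  # outcome labels partition the units
  expect_identical(sym$tp + sym$fp + sym$tn + sym$fn, sym$n)
})

test_that("zero-denominator metrics are NA with a warning, not 0 or 100", {
  expect_warning(m <- compute_metrics(rep("TP", 5)), "Specificity")
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_true(is.na(m$specificity))
  expect_error(compute_metrics(character(0)), "nonempty")
  expect_error(compute_metrics(c("TP", "XX")), "Unknown")
})

test_that("patient aggregation is the unweighted mean with population sd", {
  agg <- aggregate_patients(reference_patient_metrics)
  expect_equal(round(agg$mean[agg$metric == "accuracy"], 1), 98.4)
  expect_equal(round(agg$mean[agg$metric == "specificity"], 1), 99.9)
  expect_equal(round(agg$mean[agg$metric == "sensitivity"], 1), 95.4)
  expect_equal(round(agg$sd[agg$metric == "sensitivity"], 1), 5.5)
  expect_equal(round(agg$sd[agg$metric == "specificity"], 1), 0.2)
  # a single patient aggregates to itself with zero spread
  one <- aggregate_patients(reference_patient_metrics[4, ])
  expect_equal(one$mean[one$metric == "sensitivity"], 86.4)
  expect_true(all(one$sd == 0))
  # NA metrics are excluded from aggregation
  df <- tibble::tibble(accuracy = c(100, 90), specificity = c(100, NA),
                       sensitivity = c(100, 80))
  agg2 <- aggregate_patients(df)
  expect_equal(agg2$mean[agg2$metric == "specificity"], 100)
  expect_identical(agg2$n_patients[agg2$metric == "specificity"], 1L)
})

test_that("per-image evaluation partitions every frame into one outcome", {
  frames <- tiny_frames(8, seed = 3, p_negative = 0.3)
  m <- build_model(training_config(base_channels = 2L, rng_seed = 1L))
  rep <- suppressWarnings(evaluate_frames(frames, m))
  expect_s3_class(rep, "metrics_report")
  expect_identical(nrow(rep$outcomes), 8L)
  expect_true(all(rep$outcomes$outcome %in% c("TP", "FP", "TN", "FN")))
  expect_identical(sum(rep$counts$n), 8L)
  expect_identical(with(rep$counts, sum(tp + fp + tn + fn)), 8L)
})

test_that("operator agreement is the mutual center-of-mass criterion", {
  a <- matrix(0L, 15, 15); a[4:6, 4:6] <- 1L
  expect_true(operator_agreement(a, a))
  b <- matrix(0L, 15, 15); b[10:12, 10:12] <- 1L
  expect_false(operator_agreement(a, b))
  # ring mask whose centroid falls in its hole: one-sided containment fails
  ring <- matrix(0L, 15, 15); ring[3:13, 3:13] <- 1L; ring[5:11, 5:11] <- 0L
  small <- matrix(0L, 15, 15); small[8, 8] <- 1L # inside the hole
  expect_false(operator_agreement(small, ring))
  expect_false(operator_agreement(ring, small))
  # symmetry on random mask pairs
  set.seed(13)
  for (i in 1:10) {
    m1 <- matrix(as.integer(runif(100) < 0.3), 10, 10)
    m2 <- matrix(as.integer(runif(100) < 0.3), 10, 10)
    expect_identical(operator_agreement(m1, m2), operator_agreement(m2, m1))
  }
  # empties: both empty agree, one empty disagrees
  e <- matrix(0L, 15, 15)
  expect_true(operator_agreement(e, e))
  expect_false(operator_agreement(a, e))
})
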