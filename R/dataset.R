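#' Configuration of the semi-artificial dataset
#'
#' Defaults reproduce the study conditions of the training-data simulator:
#' an 8-subject training set and a disjoint 4-subject validation set, a
#' fixed share of 10% catheter-free training frames (so the network learns
#' to suppress false positives), and one simulated balloon per frame.
#'
#' @param n_subjects_train,n_subjects_val Number of phantom subjects per
#'   split; backgrounds are never shared across splits.
#' @param frames_per_subject Frames generated per subject (one balloon
#'   placement per frame).
#' @param negative_fraction Proportion of training frames left catheter-free
#'   (default 0.10).
#' @param image_shape Integer `c(rows, cols)` of every frame.
#' @param rng_seed Integer seed; dataset generation is bit-reproducible.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(n_subjects_train = 8L, n_subjects_val = 4L,
                           frames_per_subject = 40L,
                           negative_fraction = 0.10,
                           image_shape = c(64L, 64L), rng_seed = 1L) {
  if (negative_fraction < 0 || negative_fraction > 1) {
    abort("`negative_fraction` must lie in [0, 1].")
  }
  stopifnot(n_subjects_train >= 1, n_subjects_val >= 0,
            frames_per_subject >= 1, length(image_shape) == 2)
  structure(
    list(n_subjects_train = as.integer(n_subjects_train),
         n_subjects_val = as.integer(n_subjects_val),
         frames_per_subject = as.integer(frames_per_subject),
         negative_fraction = negative_fraction,
         image_shape = as.integer(image_shape),
         rng_seed = as.integer(rng_seed)),
    class = "dataset_config"
  )
}

build_split <- function(subjects, cfg, negative_fraction, seed_base) {
  frames <- list()
  n_total <- length(subjects) * cfg$frames_per_subject
  n_neg <- round(negative_fraction * n_total)
  # spread negatives deterministically across the frame sequence
  neg_ids <- if (n_neg > 0) {
    round(seq(1, n_total, length.out = n_neg + 2L))[2:(n_neg + 1L)]
  } else {
    integer(0)
  }
  k <- 0L
  for (s in seq_along(subjects)) {
    # every frame gets its own background slice, emulating a multi-slice
    # stack per subject rather than one repeated image
    for (j in seq_len(cfg$frames_per_subject)) {
      k <- k + 1L
      phantom <- generate_phantom(cfg$image_shape,
                                  rng_seed = derive_seed(seed_base,
                                                         s * 1000L + j))
      fr <- with_rng(derive_seed(seed_base, 500000L + s * 1000L + j), {
        if (k %in% neg_ids) {
          annotated_frame(image = phantom, subject_id = subjects[s],
                          slice_index = j)
        } else {
          pl <- sample_placements(phantom, 1L)
          p <- sample_catheter_params(pl[1L, ])
          f <- simulate_catheter(phantom, p)
          f$subject_id <- subjects[s]
          f$slice_index <- as.integer(j)
          f
        }
      })
      frames[[k]] <- fr
    }
  }
  frames
}

#' Build a semi-artificial training and validation dataset
#'
#' Generates one procedural phantom background per subject, samples balloon
#' placements inside its blood-pool structures, and creates one annotated
#' frame per placement (at most one balloon per frame, as only one catheter
#' can be present at a time during a procedure). A `negative_fraction` share
#' of each split's frames carries no balloon and an all-zero mask. Subjects
#' (and hence backgrounds) are disjoint between training and validation.
#'
#' @param config A [dataset_config()].
#' @return A list of class `catheter_dataset` with elements `train` and
#'   `val` (lists of [annotated_frame()] objects), the `config`, and a
#'   `manifest` tibble (subject_id, split, frame, has_catheter).
#' @export
#' @examples
#' ds <- build_dataset(dataset_config(n_subjects_train = 1, n_subjects_val = 1,
#'                                    frames_per_subject = 10))
#' ds$manifest
build_dataset <- function(config = dataset_config()) {
  stopifnot(inherits(config, "dataset_config"))
  train_subj <- sprintf("train%02d", seq_len(config$n_subjects_train))
  val_subj <- sprintf("val%02d", seq_len(config$n_subjects_val))
  train <- build_split(train_subj, config, config$negative_fraction,
                       derive_seed(config$rng_seed, 11L))
  val <- if (config$n_subjects_val > 0) {
    build_split(val_subj, config, config$negative_fraction,
                derive_seed(config$rng_seed, 22L))
  } else {
    list()
  }
  manifest <- dplyr::bind_rows(
    purrr::imap(train, function(f, i) {
      tibble::tibble(subject_id = f$subject_id, split = "train",
                     frame = i, has_catheter = f$has_catheter)
    }),
    purrr::imap(val, function(f, i) {
      tibble::tibble(subject_id = f$subject_id, split = "val",
                     frame = i, has_catheter = f$has_catheter)
    })
  )
  structure(list(train = train, val = val, config = config,
                 manifest = manifest),
            class = "catheter_dataset")
}

#' @export
print.catheter_dataset <- function(x, ...) {
  cat(sprintf("<catheter_dataset> %d train / %d val frames (%dx%d), %d%% negatives\n",
              length(x$train), length(x$val), x$config$image_shape[1],
              x$config$image_shape[2],
              round(100 * x$config$negative_fraction)))
  invisible(x)
}

#' Build held-out multi-slice dynamics for pipeline evaluation
#'
#' Emulates the inference-time acquisition: each dynamic is a triplet of
#' three contiguous slices from one subject (a shared anatomy background,
#' each slice carrying fresh acquisition noise). In a positive dynamic the
#' balloon is planted in exactly one (known) slice; with probability
#' `p_bleed` a fainter copy (half peak amplitude) also appears in an
#' adjacent slice, mimicking a balloon straddling two slices — the case the
#' highest-intensity disambiguation step exists to resolve. A
#' `negative_fraction` share of dynamics carries no balloon at all.
#'
#' @param n_subjects Number of held-out phantom subjects.
#' @param dynamics_per_subject Dynamics generated per subject.
#' @param negative_fraction Share of catheter-free dynamics (default 0.3,
#'   so per-patient specificity is measurable).
#' @param p_bleed Probability that a positive dynamic shows the balloon in
#'   two adjacent slices (default 0.3).
#' @param image_shape Integer `c(rows, cols)`.
#' @param rng_seed Integer seed.
#' @return A list of class `dynamic_set`: each element is a
#'   [dynamic_triplet()] carrying ground-truth masks, the true slice and the
#'   true balloon center as attributes (`gt_masks`, `true_slice`,
#'   `true_center`, `subject_id`).
#' @export
build_dynamics <- function(n_subjects = 4L, dynamics_per_subject = 15L,
                           negative_fraction = 0.3, p_bleed = 0.3,
                           image_shape = c(64L, 64L), rng_seed = 1L) {
  stopifnot(n_subjects >= 1, dynamics_per_subject >= 1)
  dynamics <- list()
  k <- 0L
  n_total <- n_subjects * dynamics_per_subject
  n_neg <- round(negative_fraction * n_total)
  neg_ids <- if (n_neg > 0) {
    round(seq(1, n_total, length.out = n_neg + 2L))[2:(n_neg + 1L)]
  } else {
    integer(0)
  }
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("test%02d", s)
    phantom <- generate_phantom(image_shape,
                                rng_seed = derive_seed(rng_seed, 333L + s))
    with_rng(derive_seed(rng_seed, 777L + s), {
      pl <- sample_placements(phantom, dynamics_per_subject)
      for (j in seq_len(dynamics_per_subject)) {
        k <- k + 1L
        slices <- list(phantom, phantom, phantom)
        gt <- list(matrix(0L, image_shape[1], image_shape[2]),
                   matrix(0L, image_shape[1], image_shape[2]),
                   matrix(0L, image_shape[1], image_shape[2]))
        true_slice <- NA_integer_
        true_center <- c(NA_real_, NA_real_)
        if (!(k %in% neg_ids)) {
          true_slice <- sample(1:3, 1)
          p <- sample_catheter_params(pl[j, ])
          f <- simulate_catheter(phantom, p)
          slices[[true_slice]] <- f$image
          gt[[true_slice]] <- f$gt_mask
          true_center <- c(p$center_row, p$center_col)
          if (runif(1) < p_bleed) {
            adj <- if (true_slice == 1) 2L else if (true_slice == 3) 2L
              else sample(c(1L, 3L), 1)
            amp <- p$amplitude_pct / 100 *
              phantom[round_px(p$center_row), round_px(p$center_col)] / 2
            slices[[adj]] <- phantom + amp *
              gaussian_field(p, image_shape)
            gt[[adj]] <- f$gt_mask
          }
        }
        # every slice is a fresh acquisition: independent pixel noise at
        # the generator's acquisition-noise level
        slices <- purrr::map(slices, function(sl) {
          pmax(sl + 0.01 * matrix(rnorm(length(sl)), nrow(sl)), 0)
        })
        dyn <- dynamic_triplet(slices, dynamic_index = k)
        attr(dyn, "gt_masks") <- gt
        attr(dyn, "true_slice") <- true_slice
        attr(dyn, "true_center") <- true_center
        attr(dyn, "subject_id") <- subj
        dynamics[[k]] <- dyn
      }
    })
  }
  structure(dynamics, class = "dynamic_set")
}
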