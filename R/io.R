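#' Write a dataset to disk
#'
#' Writes every frame as a lossless NIfTI pair (float image, uint8 mask)
#' plus a CSV manifest (subject_id, split, image and mask paths,
#' has_catheter). With `png_preview = TRUE` (and the png package installed)
#' an 8-bit PNG preview of each image is written alongside.
#'
#' @param dataset A `catheter_dataset` from [build_dataset()].
#' @param dir Output directory (created if missing).
#' @param png_preview Write 8-bit preview images.
#' @return Invisibly, the manifest tibble with file paths.
#' @export
write_dataset <- function(dataset, dir, png_preview = FALSE) {
  stopifnot(inherits(dataset, "catheter_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  k <- 0L
  for (split in c("train", "val")) {
    for (i in seq_along(dataset[[split]])) {
      f <- dataset[[split]][[i]]
      k <- k + 1L
      stem <- sprintf("%s_%04d", split, i)
      img_path <- file.path(dir, paste0(stem, "_img.nii.gz"))
      msk_path <- file.path(dir, paste0(stem, "_mask.nii.gz"))
      RNifti::writeNifti(f$image, img_path)
      RNifti::writeNifti(f$gt_mask, msk_path, datatype = "uint8")
      if (png_preview && requireNamespace("png", quietly = TRUE)) {
        rng <- range(f$image)
        png::writePNG((f$image - rng[1]) / max(rng[2] - rng[1], 1e-12),
                      file.path(dir, paste0(stem, ".png")))
      }
      rows[[k]] <- tibble::tibble(
        subject_id = f$subject_id, split = split,
        image = basename(img_path), mask = basename(msk_path),
        has_catheter = f$has_catheter)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A `catheter_dataset` with `train` and `val` frame lists.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv in %s.", dir))
  manifest <- tibble::as_tibble(read.csv(mf, stringsAsFactors = FALSE))
  load_frame <- function(row) {
    img <- drop(RNifti::asNifti(RNifti::readNifti(file.path(dir, row$image))))
    msk <- drop(RNifti::asNifti(RNifti::readNifti(file.path(dir, row$mask))))
    annotated_frame(image = matrix(as.numeric(img), nrow(img), ncol(img)),
                    gt_mask = matrix(as.integer(msk), nrow(msk), ncol(msk)),
                    subject_id = row$subject_id)
  }
  out <- list(train = list(), val = list(), manifest = manifest)
  for (split in c("train", "val")) {
    sub <- manifest[manifest$split == split, ]
    out[[split]] <- purrr::map(seq_len(nrow(sub)),
                               function(i) load_frame(sub[i, ]))
  }
  structure(out, class = "catheter_dataset")
}

#' Save a trained model
#'
#' Writes the weights in R's serialization format plus a JSON sidecar with
#' the training configuration, best epoch and loss histories.
#'
#' @param model A `catheter_model`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "catheter_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  side <- list(config = unclass(model$config), best_epoch = model$best_epoch,
               train_loss_history = model$train_loss_history,
               val_loss_history = model$val_loss_history)
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(loss_history(model), file.path(dir, "loss_history.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir Directory containing `model.rds`.
#' @return A `catheter_model`.
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) abort(sprintf("No model.rds in %s.", dir))
  readRDS(path)
}
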