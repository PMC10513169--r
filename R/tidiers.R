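#' Tidy a trained segmentation model
#'
#' @param x A `catheter_model`.
#' @param ... Unused.
#' @return The per-epoch loss curves, one row per epoch (see
#'   [loss_history()]).
#' @export
tidy.catheter_model <- function(x, ...) loss_history(x)

#' One-row summary of a trained segmentation model
#'
#' @param x A `catheter_model`.
#' @param ... Unused.
#' @return A tibble with `n_parameters`, `n_epochs`, `best_epoch`,
#'   `best_val_loss`, `final_train_loss`.
#' @export
glance.catheter_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(purrr::map_dbl(x$layers,
                                      ~ length(.x$W) + length(.x$b))),
    n_epochs = length(x$val_loss_history),
    best_epoch = x$best_epoch,
    best_val_loss = if (is.na(x$best_epoch)) NA_real_ else
      x$val_loss_history[x$best_epoch],
    final_train_loss = if (length(x$train_loss_history))
      x$train_loss_history[length(x$train_loss_history)] else NA_real_
  )
}

#' Tidy an evaluation report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-patient metric tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_patient

#' One-row summary of an evaluation report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble with mean and sd of each metric plus total counts.
#' @export
glance.metrics_report <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(.rows = 1)
  for (i in seq_len(nrow(s))) {
    out[[paste0("mean_", s$metric[i])]] <- s$mean[i]
    out[[paste0("sd_", s$metric[i])]] <- s$sd[i]
  }
  out$n_units <- sum(x$per_patient$n)
  out$n_patients <- nrow(x$per_patient)
  out
}

#' Plot training and validation loss curves
#'
#' @param object A trained `catheter_model`.
#' @param ... Unused.
#' @return A ggplot: Dice loss per epoch, best epoch marked.
#' @export
autoplot.catheter_model <- function(object, ...) {
  df <- loss_history(object) |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "set", values_to = "loss") |>
    dplyr::mutate(set = sub("_loss", "", .data$set))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                        colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Dice loss", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$best_epoch)) {
    p <- p + ggplot2::geom_vline(xintercept = object$best_epoch,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot per-patient detection metrics
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot with one bar per patient and metric.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- object$per_patient |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "percent")
  ggplot2::ggplot(df, ggplot2::aes(.data$subject_id, .data$percent,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "%", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an annotated frame
#'
#' @param object An [annotated_frame()].
#' @param ... Unused.
#' @return A ggplot raster of the image with the ground-truth balloon mask
#'   outlined.
#' @export
autoplot.annotated_frame <- function(object, ...) {
  H <- nrow(object$image); W <- ncol(object$image)
  df <- tibble::tibble(
    row = rep(seq_len(H), W),
    col = rep(seq_len(W), each = H),
    intensity = as.vector(object$image),
    balloon = as.vector(object$gt_mask) > 0
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
  if (any(df$balloon)) {
    p <- p + ggplot2::geom_tile(data = dplyr::filter(df, .data$balloon),
                                fill = NA, colour = "red",
                                linewidth = 0.2)
  }
  p
}
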