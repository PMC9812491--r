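#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   labs theme_minimal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-epoch loss trace of a fit (or the per-rotation
#' metrics of a cross-validation result); `glance()` returns a one-row
#' summary.
#'
#' @param x a `vgae_fit`, `cnn_fit`, or `cv_result`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.vgae_fit <- function(x, ...) x$losses

#' @rdname tidy.vgae_fit
#' @export
tidy.cnn_fit <- function(x, ...) x$losses

#' @rdname tidy.vgae_fit
#' @export
tidy.cv_result <- function(x, ...) x$rotations

#' @rdname tidy.vgae_fit
#' @export
glance.vgae_fit <- function(x, ...) {
  tibble(
    epochs = nrow(x$losses),
    final_loss = x$losses$total[nrow(x$losses)],
    final_reconstruction = x$losses$reconstruction[nrow(x$losses)],
    final_kl = x$losses$kl[nrow(x$losses)],
    d0 = x$config$d0, d1 = x$config$d1
  )
}

#' @rdname tidy.vgae_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(
    epochs = nrow(x$losses),
    final_loss = x$losses$loss[nrow(x$losses)],
    batch_size = x$config$batch_size
  )
}

#' @rdname tidy.vgae_fit
#' @export
glance.cv_result <- function(x, ...) x$mean

#' Loss-trace and curve plots
#'
#' `autoplot()` on a `vgae_fit`/`cnn_fit` draws the training loss trace;
#' on a `cv_result` it draws the pooled ROC and PR curves over the held-out
#' predictions of all rotations.
#'
#' @param object a fitted object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vgae_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$losses, -"epoch",
    names_to = "term", values_to = "value"
  )
  ggplot(df, aes(x = .data$epoch, y = .data$value, colour = .data$term)) +
    geom_line() +
    labs(
      x = "epoch", y = "loss",
      title = "Variational graph autoencoder training"
    ) +
    theme_minimal()
}

#' @rdname autoplot.vgae_fit
#' @export
autoplot.cnn_fit <- function(object, ...) {
  ggplot(object$losses, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(
      x = "epoch", y = "cross-entropy",
      title = "Pair classifier training"
    ) +
    theme_minimal()
}

#' @rdname autoplot.vgae_fit
#' @export
autoplot.cv_result <- function(object, ...) {
  preds <- object$predictions
  pts <- roc_pr_points(preds$label, preds$probability)
  roc <- dplyr::mutate(
    tibble(x = c(0, pts$fpr), y = c(0, pts$tpr)),
    curve = "ROC"
  )
  pr <- dplyr::mutate(
    tibble(x = pts$recall, y = pts$precision),
    curve = "Precision-recall"
  )
  ggplot(dplyr::bind_rows(roc, pr), aes(x = .data$x, y = .data$y)) +
    geom_line() +
    facet_wrap(~curve, scales = "free") +
    labs(
      x = NULL, y = NULL,
      title = sprintf(
        "Held-out performance (mean AUC %.3f, AUPR %.3f)",
        object$mean$auc, object$mean$aupr
      )
    ) +
    theme_minimal()
}
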