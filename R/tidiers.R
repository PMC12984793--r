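# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The summary tibble (one row per metric with mean, SD and CI).
#' @export
tidy.metric_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_cases = nrow(x$per_case),
                 mean_dice = s$mean[s$metric == "dice"],
                 mean_hd_mm = s$mean[s$metric == "hd_mm"],
                 auc = x$auc)
}

#' Tidy Holm-corrected paired comparisons
#'
#' @param x A `cineseg_holm` tibble from [paired_t_holm()].
#' @param ... Unused.
#' @export
tidy.cineseg_holm <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a trained structure CNN
#'
#' @param x A `cineseg_trained_model`.
#' @param ... Unused.
#' @return One row: architecture, parameter count, loss used, epochs,
#'   first/final training loss.
#' @export
glance.cineseg_trained_model <- function(x, ...) {
  tibble::tibble(arch = x$spec$name,
                 n_params = count_trainable_params(x$spec),
                 loss = x$config$loss,
                 epochs = length(x$loss_history),
                 first_loss = x$loss_history[1],
                 final_loss = utils::tail(x$loss_history, 1))
}

#' @rdname glance.cineseg_trained_model
#' @export
glance.cineseg_mi_trained <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_train_loss = utils::tail(h$train_loss, 1),
                 best_val_loss = min(h$val_loss),
                 final_lr = utils::tail(h$lr, 1))
}

#' Plot a metric report as mean +/- CI bars
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @export
autoplot.metric_report <- function(object, ...) {
  s <- dplyr::filter(object$summary, !is.na(.data$mean))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Segmentation metrics (mean, 95% bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' Plot the training-loss trajectory of a structure CNN
#'
#' @param object A `cineseg_trained_model`.
#' @param ... Unused.
#' @export
autoplot.cineseg_trained_model <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_history),
                       loss = object$loss_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = sprintf("Training loss (%s, %s)",
                                  object$spec$name, object$config$loss),
                  x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}

#' Plot a phantom frame with its structure masks outlined
#'
#' @param object A `phantom_case`.
#' @param frame Frame index to show.
#' @param ... Unused.
#' @export
autoplot.phantom_case <- function(object, frame = 1, ...) {
  img <- object$frames[[frame]]
  df <- tibble::tibble(row = rep(seq_len(nrow(img)), ncol(img)),
                       col = rep(seq_len(ncol(img)), each = nrow(img)),
                       value = as.vector(img))
  outlines <- purrr::map_dfr(names(object$masks[[frame]]), function(s) {
    m <- object$masks[[frame]][[s]]
    if (sum(m) == 0) return(NULL)
    ct <- contour_points(extract_contour(m))
    tibble::tibble(structure = s, row = ct[, 1], col = ct[, 2])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_point(data = outlines,
                        ggplot2::aes(color = .data$structure), size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Phantom frame %d", frame),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}
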