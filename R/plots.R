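#' Tidy / summarize fitted objects
#'
#' `tidy()` on a training fit returns the per-epoch history;
#' `glance()` returns a one-row summary.
#'
#' @param x A `rootgpr_fit` (from [train_model()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.rootgpr_fit <- function(x, ...) x$history

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.rootgpr_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_train_loss = h$train_loss[nrow(h)],
                 best_score = x$best_score,
                 final_lr = h$lr[nrow(h)],
                 parameters = count_parameters(x$model))
}

#' Plot a B-scan
#'
#' @param object A [bscan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bscan <- function(object, ...) {
  dt <- attr(object, "dt")
  pos <- attr(object, "trace_positions")
  df <- expand.grid(t = seq_len(nrow(object)) * dt * 1e9, x = pos)
  df$amplitude <- as.vector(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$t,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "trace position (m)", y = "two-way time (ns)",
                  fill = "amp") +
    ggplot2::theme_minimal()
}

#' Plot a permittivity map
#'
#' @param object A [permittivity_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permittivity_map <- function(object, ...) {
  dx <- attr(object, "dx")
  m <- unclass(object)
  df <- expand.grid(z = (seq_len(nrow(m)) - 0.5) * dx,
                    x = (seq_len(ncol(m)) - 0.5) * dx)
  df$eps <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$eps)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (m)", y = "depth (m)",
                  fill = expression(epsilon * minute)) +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param fit A `rootgpr_fit`.
#' @return A ggplot of train (and validation, when present) loss by epoch.
#' @export
plot_loss_curves <- function(fit) {
  h <- fit$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$train_loss,
                         set = "train"),
              if (any(!is.na(h$val_loss)))
                data.frame(epoch = h$epoch, loss = h$val_loss,
                           set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "composite loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
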