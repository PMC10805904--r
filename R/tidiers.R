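# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted detector
#'
#' One row per weight tensor with its shape and norm summaries.
#'
#' @param x An `eesnn_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `n_params`, `l2_norm`, `max_abs`.
#' @export
tidy.eesnn_fit <- function(x, ...) {
  w <- x$weights
  terms <- c(stats::setNames(w$F, sprintf("F%d", seq_along(w$F))),
             stats::setNames(w$b, sprintf("b%d", seq_along(w$b))),
             list(W1 = w$W1, W0 = w$W0, b0 = w$b0))
  dplyr::bind_rows(lapply(names(terms), function(nm) {
    v <- as.numeric(terms[[nm]])
    tibble::tibble(term = nm, n_params = length(v),
                   l2_norm = sqrt(sum(v^2)), max_abs = max(abs(v)))
  }))
}

#' Glance at a fitted detector
#'
#' @param x An `eesnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: trainer, layers, parameter count, epochs,
#'   final and minimum training loss.
#' @export
glance.eesnn_fit <- function(x, ...) {
  n_par <- sum(vapply(c(x$weights$F, x$weights$b,
                        list(x$weights$W1, x$weights$W0, x$weights$b0)),
                      length, integer(1)))
  tibble::tibble(trainer = x$trainer,
                 hidden_layers = x$config$hidden_layers,
                 snn_steps = x$config$snn_steps,
                 n_params = n_par,
                 epochs = if (nrow(x$log)) max(x$log$epoch) else 0L,
                 final_loss = if (nrow(x$log)) {
                   x$log$loss[nrow(x$log)]
                 } else {
                   NA_real_
                 },
                 min_loss = if (nrow(x$log)) min(x$log$loss) else NA_real_)
}

#' Tidy an evaluation
#'
#' @param x An `eesnn_eval`.
#' @param ... Unused.
#' @return A long tibble of metric/value pairs.
#' @export
tidy.eesnn_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Plot the training loss curve
#'
#' @param object An `eesnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eesnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$step,
                                           y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "optimization step", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot a saliency map
#'
#' Channels on the y axis, time on the x axis; red marks positive
#' (towards seizure) and blue negative gradients.
#'
#' @param object An `eesnn_saliency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eesnn_saliency <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(channel = seq_len(nrow(m)),
                           sample = seq_len(ncol(m)))
  df$value <- as.vector(m)[(df$sample - 1L) * nrow(m) + df$channel]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "time (samples)", y = "channel",
                  fill = "gradient") +
    ggplot2::theme_minimal()
}
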