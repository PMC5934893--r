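#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 diagnostics:
#' * `channel_map` — heat map of the pointwise biserial matrix \eqn{P_i(n)}
#'   with the selected channels marked;
#' * `hdca_model` — temporal weights \eqn{v_k} per time window;
#' * `auth_cv` — distribution of per-fold ACC/FAR/FRR.
#'
#' @param object The object to plot.
#' @param rate_hz Sampling rate used to label the time axis (default 600).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-rsvpauth
NULL

#' @rdname autoplot-rsvpauth
#' @method autoplot channel_map
#' @export
autoplot.channel_map <- function(object, rate_hz = 600, ...) {
  P <- object$P
  df <- tibble::tibble(
    channel = factor(rep(rownames(P), ncol(P)), levels = rev(rownames(P))),
    time_ms = rep((seq_len(ncol(P)) - 1) / rate_hz * 1000,
                  each = nrow(P)),
    p = as.numeric(P))
  sel <- if (!is.null(object$selected))
    object$channel_names[object$selected] else character()
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "P") +
    ggplot2::labs(x = "time after stimulus (ms)", y = NULL,
                  title = "Pointwise biserial discriminability",
                  subtitle = if (length(sel))
                    paste("selected:", paste(sel, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-rsvpauth
#' @method autoplot hdca_model
#' @export
autoplot.hdca_model <- function(object, ...) {
  df <- tibble::tibble(window = seq_along(object$v), v = object$v)
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$v)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = df$window) +
    ggplot2::labs(x = "time window", y = expression(v[k]),
                  title = "HDCA temporal weights") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-rsvpauth
#' @method autoplot auth_cv
#' @export
autoplot.auth_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("acc", "far", "frr"),
                            names_to = "metric", values_to = "value")
  df$metric <- toupper(df$metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("%d x %d-fold authentication metrics",
                                  object$repeats, object$k)) +
    ggplot2::theme_minimal()
}

#' Compare self and non-self average ERPs
#'
#' Averages epochs by class on one channel and overlays the two waveforms —
#' the visual check that a subject's self-face contrast exists (user) or
#' not (scenario-1 imposter).
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel name or index (default "Cz").
#' @return A ggplot object.
#' @export
plot_erp_contrast <- function(epochs, channel = "Cz") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(channel)) channel <- match(channel, epochs$channel_names)
  t_ms <- (epochs$t0_s + (seq_len(dim(epochs$data)[3]) - 1) /
             epochs$rate_hz) * 1000
  avg <- function(rows) apply(epochs$data[rows, channel, , drop = FALSE],
                              3, mean)
  df <- tibble::tibble(
    time_ms = rep(t_ms, 2),
    uV = c(avg(which(epochs$labels$is_self)),
           avg(which(!epochs$labels$is_self))),
    class = rep(c("self-face", "non-self-face"), each = length(t_ms)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uV,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_colour_manual(values = c("self-face" = "#b2182b",
                                            "non-self-face" = "grey20")) +
    ggplot2::labs(x = "time after stimulus (ms)", y = expression(mu * V),
                  colour = NULL,
                  title = sprintf("Average ERPs at %s",
                                  epochs$channel_names[channel])) +
    ggplot2::theme_minimal()
}
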