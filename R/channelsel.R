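#' Pointwise biserial channel discriminability
#'
#' For every channel `i` and post-stimulus sample `n`, computes
#' \deqn{P_i(n) = \frac{\sqrt{N_1 N_2}}{N_1 + N_2}
#'   \cdot \frac{M_i^{SF}(n) - M_i^{NSF}(n)}{S(n)}}
#' where \eqn{N_1, N_2} are the self-face and non-self-face trial counts,
#' \eqn{M_i^{SF}, M_i^{NSF}} the class means, and \eqn{S(n)} the population
#' standard deviation (per channel and sample) over the union of both
#' classes. With the population denominator this is exactly the Pearson
#' correlation between the binary class indicator and the amplitude, so
#' every entry lies in \[-1, 1\]. Samples with \eqn{S(n) = 0} get
#' \eqn{P_i(n) = 0} and are counted as degenerate.
#'
#' @param epochs An `epoch_set` for one subject; both classes must have at
#'   least 2 epochs. Only post-stimulus samples (t >= 0) are scored.
#' @param epoch_subset Optional integer vector of epoch indices to use
#'   (e.g. the epochs of a training fold's trials).
#' @return A list of class `channel_map` with `P` (channels x samples
#'   matrix), `N1`, `N2`, `n_degenerate`, `channel_names`; `scores`,
#'   `selected` and `aggregate_mode` are filled by [rank_and_select()].
#' @export
pointwise_biserial <- function(epochs, epoch_subset = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- epoch_subset %||% seq_len(dim(epochs$data)[1])
  is_self <- epochs$labels$is_self[idx]
  N1 <- sum(is_self)
  N2 <- sum(!is_self)
  if (N1 < 2 || N2 < 2) {
    abort("need at least 2 epochs in each class",
          class = "rsvpauth_invalid_parameter")
  }
  post <- post_stimulus_index(epochs)
  C <- dim(epochs$data)[2]
  dat <- epochs$data[idx, , post, drop = FALSE]
  n_all <- length(idx)
  flat <- dat
  dim(flat) <- c(n_all, C * length(post))
  m1 <- colMeans(flat[is_self, , drop = FALSE])
  m2 <- colMeans(flat[!is_self, , drop = FALSE])
  mall <- (N1 * m1 + N2 * m2) / (N1 + N2)
  s_pop <- sqrt(pmax(colMeans(flat^2) - mall^2, 0))
  pref <- sqrt(N1 * N2) / (N1 + N2)
  P <- pref * (m1 - m2) / s_pop
  degen <- s_pop == 0
  P[degen] <- 0
  if (any(degen)) {
    inform(sprintf("%d degenerate (zero-variance) channel-sample points set to 0",
                   sum(degen)))
  }
  structure(list(P = matrix(P, nrow = C,
                            dimnames = list(epochs$channel_names, NULL)),
                 N1 = N1, N2 = N2, n_degenerate = sum(degen),
                 channel_names = epochs$channel_names,
                 scores = NULL, selected = NULL, aggregate_mode = NULL),
            class = "channel_map")
}

#' Rank channels and select the top k
#'
#' Aggregates each channel's pointwise biserial coefficients over the
#' post-stimulus samples and keeps the `k` highest-scoring channels
#' (default 6). The default aggregate is the sum of absolute values, which
#' does not let opposite-polarity ERP deflections cancel; `signed_sum` and
#' `square_sum` are available for a literal "sum of p values" reading. Ties
#' are broken toward the lower channel index.
#'
#' @param map A `channel_map` from [pointwise_biserial()].
#' @param k Number of channels to select (default 6).
#' @param aggregate_mode One of `"abs_sum"`, `"signed_sum"`, `"square_sum"`.
#' @return The `channel_map` with `scores` (tibble: channel, name, score,
#'   rank, selected), `selected` (integer indices ordered by descending
#'   score) and `aggregate_mode` filled in.
#' @export
rank_and_select <- function(map, k = 6,
                            aggregate_mode = c("abs_sum", "signed_sum",
                                               "square_sum")) {
  stopifnot(inherits(map, "channel_map"))
  aggregate_mode <- match.arg(aggregate_mode)
  C <- nrow(map$P)
  k <- check_count(k, "k")
  if (k > C) {
    abort(sprintf("k = %d exceeds the %d available channels", k, C),
          class = "rsvpauth_invalid_parameter")
  }
  f <- switch(aggregate_mode, abs_sum = abs, signed_sum = identity,
              square_sum = function(x) x^2)
  score <- rowSums(f(map$P))
  ord <- order(-score, seq_len(C))   # stable: ties to lower index
  map$scores <- tibble::tibble(
    channel = seq_len(C),
    name = map$channel_names,
    score = score,
    rank = match(seq_len(C), ord),
    selected = match(seq_len(C), ord) <= k
  )
  map$selected <- ord[seq_len(k)]
  map$aggregate_mode <- aggregate_mode
  map
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("<channel_map> %d channels x %d samples (N1 = %d, N2 = %d)\n",
              nrow(x$P), ncol(x$P), x$N1, x$N2))
  if (!is.null(x$selected)) {
    cat(sprintf("  selected (%s): %s\n", x$aggregate_mode,
                paste(x$channel_names[x$selected], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname tidy.hdca_model
#' @method tidy channel_map
#' @export
tidy.channel_map <- function(x, ...) {
  if (!is.null(x$scores)) return(x$scores)
  tibble::tibble(channel = seq_len(nrow(x$P)), name = x$channel_names)
}
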