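#' Low-pass filter specification
#'
#' Chebyshev Type I low-pass design used by the acquisition chain: passband
#' edge 40 Hz, stopband edge 49 Hz, 0.5 dB passband ripple, 40 dB stopband
#' attenuation, applied forward-backward (zero phase) so ERP latencies are
#' preserved. The filter order is the minimum meeting the specification at
#' the recording's sampling rate.
#'
#' @param passband_hz,stopband_hz Band edges in Hz (passband < stopband).
#' @param ripple_db Maximum passband ripple, dB.
#' @param atten_db Minimum stopband attenuation, dB.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(passband_hz = 40, stopband_hz = 49, ripple_db = 0.5,
                        atten_db = 40, zero_phase = TRUE) {
  check_positive(passband_hz, "passband_hz")
  check_positive(stopband_hz, "stopband_hz")
  if (passband_hz >= stopband_hz) {
    abort("passband_hz must be below stopband_hz",
          class = "rsvpauth_invalid_parameter")
  }
  structure(list(passband_hz = passband_hz, stopband_hz = stopband_hz,
                 ripple_db = ripple_db, atten_db = atten_db,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

# Chebyshev Type I low-pass design in zero-pole-gain form (analog
# prototype + bilinear transform with prewarping). The transfer-function
# polynomial form of this design is numerically ill-conditioned at the
# narrow normalized cutoffs used here (40 Hz at 2400 Hz), so the response
# is kept factored: poles, n zeros at z = -1, and a real gain.
design_cheby <- function(spec, rate_hz) {
  if (rate_hz <= 2 * spec$stopband_hz) {
    abort("sampling rate must exceed twice the stopband edge",
          class = "rsvpauth_invalid_parameter")
  }
  fs <- rate_hz
  # prewarped analog edge frequencies (rad/s)
  wp <- 2 * fs * tan(pi * spec$passband_hz / fs)
  ws <- 2 * fs * tan(pi * spec$stopband_hz / fs)
  eps2 <- 10^(spec$ripple_db / 10) - 1
  sel2 <- 10^(spec$atten_db / 10) - 1
  n <- ceiling(acosh(sqrt(sel2 / eps2)) / acosh(ws / wp))
  if (n > 40) {
    abort("filter order explosion; relax ripple_db or atten_db",
          class = "rsvpauth_filter_error")
  }
  # analog prototype poles (cutoff 1 rad/s)
  eps <- sqrt(eps2)
  mu <- asinh(1 / eps) / n
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  s <- complex(real = -sinh(mu) * sin(theta),
               imaginary = cosh(mu) * cos(theta))
  g <- Re(prod(-s))
  if (n %% 2 == 0) g <- g / sqrt(1 + eps2)
  # scale to the prewarped cutoff, then bilinear transform
  s <- s * wp
  g <- g * wp^n
  p <- (2 * fs + s) / (2 * fs - s)
  g <- Re(g * prod(1 / (2 * fs - s)))
  if (any(Mod(p) >= 1)) {
    abort("designed filter is unstable; relax ripple_db or atten_db",
          class = "rsvpauth_filter_error")
  }
  list(poles = p, n = n, gain = g, rate_hz = rate_hz, spec = spec)
}

# complex frequency response of the zpk design at digital frequencies
# (radians/sample); evaluated from the factored form, which stays accurate
# where the expanded polynomial coefficients would not
filter_response <- function(flt, w) {
  z <- exp(1i * w)
  h <- rep(complex(real = flt$gain), length(w))
  for (p in flt$poles) h <- h * (z + 1) / (z - p)
  h
}

# causal single pass as a cascade of biquads built from conjugate pole
# pairs (plus one real-pole section if the order is odd)
sos_filter <- function(flt, x) {
  p <- flt$poles[order(Im(flt$poles))]
  pairs <- list()
  used <- rep(FALSE, length(p))
  for (i in seq_along(p)) {
    if (used[i]) next
    j <- which(!used & abs(Conj(p) - p[i]) < 1e-9 & seq_along(p) != i)[1]
    if (is.na(j)) {
      pairs[[length(pairs) + 1]] <- p[i]
      used[i] <- TRUE
    } else {
      pairs[[length(pairs) + 1]] <- c(p[i], p[j])
      used[c(i, j)] <- TRUE
    }
  }
  y <- x * flt$gain
  for (pp in pairs) {
    if (length(pp) == 2L) {
      a1 <- -2 * Re(pp[1]); a2 <- Mod(pp[1])^2
      y <- y + c(0, 2 * y[-length(y)]) + c(0, 0, y[seq_len(length(y) - 2)])
      y <- as.numeric(stats::filter(y, c(-a1, -a2), method = "recursive"))
    } else {
      a1 <- -Re(pp[1])
      y <- y + c(0, y[-length(y)])
      y <- as.numeric(stats::filter(y, -a1, method = "recursive"))
    }
  }
  y
}

#' Low-pass filter a continuous recording
#'
#' Applies the Chebyshev Type I design of `spec` to every channel. With
#' `zero_phase = TRUE` the filter is applied forward and backward, giving
#' zero group delay and the squared magnitude response \eqn{|H(\omega)|^2};
#' the forward-backward pass is computed in the frequency domain (the
#' recordings here are long and have quiet ends, so wrap-around transients
#' are negligible). With `zero_phase = FALSE` the filter runs as a single
#' causal pass.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `eeg_recording`.
#' @export
lowpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  flt <- design_cheby(spec, rec$rate_hz)
  if (spec$zero_phase) {
    n <- ncol(rec$data)
    m <- stats::nextn(n, c(2, 3, 5))
    h2 <- Mod(filter_response(flt, 2 * pi * (0:(m - 1)) / m))^2
    pad <- numeric(m)
    for (i in seq_len(nrow(rec$data))) {   # channel-wise: bounded buffers
      pad[seq_len(n)] <- rec$data[i, ]
      rec$data[i, ] <- Re(fft(fft(pad) * h2, inverse = TRUE))[seq_len(n)] / m
    }
  } else {
    rec$data <- t(apply(rec$data, 1, function(x) sos_filter(flt, x)))
  }
  dimnames(rec$data) <- list(rec$channel_names, NULL)
  rec
}

#' Downsample by block averaging
#'
#' Output sample `m` is the mean of input samples
#' `[(m-1)*factor + 1, m*factor]`; trailing samples that do not fill a block
#' are dropped, and the sampling rate is divided by `factor`. The
#' acquisition chain uses `factor = 4` to go from 2400 Hz to 600 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param factor Positive integer decimation factor.
#' @return The decimated `eeg_recording`.
#' @examples
#' # downsample_by_averaging on c(1, 2, 3, 4) with factor 4 yields 2.5
#' @export
downsample_by_averaging <- function(rec, factor = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- check_count(factor, "factor")
  if (factor == 1L) return(rec)
  n_out <- floor(ncol(rec$data) / factor)
  if (n_out == 0L) {
    abort("recording shorter than one averaging block",
          class = "rsvpauth_invalid_parameter")
  }
  C <- nrow(rec$data)
  out <- matrix(0, nrow = C, ncol = n_out,
                dimnames = list(rec$channel_names, NULL))
  for (i in seq_len(C)) {
    x <- rec$data[i, seq_len(n_out * factor)]
    out[i, ] <- colMeans(matrix(x, nrow = factor))
  }
  rec$data <- out
  rec$rate_hz <- rec$rate_hz / factor
  rec
}

#' Extract baseline-corrected epochs around stimulus events
#'
#' Cuts one epoch per stimulus event on the half-open grid
#' `[t0_s, t1_s)` relative to onset (default -200 to 1000 ms: 720 samples at
#' 600 Hz, of which 600 are post-stimulus, the onset sample included) and
#' subtracts, per epoch and channel, the mean over the baseline interval
#' (default `[-200, 0)` ms). Events without enough data before or after
#' their onset are dropped with a message reporting the count. At a 300 ms
#' SOA consecutive epochs deliberately share underlying samples.
#'
#' @param rec An `eeg_recording`.
#' @param schedule Event table; defaults to the recording's own schedule.
#' @param t0_s,t1_s Epoch window relative to stimulus onset, seconds.
#' @param baseline Length-2 interval `[b0, b1)` used for baseline
#'   correction, seconds; `NULL` to skip correction.
#' @return A list of class `epoch_set`: `data` (epochs x channels x samples
#'   array, µV), `rate_hz`, `t0_s`, `labels` (tibble: epoch, block, trial,
#'   position, image_id, is_self, subject_id, role, session), `channel_names`,
#'   `n_dropped`.
#' @export
extract_epochs <- function(rec, schedule = NULL, t0_s = -0.2, t1_s = 1.0,
                           baseline = c(-0.2, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  schedule <- schedule %||% rec$schedule
  if (is.null(schedule) || nrow(schedule) == 0) {
    abort("no events to epoch", class = "rsvpauth_invalid_parameter")
  }
  rate <- rec$rate_hz
  i0 <- round(t0_s * rate)
  i1 <- round(t1_s * rate) - 1L
  rel <- i0:i1
  n_s <- length(rel)
  n_total <- ncol(rec$data)

  onset_idx <- round(schedule$onset_s * rate) + 1L
  ok <- (onset_idx + i0) >= 1L & (onset_idx + i1) <= n_total
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d event(s) without enough surrounding data",
                   n_dropped))
  }
  if (!any(ok)) {
    abort("no events have enough surrounding data to epoch",
          class = "rsvpauth_epoching_error")
  }
  keep <- which(ok)
  C <- nrow(rec$data)
  n_e <- length(keep)
  arr <- array(0, dim = c(n_e, C, n_s))
  for (e in seq_len(n_e)) {
    # rel is contiguous, so each epoch is one contiguous column block
    arr[e, , ] <- rec$data[, onset_idx[keep[e]] + rel]
  }

  if (!is.null(baseline)) {
    b_rel <- round(baseline[1] * rate):(round(baseline[2] * rate) - 1L)
    b_pos <- match(b_rel, rel)
    if (anyNA(b_pos)) {
      abort("baseline interval must lie within the epoch window",
            class = "rsvpauth_invalid_parameter")
    }
    bl <- rowMeans(arr[, , b_pos, drop = FALSE], dims = 2)
    arr <- arr - array(bl, dim = dim(arr))   # recycles over samples
  }

  labels <- tibble::as_tibble(schedule)[keep,
    c("block", "trial", "position", "image_id", "is_self")]
  labels <- tibble::add_column(labels, epoch = seq_along(keep), .before = 1)
  labels$subject_id <- rec$profile_id %||% NA_character_
  labels$role <- rec$role %||% NA_character_
  labels$session <- rec$session %||% 1L

  structure(list(data = arr, rate_hz = rate, t0_s = t0_s, labels = labels,
                 channel_names = rec$channel_names, n_dropped = n_dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              d[1], d[2], d[3], x$rate_hz, x$t0_s))
  cat(sprintf("  self: %d, non-self: %d; dropped at epoching: %d\n",
              sum(x$labels$is_self), sum(!x$labels$is_self), x$n_dropped))
  invisible(x)
}

#' Post-stimulus sample positions of an epoch set
#'
#' Indices (into the epoch's sample axis) of the samples at or after
#' stimulus onset — the 600 samples scored by channel selection and
#' classification under the default window.
#'
#' @param epochs An `epoch_set`.
#' @return Integer vector of sample positions.
#' @export
post_stimulus_index <- function(epochs) {
  n_s <- dim(epochs$data)[3]
  rel <- round(epochs$t0_s * epochs$rate_hz) + seq_len(n_s) - 1L
  which(rel >= 0L)
}

#' Average adjacent trials
#'
#' Averages non-overlapping consecutive pairs (1,2), (3,4), ... of per-trial
#' features elementwise, halving the count: 200 single trials become 100
#' averaged trials, so one authentication unit spans two trials (6 s of
#' stimulation). An odd trailing trial is dropped with a warning.
#'
#' @param features A `trial_features` object (see [build_trial_features()]).
#' @return A `trial_features` object with half as many rows; the `meta`
#'   tibble records which source trials entered each average.
#' @export
average_adjacent_trials <- function(features) {
  stopifnot(inherits(features, "trial_features"))
  n <- dim(features$data)[1]
  if (n < 2) {
    abort("need at least 2 trials to pair-average",
          class = "rsvpauth_invalid_parameter")
  }
  if (n %% 2 == 1) {
    warn(sprintf("odd trial count (%d): dropping the last trial", n))
    n <- n - 1L
  }
  first <- seq(1L, n, by = 2L)
  out <- (features$data[first, , , drop = FALSE] +
            features$data[first + 1L, , , drop = FALSE]) / 2
  meta <- tibble::tibble(
    unit = seq_along(first),
    trials = purrr::map(seq_along(first), function(j) {
      c(features$meta$trials[[first[j]]], features$meta$trials[[first[j] + 1L]])
    })
  )
  features$data <- out
  features$meta <- meta
  features$pair_averaged <- TRUE
  features
}
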