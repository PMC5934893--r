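#' 1/f ("pink") noise generator
#'
#' Spectrally shaped Gaussian noise with power spectral density proportional
#' to 1/f between `f_lo` and the Nyquist frequency — the simplest process
#' with an EEG-like spectrum. The RMS is specified at a fixed reference
#' bandwidth (`reference_hz`, default the 1200 Hz Nyquist of the 2400 Hz
#' acquisition rate) so that the same physical process is realized whatever
#' rate the simulation runs at: a recording simulated below the reference
#' rate carries only the spectral portion below its own Nyquist, exactly as
#' an acquired-then-decimated recording would.
#'
#' @param n Number of samples.
#' @param rms Root-mean-square amplitude over the full reference bandwidth.
#' @param rate_hz Sampling rate of the generated stream.
#' @param reference_hz Reference bandwidth over which `rms` is defined.
#' @param f_lo Low-frequency cutoff of the 1/f regime, Hz (density is
#'   flat below it).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, rms = 1, rate_hz = 2 * reference_hz,
                       reference_hz = 1200, f_lo = 0.1) {
  x <- pink_noise_matrix(n, 1, rms, rate_hz, reference_hz, f_lo)
  x[, 1]
}

# pink noise for C independent channels, one channel at a time to keep the
# transient FFT buffers small on long acquisition-rate recordings
pink_noise_matrix <- function(n, C, rms, rate_hz, reference_hz = 1200,
                              f_lo = 0.1) {
  if (n < 2) return(matrix(rnorm(n * C, 0, rms), n, C))
  nyq <- rate_hz / 2
  m <- stats::nextn(n, c(2, 3, 5))   # composite FFT length, then truncate
  f <- pmin(0:(m - 1), m - (0:(m - 1))) * (rate_hz / m)  # two-sided |freq|
  shape <- 1 / pmax(f, f_lo)          # 1/f density, flat below f_lo
  shape[1] <- 0                       # no DC
  amp <- sqrt(shape)
  # calibrate: variance carried below this Nyquist as a fraction of the
  # variance over the reference band [f_lo, reference_hz]
  var_ref <- log(reference_hz / f_lo) + 1   # integral of density shape
  var_here <- log(pmin(nyq, reference_hz) / f_lo) + 1
  target_var <- rms^2 * var_here / var_ref
  X <- matrix(0, n, C)
  ss <- 0
  for (j in seq_len(C)) {
    spec <- fft(rnorm(m))
    x <- Re(fft(spec * amp, inverse = TRUE))[seq_len(n)] / m
    ss <- ss + sum(x^2)
    X[, j] <- x
  }
  s2 <- ss / (n * C)
  if (s2 == 0) return(X)
  X * sqrt(target_var / s2)
}

# linear convolution via zero-padded FFT at a 2-3-5-composite length;
# y[k] = sum_j a[j] b[k - j + 1], length n_a + n_b - 1
fft_convolve <- function(a, b) {
  n_out <- length(a) + length(b) - 1L
  m <- stats::nextn(n_out, c(2, 3, 5))
  fa <- fft(c(a, numeric(m - length(a))))
  fb <- fft(c(b, numeric(m - length(b))))
  Re(fft(fa * fb, inverse = TRUE))[seq_len(n_out)] / m
}

# evaluate one component's waveform on the sample grid relative to stimulus
# onset; support truncated at +/- 4 envelope SDs
component_wave <- function(comp, rate_hz) {
  i0 <- floor((comp$latency_s - 4 * comp$width_s) * rate_hz)
  i1 <- ceiling((comp$latency_s + 4 * comp$width_s) * rate_hz)
  idx <- i0:i1
  t <- idx / rate_hz
  list(offsets = idx,
       wave = comp$amplitude_uV *
         exp(-0.5 * ((t - comp$latency_s) / comp$width_s)^2))
}

#' Simulate a continuous multi-channel EEG recording
#'
#' Produces the linear superposition, over all stimulus events of `schedule`,
#' of the profile's ERP component waveforms (Gaussian envelope x amplitude x
#' topography). Components in `common_components` are evoked by every image;
#' `self_contrast_components` are added only on self-face events. Responses
#' of successive images at the 300 ms SOA overlap additively. Per-channel
#' 1/f and white noise are added on top. The schedule is shifted by
#' `lead_in_s` so that every event has pre-stimulus baseline data; the
#' shifted schedule is stored in the returned recording.
#'
#' @param profile A [make_subject_profile()] object.
#' @param schedule An [generate_schedule()] schedule.
#' @param rate_hz Sampling rate (default 2400 Hz, the acquisition rate).
#' @param seed Integer seed for the noise streams.
#' @param session Session label stored with the recording (1 or 2).
#' @param lead_in_s Quiet lead-in before the first stimulus, seconds.
#' @param duration_s Optional total duration; if too short for the schedule
#'   plus 1.5 s tail it is auto-extended with a warning.
#' @return A list of class `eeg_recording` with elements `data`
#'   (channels x samples matrix, µV), `rate_hz`, `channel_names`, `schedule`
#'   (onsets relative to recording start), `profile_id`, `role`, `session`.
#' @examples
#' sched <- generate_schedule(n_blocks = 1, seed = 1)
#' prof <- make_subject_profile("user", seed = 1)
#' rec <- simulate_recording(prof, sched, rate_hz = 600, seed = 1)
#' dim(rec$data)
#' @export
simulate_recording <- function(profile, schedule, rate_hz = 2400, seed = 1L,
                               session = 1L, lead_in_s = 2.0,
                               duration_s = NULL) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(schedule, "rsvp_schedule"))
  check_positive(rate_hz, "rate_hz")
  if (nrow(schedule) == 0) {
    abort("schedule is empty", class = "rsvpauth_invalid_parameter")
  }
  seed <- check_count(seed, "seed", min = 0L)

  sched <- shift_schedule(schedule, lead_in_s)
  needed_s <- max(sched$onset_s) + 1.5
  if (is.null(duration_s)) {
    duration_s <- needed_s
  } else if (duration_s < needed_s) {
    warn(sprintf("duration_s = %.2f too short for schedule; extended to %.2f s",
                 duration_s, needed_s))
    duration_s <- needed_s
  }
  n <- ceiling(duration_s * rate_hz)
  ch <- profile$montage
  C <- length(ch)
  data <- matrix(0, nrow = C, ncol = n, dimnames = list(ch, NULL))

  add_component <- function(comp, onsets) {
    cw <- component_wave(comp, rate_hz)
    topo <- comp$topography
    on_ch <- which(topo != 0)
    # superpose via one FFT convolution of the onset impulse train with the
    # component waveform; y[d - i0] is the summed waveform at sample d
    imp <- numeric(n)
    s0 <- round(onsets * rate_hz) + 1L      # sample index at t = 0
    s0 <- s0[s0 >= 1L & s0 <= n]
    imp[s0] <- imp[s0] + 1
    y <- fft_convolve(imp, cw$wave)
    i0 <- cw$offsets[1]
    d <- seq_len(n)
    k <- d - i0
    ok <- k >= 1L & k <= length(y)
    sig <- numeric(n)
    sig[d[ok]] <- y[k[ok]]
    data[on_ch, ] <<- data[on_ch, ] + outer(topo[on_ch], sig)
  }

  for (comp in profile$common_components) add_component(comp, sched$onset_s)
  self_onsets <- sched$onset_s[sched$is_self]
  for (comp in profile$self_contrast_components) add_component(comp, self_onsets)

  # noise RMS values are defined over the 1200 Hz acquisition bandwidth;
  # at lower simulation rates only the in-band portion is realized, so the
  # same profile yields the same post-filter noise whatever rate is used
  ref_hz <- 1200
  band <- min(rate_hz / 2, ref_hz) / ref_hz
  with_seed_local(derive_seed(seed, 91L + session), {
    if (profile$noise_pink_uV > 0) {
      X <- pink_noise_matrix(n, C, profile$noise_pink_uV, rate_hz, ref_hz)
      for (j in seq_len(C)) data[j, ] <- data[j, ] + X[, j]
      rm(X)
    }
    if (profile$noise_white_uV > 0) {
      sd_w <- profile$noise_white_uV * sqrt(band)
      for (j in seq_len(C)) data[j, ] <- data[j, ] + rnorm(n, 0, sd_w)
    }
  })

  structure(list(data = data, rate_hz = rate_hz, channel_names = ch,
                 schedule = sched, profile_id = profile$subject_id,
                 role = profile$role, session = as.integer(session)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (role %s, session %d)\n",
              x$profile_id %||% "?", x$role %||% "?", x$session %||% 1L))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  cat(sprintf("  %d stimulus events\n",
              if (is.null(x$schedule)) 0L else nrow(x$schedule)))
  invisible(x)
}
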