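#' Run the acquisition signal chain on a continuous recording
#'
#' Applies the standard preprocessing order — low-pass filter, downsample by
#' block averaging, epoch with baseline correction — and returns the epoch
#' set. The order is fixed; pass `spec = NULL` to skip filtering (e.g. for
#' recordings simulated directly at the analysis rate, which are
#' band-limited by construction) and `factor = 1` to skip decimation.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()] or `NULL`.
#' @param factor Decimation factor (default chosen to reach `target_hz`).
#' @param target_hz Analysis rate the default `factor` aims for (600 Hz).
#' @param t0_s,t1_s,baseline Epoching window, see [extract_epochs()].
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(), factor = NULL,
                                 target_hz = 600, t0_s = -0.2, t1_s = 1.0,
                                 baseline = c(-0.2, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- factor %||% max(1L, round(rec$rate_hz / target_hz))
  if (!is.null(spec)) rec <- lowpass_filter(rec, spec)
  rec <- downsample_by_averaging(rec, factor)
  extract_epochs(rec, t0_s = t0_s, t1_s = t1_s, baseline = baseline)
}

#' Pair-averaged contrast features for one subject
#'
#' Convenience wrapper: build per-trial features from an epoch set and
#' average adjacent trials, yielding the authentication units (100 units
#' from the default 200-trial session).
#'
#' @param epochs An `epoch_set`.
#' @param channels Optional channel subset (indices or names).
#' @param mode Feature construction mode, see [build_trial_features()].
#' @return A pair-averaged `trial_features` object.
#' @export
subject_features <- function(epochs, channels = NULL,
                             mode = "self_minus_nonself_mean") {
  average_adjacent_trials(build_trial_features(epochs, channels = channels,
                                               mode = mode))
}

#' Simulate and preprocess a full subject session
#'
#' One call from profile to analysis-ready epochs: simulate the continuous
#' recording for a schedule, then run the signal chain. When the recording
#' is simulated directly at `target_hz` the filter and decimation are
#' skipped (the simulator output is band-limited below the passband edge).
#'
#' @param profile A `subject_profile`.
#' @param schedule An `rsvp_schedule`.
#' @param rate_hz Acquisition rate (default 2400; use 600 to simulate at
#'   the analysis rate directly).
#' @param seed Noise seed.
#' @param session Session id (1 or 2).
#' @param target_hz Analysis rate (default 600).
#' @return An `epoch_set`.
#' @details The 40/49 Hz low-pass is applied at whatever rate the recording
#'   was simulated, so a recording simulated directly at the analysis rate
#'   passes through the same noise-rejecting filter as one simulated at the
#'   acquisition rate and decimated; only the decimation step drops out.
#' @export
simulate_session_epochs <- function(profile, schedule, rate_hz = 2400,
                                    seed = 1L, session = 1L,
                                    target_hz = 600) {
  rec <- simulate_recording(profile, schedule, rate_hz = rate_hz,
                            seed = seed, session = session)
  preprocess_recording(rec, target_hz = target_hz)
}
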