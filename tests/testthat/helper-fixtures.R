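# shared fixtures: all built in code at test time
suppressPackageStartupMessages(library(dplyr))
`%||%` <- rlang::`%||%`

montage16 <- default_montage()
truth_channels <- c("Cz", "Pz", "P3", "P4", "C4")

# a profile assembled by hand, for tests needing exact control
manual_profile <- function(common = list(), contrast = list(),
                           pink = 0, white = 0, role = "user",
                           id = "manual") {
  structure(list(subject_id = id, role = role,
                 common_components = common,
                 self_contrast_components = contrast,
                 noise_pink_uV = pink, noise_white_uV = white,
                 montage = montage16, seed = 0L),
            class = "subject_profile")
}

quiet_profile <- function(role = "user", seed = 1L, ...) {
  make_subject_profile(role, seed = seed,
                       config = profile_config(noise_pink_uV = 0,
                                               noise_white_uV = 0, ...))
}

# bare continuous recording around a data matrix
manual_recording <- function(data, rate_hz, schedule = NULL,
                             channel_names = NULL) {
  data <- rbind(data)
  channel_names <- channel_names %||%
    paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channel_names
  structure(list(data = data, rate_hz = rate_hz,
                 channel_names = channel_names, schedule = schedule,
                 profile_id = "manual", role = "user", session = 1L),
            class = "eeg_recording")
}

# epoch_set wrapped around an epochs x channels x samples array; t0_s = 0
# makes every sample post-stimulus
manual_epochs <- function(arr, is_self, rate_hz = 100, t0_s = 0,
                          block = NULL, trial = NULL) {
  n <- dim(arr)[1]
  labels <- tibble::tibble(
    epoch = seq_len(n),
    block = block %||% rep(1L, n),
    trial = trial %||% seq_len(n),
    position = rep(0L, n),
    image_id = seq_len(n),
    is_self = is_self,
    subject_id = "manual", role = "user", session = 1L)
  structure(list(data = arr, rate_hz = rate_hz, t0_s = t0_s,
                 labels = labels,
                 channel_names = paste0("ch", seq_len(dim(arr)[2])),
                 n_dropped = 0L),
            class = "epoch_set")
}

# trial_features around an array, one source trial per row
manual_features <- function(arr, rate_hz = 600) {
  structure(list(data = arr,
                 meta = tibble::tibble(unit = seq_len(dim(arr)[1]),
                                       trials = as.list(seq_len(dim(arr)[1]))),
                 channel_names = paste0("ch", seq_len(dim(arr)[2])),
                 rate_hz = rate_hz, mode = "self_minus_nonself_mean",
                 pair_averaged = TRUE),
            class = "trial_features")
}

# Gaussian two-class features: user class mean-shifted on given channels
# over a sample range
gaussian_features <- function(n_per_class, C = 4, S = 60, shift = 1,
                              shift_channels = 1, shift_samples = NULL,
                              sd = 1, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(2 * n_per_class * C * S, 0, sd),
                 dim = c(2 * n_per_class, C, S))
    shift_samples <- shift_samples %||% seq_len(S)
    arr[seq_len(n_per_class), shift_channels, shift_samples] <-
      arr[seq_len(n_per_class), shift_channels, shift_samples] + shift
    list(user = manual_features(arr[seq_len(n_per_class), , , drop = FALSE]),
         imposter = manual_features(arr[n_per_class + seq_len(n_per_class), , ,
                                        drop = FALSE]),
         labels = rep(c(TRUE, FALSE), each = n_per_class),
         all = arr)
  })
}

# analytic component waveform on the post-stimulus sample grid, with the
# generator's +/- 4 SD support truncation (index-based, same convention)
analytic_wave <- function(comp, rate_hz, n_samples) {
  idx <- seq_len(n_samples) - 1
  w <- comp$amplitude_uV *
    exp(-0.5 * ((idx / rate_hz - comp$latency_s) / comp$width_s)^2)
  i0 <- floor((comp$latency_s - 4 * comp$width_s) * rate_hz)
  i1 <- ceiling((comp$latency_s + 4 * comp$width_s) * rate_hz)
  w[idx < i0 | idx > i1] <- 0
  w
}
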