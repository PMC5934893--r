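#' Define an ERP component
#'
#' A monophasic deflection with a Gaussian temporal envelope: amplitude
#' (microvolts, signed), peak latency (seconds post-stimulus), envelope SD
#' (seconds) and a 16-channel topography of gains in \[-1, 1\]. Gaussian
#' envelopes keep every downstream quantity analytically computable.
#'
#' @param name Component label.
#' @param amplitude_uV Peak amplitude in microvolts (signed; negative for
#'   N-type deflections).
#' @param latency_s Peak latency after stimulus onset, seconds.
#' @param width_s Gaussian envelope standard deviation, seconds (> 0).
#' @param topography Numeric vector of per-channel gains, one per montage
#'   channel, at least one nonzero.
#' @return A list of class `erp_component`.
#' @export
erp_component <- function(name, amplitude_uV, latency_s, width_s, topography) {
  check_positive(width_s, "width_s")
  if (!any(topography != 0)) {
    abort("`topography` must have at least one nonzero entry",
          class = "rsvpauth_invalid_parameter")
  }
  structure(list(name = name, amplitude_uV = amplitude_uV,
                 latency_s = latency_s, width_s = width_s,
                 topography = topography),
            class = "erp_component")
}

#' Generator settings for subject profiles
#'
#' Defaults parameterize the qualitative structure of self-face RSVP ERPs:
#' a subject-specific N250-like self/non-self contrast with latency drawn
#' uniformly on 0.20--0.45 s, peak magnitude 2--8 µV and a centro-parietal
#' topography (Cz, Pz, P3, P4, C4), riding on face-evoked components common
#' to all images (P1-like and N170-like), plus 1/f and white noise whose RMS
#' amplitudes (8 and 4 µV) are typical of band-limited single-trial scalp
#' EEG.
#'
#' @param latency_range,amplitude_range,width_range Uniform draw ranges for
#'   the self-contrast component (seconds / microvolts / seconds).
#' @param contrast_channels Channels carrying the self contrast.
#' @param gain_range Uniform range of per-channel topography gains on
#'   `contrast_channels`.
#' @param noise_pink_uV,noise_white_uV RMS of the 1/f and white noise, µV.
#' @param min_latency_sep Minimum latency separation enforced between a
#'   scenario-2 imposter's contrast and the paired user's, seconds.
#' @param montage Channel labels (defines topography length).
#' @return A list of generator settings.
#' @export
profile_config <- function(latency_range = c(0.20, 0.45),
                           amplitude_range = c(2, 8),
                           width_range = c(0.04, 0.07),
                           contrast_channels = c("Cz", "Pz", "P3", "P4", "C4"),
                           gain_range = c(0.5, 1),
                           noise_pink_uV = 8, noise_white_uV = 4,
                           min_latency_sep = 0.10,
                           montage = default_montage()) {
  list(latency_range = latency_range, amplitude_range = amplitude_range,
       width_range = width_range, contrast_channels = contrast_channels,
       gain_range = gain_range, noise_pink_uV = noise_pink_uV,
       noise_white_uV = noise_white_uV, min_latency_sep = min_latency_sep,
       montage = montage)
}

# topography helper: gains on `on` channels, zero elsewhere
topo_on <- function(montage, on, gains) {
  v <- setNames(numeric(length(montage)), montage)
  v[on] <- gains
  v
}

# face-evoked components shared by self and non-self images; small
# per-subject amplitude jitter so subjects are not clones
draw_common_components <- function(config) {
  m <- config$montage
  occ <- c("Oz", "Po7", "Po8")
  par <- c("Pz", "P3", "P4", "Cz")
  j <- runif(2, 0.8, 1.2)
  list(
    erp_component("P1-like", amplitude_uV = 3 * j[1], latency_s = 0.10,
                  width_s = 0.030,
                  topography = topo_on(m, occ, c(1, 0.8, 0.8))),
    erp_component("N170-like", amplitude_uV = -4 * j[2], latency_s = 0.17,
                  width_s = 0.035,
                  topography = topo_on(m, c(occ, par),
                                       c(0.9, 1, 1, 0.4, 0.3, 0.3, 0.3)))
  )
}

draw_contrast_component <- function(config, avoid_latency = NULL) {
  lat <- runif(1, config$latency_range[1], config$latency_range[2])
  if (!is.null(avoid_latency)) {
    # rejection sampling against the paired user's latency; bounded because
    # min_latency_sep is well below the range width
    tries <- 0L
    while (abs(lat - avoid_latency) < config$min_latency_sep) {
      lat <- runif(1, config$latency_range[1], config$latency_range[2])
      tries <- tries + 1L
      if (tries > 1000L) {
        abort("cannot separate imposter latency from user latency; widen latency_range or lower min_latency_sep",
              class = "rsvpauth_invalid_parameter")
      }
    }
  }
  amp <- -runif(1, config$amplitude_range[1], config$amplitude_range[2])
  wid <- runif(1, config$width_range[1], config$width_range[2])
  gains <- runif(length(config$contrast_channels),
                 config$gain_range[1], config$gain_range[2])
  erp_component("self-N250-like", amplitude_uV = amp, latency_s = lat,
                width_s = wid,
                topography = topo_on(config$montage,
                                     config$contrast_channels, gains))
}

#' Draw a subject profile for the simulator
#'
#' Creates the latent description of one participant: ERP components evoked
#' by every face image (`common_components`), the subject-specific
#' self-vs-non-self contrast (`self_contrast_components`), and noise levels.
#' Roles encode the authentication scenarios:
#' * `user` — attends to their own face; has a self contrast.
#' * `imposter_scenario1` — views the user's stimulus inattentively; no
#'   self/non-self contrast at all.
#' * `imposter_scenario2` — imitates the user's strategy, so a contrast
#'   exists, but its latency is kept at least `min_latency_sep` away from the
#'   paired user's and its amplitude and topography are drawn independently.
#'
#' @param role One of `"user"`, `"imposter_scenario1"`, `"imposter_scenario2"`.
#' @param seed Integer seed; profiles are deterministic in (role, seed,
#'   config, paired_user).
#' @param config Generator settings from [profile_config()].
#' @param paired_user For `imposter_scenario2`, the user profile being
#'   attacked (enforces the separation floor).
#' @param subject_id Optional label (default derived from role and seed).
#' @return A list of class `subject_profile`.
#' @examples
#' u <- make_subject_profile("user", seed = 7)
#' i1 <- make_subject_profile("imposter_scenario1", seed = 8)
#' length(i1$self_contrast_components)  # 0
#' @export
make_subject_profile <- function(role = c("user", "imposter_scenario1",
                                          "imposter_scenario2"),
                                 seed = 1L, config = profile_config(),
                                 paired_user = NULL, subject_id = NULL) {
  role <- tryCatch(match.arg(role),
                   error = function(e) abort(
                     sprintf("unknown role '%s'", paste(role, collapse = "/")),
                     class = "rsvpauth_invalid_parameter"))
  seed <- check_count(seed, "seed", min = 0L)
  if (role == "imposter_scenario2" && !is.null(paired_user) &&
      !inherits(paired_user, "subject_profile")) {
    abort("`paired_user` must be a subject_profile",
          class = "rsvpauth_invalid_parameter")
  }
  prof <- with_seed_local(derive_seed(seed, 577L), {
    common <- draw_common_components(config)
    contrast <- switch(
      role,
      user = list(draw_contrast_component(config)),
      imposter_scenario1 = list(),
      imposter_scenario2 = list(draw_contrast_component(
        config,
        avoid_latency = if (!is.null(paired_user))
          paired_user$self_contrast_components[[1]]$latency_s))
    )
    list(common = common, contrast = contrast)
  })
  structure(list(
    subject_id = subject_id %||% sprintf("%s_s%d", role, seed),
    role = role,
    common_components = prof$common,
    self_contrast_components = prof$contrast,
    noise_pink_uV = config$noise_pink_uV,
    noise_white_uV = config$noise_white_uV,
    montage = config$montage,
    seed = seed
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s (role: %s)\n", x$subject_id, x$role))
  cat(sprintf("  common components: %s\n",
              paste(vapply(x$common_components, `[[`, "", "name"),
                    collapse = ", ")))
  if (length(x$self_contrast_components)) {
    ct <- x$self_contrast_components[[1]]
    cat(sprintf("  self contrast: %.1f uV at %.0f ms (width %.0f ms) on %s\n",
                ct$amplitude_uV, 1000 * ct$latency_s, 1000 * ct$width_s,
                paste(names(ct$topography)[ct$topography != 0],
                      collapse = ",")))
  } else {
    cat("  self contrast: none\n")
  }
  cat(sprintf("  noise: pink %.1f uV + white %.1f uV RMS\n",
              x$noise_pink_uV, x$noise_white_uV))
  invisible(x)
}
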