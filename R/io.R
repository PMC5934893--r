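# versioned on-disk containers for epochs, models and metrics

EPOCHS_FORMAT_VERSION <- 1L
MODEL_FORMAT_VERSION <- 1L

#' Store and load epoch sets
#'
#' Epochs are written as a self-describing versioned container (RDS payload
#' holding the data array, labels table, timebase and channel names) and
#' round-trip losslessly at full float precision.
#'
#' @param epochs An `epoch_set`.
#' @param path File path (conventionally `.rds`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns the `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(list(format = "rsvpauth_epochs",
               format_version = EPOCHS_FORMAT_VERSION,
               data = epochs$data, rate_hz = epochs$rate_hz,
               t0_s = epochs$t0_s, labels = epochs$labels,
               channel_names = epochs$channel_names,
               n_dropped = epochs$n_dropped),
          path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "rsvpauth_epochs") ||
      !identical(x$format_version, EPOCHS_FORMAT_VERSION)) {
    abort(sprintf("incompatible epochs container (format %s v%s; expected v%d)",
                  x$format %||% "?", x$format_version %||% "?",
                  EPOCHS_FORMAT_VERSION),
          class = "rsvpauth_format_version_error")
  }
  structure(x[c("data", "rate_hz", "t0_s", "labels", "channel_names",
                "n_dropped")],
            class = "epoch_set")
}

#' Store and load trained model bundles
#'
#' A model bundle (selected channels, HDCA weights, preprocessing
#' fingerprint and training metadata) is written as a versioned container;
#' loading a container with a different format version raises an explicit
#' incompatibility error.
#'
#' @param bundle A `model_bundle` from [train_authenticator()].
#' @param path File path (conventionally `.rds`).
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   `model_bundle`.
#' @export
write_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(list(format = "rsvpauth_model",
               format_version = MODEL_FORMAT_VERSION,
               bundle = unclass(bundle)),
          path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "rsvpauth_model") ||
      !identical(x$format_version, MODEL_FORMAT_VERSION)) {
    abort(sprintf("incompatible model container (format %s v%s; expected v%d)",
                  x$format %||% "?", x$format_version %||% "?",
                  MODEL_FORMAT_VERSION),
          class = "rsvpauth_format_version_error")
  }
  structure(x$bundle, class = "model_bundle")
}

#' Write an authentication metrics table to CSV
#'
#' One row per (user, scenario, fold/repeat or aggregate); the column set
#' must include `user`, `scenario`, `acc`, `far`, `frr`. Writing is
#' deterministic given identical inputs (no timestamps in the payload).
#'
#' @param metrics A tibble of metrics (e.g. from [scenario_report()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  req <- c("user", "scenario", "acc", "far", "frr")
  missing <- setdiff(req, names(metrics))
  if (length(missing)) {
    abort(sprintf("metrics table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "rsvpauth_invalid_parameter")
  }
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}
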