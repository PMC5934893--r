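# Minimal EDF (European Data Format) continuous-recording support.
# Implements the fixed-layout 16-bit EDF subset this package needs: one
# recording, all signals at one sampling rate, physical dimension uV.
# Layout: 256-byte fixed header, 256 bytes of signal header per signal
# (transposed field-wise), then data records of 2-byte little-endian
# integers, signal-major within each record.

edf_pad <- function(x, width) {
  x <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a continuous recording to an EDF file
#'
#' Stores all channels as 16-bit EDF signals with physical dimension uV.
#' Per-channel physical min/max are taken from the data range, so the
#' round-trip error is bounded by half a quantization step
#' (range / 65535 / 2 per channel). The stimulus events are not part of
#' EDF; write them separately with [write_events()].
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param record_duration_s Duration of one EDF data record (default 1 s).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- round(rec$rate_hz * record_duration_s)   # samples per record/signal
  if (spr < 1) abort("record_duration_s too short for the sampling rate",
                     class = "rsvpauth_invalid_parameter")
  n_rec <- ceiling(ncol(rec$data) / spr)
  n_pad <- n_rec * spr - ncol(rec$data)
  data <- cbind(rec$data, matrix(0, ns, n_pad))

  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin == 0
  pmax[flat] <- pmin[flat] + 1          # avoid zero physical range
  # physical min/max live in 8 ASCII characters; round outward so the
  # stored range still covers the data
  fmt8 <- function(x) {
    for (d in 7:1) {
      s <- trimws(formatC(x, digits = d, format = "g"))
      if (nchar(s) <= 8) return(s)
    }
    stop("physical range not representable in EDF header")
  }
  rng <- pmax - pmin
  pmin_s <- character(ns); pmax_s <- character(ns)
  for (i in seq_len(ns)) {
    lo <- pmin[i] - 1e-5 * rng[i]
    repeat {
      pmin_s[i] <- fmt8(lo)
      if (as.numeric(pmin_s[i]) <= pmin[i]) break
      lo <- lo - 1e-3 * rng[i]
    }
    hi <- pmax[i] + 1e-5 * rng[i]
    repeat {
      pmax_s[i] <- fmt8(hi)
      if (as.numeric(pmax_s[i]) >= pmax[i]) break
      hi <- hi + 1e-3 * rng[i]
    }
  }
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                                     # version
    edf_pad(paste("subject", rec$profile_id %||% "X"), 80),
    edf_pad(paste("recording session", rec$session %||% 1L), 80),
    "01.01.00", "00.00.00",                              # fixed date/time:
                                                         # payload stays
                                                         # deterministic
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(record_duration_s), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_names, 16)                           # label
  field(rep("", ns), 80)                                 # transducer
  field(rep("uV", ns), 8)                                # physical dimension
  field(pmin_s, 8)
  field(pmax_s, 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                                 # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                                 # reserved

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    block <- round((data[, cols, drop = FALSE] - pmin) * scale + dmin)
    block <- pmin(pmax(block, dmin), dmax)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a continuous recording
#'
#' Reads the EDF subset written by [write_edf()] (one sampling rate across
#' signals). Physical units are converted to microvolts; signals stored in
#' mV or V are rescaled, other dimensions raise an error. If `events_path`
#' is given the event table is attached as the recording's schedule after
#' validating that all onsets fall inside the recording.
#'
#' @param path EDF file path.
#' @param events_path Optional events TSV path (see [read_events()]).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, events_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8)                    # version
  rd(80); rd(80)           # patient / recording ids
  rd(8); rd(8)             # date / time
  rd(8)                    # header bytes
  rd(44)                   # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns < 1) abort("EDF file has no signals",
                    class = "rsvpauth_unsupported_format")
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16)
  fld(80)
  dims <- fld(8)
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1L) {
    abort("mixed per-signal sampling rates are not supported",
          class = "rsvpauth_unsupported_format")
  }
  to_uv <- vapply(dims, function(d) switch(tolower(d),
    "uv" = 1, "mv" = 1e3, "v" = 1e6,
    abort(sprintf("unsupported physical dimension '%s'", d),
          class = "rsvpauth_unsupported_format")), numeric(1))

  rate_hz <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])        # samples x signals
    phys <- t(block) * scale + (pmin - dmin * scale)
    data[, (r - 1L) * spr[1] + seq_len(spr[1])] <- phys * to_uv
  }
  dimnames(data) <- list(labels, NULL)

  rec <- structure(list(data = data, rate_hz = rate_hz,
                        channel_names = labels, schedule = NULL,
                        profile_id = NA_character_, role = NA_character_,
                        session = 1L),
                   class = "eeg_recording")
  if (!is.null(events_path)) {
    ev <- read_events(events_path)
    dur <- ncol(data) / rate_hz
    bad <- which(ev$onset_s >= dur)
    if (length(bad)) {
      abort(sprintf("%d event(s) beyond recording duration (%.2f s); rows: %s",
                    length(bad), dur,
                    paste(utils::head(bad, 10), collapse = ", ")),
            class = "rsvpauth_validation_error")
    }
    rec$schedule <- ev
  }
  rec
}

#' @rdname read_edf
#' @param events_path Path to the events TSV.
#' @export
read_recording <- function(path, events_path = NULL) {
  read_edf(path, events_path)
}
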