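#' Generate a face-RSVP stimulus schedule
#'
#' Builds the full event list for a rapid-serial-visual-presentation (RSVP)
#' session: `n_blocks` blocks of `trials_per_block` trials, each trial showing
#' `images_per_trial` face images at a fixed stimulus-onset asynchrony (SOA).
#' Every trial contains exactly one self-face image and
#' `images_per_trial - 1` non-self-face images; within a block all trials use
#' the same image set in independently randomized orders.
#'
#' The self-face image always has `image_id = 0`; each block uses its own set
#' of non-self image ids so that the "same 10 images per block, different
#' order per trial" structure is explicit in the events table. Each trial's
#' presentation order is drawn from a per-trial derived seed, so any single
#' trial is reproducible without replaying the whole schedule.
#'
#' @param n_blocks Number of blocks (default 20).
#' @param trials_per_block Trials per block (default 10).
#' @param images_per_trial Images per trial (default 10; one of them self).
#' @param soa_s Stimulus-onset asynchrony in seconds (default 0.3).
#' @param inter_trial_gap_s Gap between the offset of a trial's last image and
#'   the next trial's first onset, seconds (default 1.0).
#' @param inter_block_gap_s Additional rest inserted between blocks, seconds
#'   (default 10).
#' @param seed Integer seed; the schedule is bit-reproducible given the same
#'   parameters and seed.
#'
#' @return A tibble of class `rsvp_schedule` with one row per stimulus event
#'   and columns `onset_s`, `block`, `trial`, `position` (0-based within
#'   trial), `image_id`, `is_self`. Paradigm parameters are stored as
#'   attributes (`soa_s`, `n_blocks`, `trials_per_block`, `images_per_trial`,
#'   `inter_trial_gap_s`, `inter_block_gap_s`, `seed`).
#' @examples
#' sched <- generate_schedule(seed = 1)
#' nrow(sched)                      # 2000 events
#' sum(sched$is_self)               # 200 trials, one self image each
#' @export
generate_schedule <- function(n_blocks = 20, trials_per_block = 10,
                              images_per_trial = 10, soa_s = 0.3,
                              inter_trial_gap_s = 1.0,
                              inter_block_gap_s = 10.0, seed = 1L) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  trials_per_block <- check_count(trials_per_block, "trials_per_block")
  images_per_trial <- check_count(images_per_trial, "images_per_trial")
  check_positive(soa_s, "soa_s")
  check_positive(inter_trial_gap_s, "inter_trial_gap_s", strict = FALSE)
  check_positive(inter_block_gap_s, "inter_block_gap_s", strict = FALSE)
  seed <- check_count(seed, "seed", min = 0L)

  trial_len <- images_per_trial * soa_s
  rows <- vector("list", n_blocks * trials_per_block)
  t_cursor <- 0
  g <- 0L
  for (b in seq_len(n_blocks)) {
    # one self image (id 0) + block-specific non-self ids
    block_ids <- c(0L, (b - 1L) * (images_per_trial - 1L) +
                     seq_len(images_per_trial - 1L))
    for (tr in seq_len(trials_per_block)) {
      g <- g + 1L
      ord <- with_seed_local(derive_seed(seed, g),
                             sample.int(images_per_trial))
      ids <- block_ids[ord]
      rows[[g]] <- tibble::tibble(
        onset_s = t_cursor + (seq_len(images_per_trial) - 1L) * soa_s,
        block = b,
        trial = tr,
        position = seq_len(images_per_trial) - 1L,
        image_id = ids,
        is_self = ids == 0L
      )
      t_cursor <- t_cursor + trial_len + inter_trial_gap_s
    }
    if (b < n_blocks) t_cursor <- t_cursor + inter_block_gap_s
  }
  sched <- dplyr::bind_rows(rows)
  attr(sched, "soa_s") <- soa_s
  attr(sched, "n_blocks") <- n_blocks
  attr(sched, "trials_per_block") <- trials_per_block
  attr(sched, "images_per_trial") <- images_per_trial
  attr(sched, "inter_trial_gap_s") <- inter_trial_gap_s
  attr(sched, "inter_block_gap_s") <- inter_block_gap_s
  attr(sched, "seed") <- seed
  class(sched) <- c("rsvp_schedule", class(sched))
  sched
}

#' Stimulus duration of an authentication unit
#'
#' Duration of `n_trials` consecutive RSVP trials' stimulation:
#' `n_trials * images_per_trial * soa_s` seconds. With the default paradigm a
#' single trial lasts 3 s, and the authentication unit of two
#' adjacent-averaged trials lasts 6 s.
#'
#' @param schedule An `rsvp_schedule`.
#' @param n_trials Number of trials in the unit (default 1).
#' @return Duration in seconds.
#' @export
trial_duration <- function(schedule, n_trials = 1) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  n_trials <- check_count(n_trials, "n_trials")
  n_trials * attr(schedule, "images_per_trial") * attr(schedule, "soa_s")
}

# shift all onsets by a fixed lead-in (used when embedding a schedule in a
# recording so that pre-stimulus baseline data exist for the first trial)
shift_schedule <- function(schedule, by_s) {
  at <- attributes(schedule)
  schedule$onset_s <- schedule$onset_s + by_s
  for (nm in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(schedule, nm) <- at[[nm]]
  }
  schedule
}

#' Write or read a stimulus event table
#'
#' Events are stored as a tab-separated file with header columns
#' `onset_s` (seconds, 6 decimal places), `block`, `trial`, `position`,
#' `image_id`, `is_self` (0/1).
#'
#' @param schedule An `rsvp_schedule` (or any tibble with the event columns).
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an `rsvp_schedule` tibble (paradigm attributes reconstructed from the
#'   events where possible).
#' @export
write_events <- function(schedule, path) {
  out <- tibble::as_tibble(schedule)
  out$onset_s <- sprintf("%.6f", out$onset_s)
  out$is_self <- as.integer(out$is_self)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, col_types = readr::cols(
    onset_s = readr::col_double(), block = readr::col_integer(),
    trial = readr::col_integer(), position = readr::col_integer(),
    image_id = readr::col_integer(), is_self = readr::col_integer()
  ), progress = FALSE)
  if (any(ev$onset_s < 0)) {
    abort(sprintf("events file has %d negative onset(s); first offending row: %d",
                  sum(ev$onset_s < 0), which(ev$onset_s < 0)[1]),
          class = "rsvpauth_validation_error")
  }
  ev$is_self <- ev$is_self == 1L
  ons <- sort(unique(round(diff(ev$onset_s), 9)))
  soa <- if (length(ons)) min(ons[ons > 0]) else NA_real_
  attr(ev, "soa_s") <- soa
  attr(ev, "n_blocks") <- length(unique(ev$block))
  attr(ev, "trials_per_block") <- max(ev$trial)
  attr(ev, "images_per_trial") <- max(ev$position) + 1L
  class(ev) <- c("rsvp_schedule", class(ev))
  ev
}
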