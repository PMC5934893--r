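# per-trial sufficient statistics for fast fold-wise biserial computation:
# for each trial, the self epoch, the sum over non-self epochs, and the
# corresponding sums of squares, all over post-stimulus samples
precompute_trial_stats <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  post <- post_stimulus_index(epochs)
  lab <- epochs$labels
  key <- paste(lab$block, lab$trial, sep = ":")
  trials <- unique(key)
  C <- dim(epochs$data)[2]
  S <- length(post)
  dat <- epochs$data[, , post, drop = FALSE]
  dim(dat) <- c(dim(epochs$data)[1], C * S)
  self_x <- matrix(0, length(trials), C * S)
  self_sq <- matrix(0, length(trials), C * S)
  ns_sum <- matrix(0, length(trials), C * S)
  ns_sumsq <- matrix(0, length(trials), C * S)
  n_ns <- integer(length(trials))
  for (j in seq_along(trials)) {
    rows <- which(key == trials[j])
    sr <- rows[lab$is_self[rows]]
    nr <- rows[!lab$is_self[rows]]
    stopifnot(length(sr) == 1L)
    self_x[j, ] <- dat[sr, ]
    self_sq[j, ] <- dat[sr, ]^2
    if (length(nr) == 1L) {
      ns_sum[j, ] <- dat[nr, ]
      ns_sumsq[j, ] <- dat[nr, ]^2
    } else {
      ns_sum[j, ] <- colSums(dat[nr, , drop = FALSE])
      ns_sumsq[j, ] <- colSums(dat[nr, , drop = FALSE]^2)
    }
    n_ns[j] <- length(nr)
  }
  list(trials = trials, self_x = self_x, self_sq = self_sq,
       ns_sum = ns_sum, ns_sumsq = ns_sumsq, n_ns = n_ns,
       C = C, S = S, channel_names = epochs$channel_names)
}

# pointwise biserial map restricted to a subset of trials, computed from the
# precomputed statistics; numerically identical to pointwise_biserial() on
# the corresponding epoch subset
biserial_from_trials <- function(stats, trial_idx) {
  N1 <- length(trial_idx)
  N2 <- sum(stats$n_ns[trial_idx])
  m1 <- colSums(stats$self_x[trial_idx, , drop = FALSE]) / N1
  m2 <- colSums(stats$ns_sum[trial_idx, , drop = FALSE]) / N2
  sumsq <- colSums(stats$self_sq[trial_idx, , drop = FALSE]) +
    colSums(stats$ns_sumsq[trial_idx, , drop = FALSE])
  ntot <- N1 + N2
  mall <- (N1 * m1 + N2 * m2) / ntot
  s_pop <- sqrt(pmax(sumsq / ntot - mall^2, 0))
  P <- sqrt(N1 * N2) / ntot * (m1 - m2) / s_pop
  P[s_pop == 0] <- 0
  structure(list(P = matrix(P, nrow = stats$C,
                            dimnames = list(stats$channel_names, NULL)),
                 N1 = N1, N2 = N2, n_degenerate = sum(s_pop == 0),
                 channel_names = stats$channel_names,
                 scores = NULL, selected = NULL, aggregate_mode = NULL),
            class = "channel_map")
}

# stack two trials x channels x samples arrays along the trial axis
bind_trials <- function(a, b) {
  stopifnot(all(dim(a)[-1] == dim(b)[-1]))
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

fold_metrics <- function(accept_user, accept_imposter) {
  n_u <- length(accept_user); n_i <- length(accept_imposter)
  fr <- sum(!accept_user); fa <- sum(accept_imposter)
  correct <- (n_u - fr) + (n_i - fa)
  tibble::tibble(n_user_test = n_u, n_imposter_test = n_i,
                 correct = correct, false_accepts = fa, false_rejects = fr,
                 acc = 100 * correct / (n_u + n_i),
                 far = 100 * fa / n_i, frr = 100 * fr / n_u)
}

#' Repeated stratified cross-validated authentication
#'
#' Evaluates a user-vs-imposter authentication problem with a
#' `repeats`-time, `k`-fold stratified cross-validation (default 10 x 10):
#' each repeat shuffles both classes into k folds of equal size, trains the
#' channel selection (optionally) and the HDCA model on the k-1 training
#' folds and tests on the held-out fold, so with 100 averaged trials per
#' class every fold trains on 90 and tests on 10 per class. ACC, FAR and FRR
#' are accumulated per fold and summarized as mean (std) over all
#' `repeats * k` fold evaluations.
#'
#' @param user_features,imposter_features Full-montage, pair-averaged
#'   `trial_features` for the user and the imposter scenario.
#' @param k Folds per repeat (default 10).
#' @param repeats Number of shuffled repeats (default 10).
#' @param seed Integer seed; repeat r uses `seed + r`.
#' @param selection `"per_fold"` (default; channels re-selected from the
#'   training trials of each fold), `"per_user"` (selected once from
#'   `user_epochs` or given via `selected_channels`), or `"none"` (all
#'   channels).
#' @param user_epochs The user's `epoch_set` (required for selection unless
#'   `selected_channels` is given).
#' @param selected_channels Optional fixed channel indices.
#' @param n_channels Channels to select (default 6).
#' @param aggregate_mode Aggregate for [rank_and_select()].
#' @param n_windows,shrinkage,penalty,threshold HDCA settings, see
#'   [fit_hdca()].
#' @return A list of class `auth_cv` with `folds` (per-fold metrics tibble),
#'   `scores` (per-test-sample scores with labels), and the settings.
#' @export
crossvalidate <- function(user_features, imposter_features, k = 10,
                          repeats = 10, seed = 1L,
                          selection = c("per_fold", "per_user", "none"),
                          user_epochs = NULL, selected_channels = NULL,
                          n_channels = 6, aggregate_mode = "abs_sum",
                          n_windows = 10, shrinkage = 0.1, penalty = 1e-2,
                          threshold = 0) {
  stopifnot(inherits(user_features, "trial_features"),
            inherits(imposter_features, "trial_features"))
  selection <- match.arg(selection)
  k <- check_count(k, "k", min = 2L)
  repeats <- check_count(repeats, "repeats")
  n_u <- dim(user_features$data)[1]
  n_i <- dim(imposter_features$data)[1]
  if (n_u < k || n_i < k) {
    abort(sprintf("classes of size %d/%d cannot form %d folds", n_u, n_i, k),
          class = "rsvpauth_invalid_parameter")
  }

  stats <- NULL
  if (selection == "per_fold") {
    if (is.null(user_epochs)) {
      abort("per_fold selection requires `user_epochs`",
            class = "rsvpauth_invalid_parameter")
    }
    stats <- precompute_trial_stats(user_epochs)
  } else if (selection == "per_user") {
    if (is.null(selected_channels)) {
      if (is.null(user_epochs)) {
        abort("per_user selection requires `user_epochs` or `selected_channels`",
              class = "rsvpauth_invalid_parameter")
      }
      map <- rank_and_select(pointwise_biserial(user_epochs),
                             k = n_channels, aggregate_mode = aggregate_mode)
      selected_channels <- map$selected
    }
  } else {
    selected_channels <- seq_len(dim(user_features$data)[2])
  }

  folds_out <- vector("list", repeats * k)
  scores_out <- vector("list", repeats * k)
  fi <- 0L
  for (r in seq_len(repeats)) {
    assign_u <- with_seed_local(derive_seed(seed, 10000L + r),
                                sample(rep(seq_len(k), length.out = n_u)))
    assign_i <- with_seed_local(derive_seed(seed, 20000L + r),
                                sample(rep(seq_len(k), length.out = n_i)))
    for (f in seq_len(k)) {
      fi <- fi + 1L
      test_u <- which(assign_u == f); train_u <- which(assign_u != f)
      test_i <- which(assign_i == f); train_i <- which(assign_i != f)

      sel <- selected_channels
      if (selection == "per_fold") {
        train_trials <- unique(unlist(user_features$meta$trials[train_u]))
        map <- biserial_from_trials(stats, match(train_trials, stats$trials))
        map <- rank_and_select(map, k = n_channels,
                               aggregate_mode = aggregate_mode)
        sel <- map$selected
      }

      Xtr <- bind_trials(user_features$data[train_u, sel, , drop = FALSE],
                         imposter_features$data[train_i, sel, , drop = FALSE])
      ytr <- c(rep(TRUE, length(train_u)), rep(FALSE, length(train_i)))
      model <- fit_hdca(Xtr, ytr, n_windows = n_windows,
                        shrinkage = shrinkage, penalty = penalty,
                        threshold = threshold)
      s_u <- score_features(user_features$data[test_u, sel, , drop = FALSE],
                            model)
      s_i <- score_features(imposter_features$data[test_i, sel, , drop = FALSE],
                            model)
      m <- fold_metrics(decide(s_u, threshold), decide(s_i, threshold))
      m$repeat_id <- r; m$fold <- f
      folds_out[[fi]] <- m
      scores_out[[fi]] <- tibble::tibble(
        repeat_id = r, fold = f,
        label = c(rep("user", length(s_u)), rep("imposter", length(s_i))),
        score = c(s_u, s_i))
    }
  }
  folds <- dplyr::bind_rows(folds_out)
  folds <- folds[, c("repeat_id", "fold", "n_user_test", "n_imposter_test",
                     "correct", "false_accepts", "false_rejects",
                     "acc", "far", "frr")]
  structure(list(folds = folds, scores = dplyr::bind_rows(scores_out),
                 k = k, repeats = repeats, seed = seed,
                 selection = selection, n_channels = n_channels,
                 threshold = threshold),
            class = "auth_cv")
}

#' @export
print.auth_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<auth_cv> %d x %d-fold CV (%s channel selection)\n",
              x$repeats, x$k, x$selection))
  cat(sprintf("  ACC %.2f (%.2f)%%  FAR %.2f (%.2f)%%  FRR %.2f (%.2f)%%\n",
              g$acc_mean, g$acc_sd, g$far_mean, g$far_sd,
              g$frr_mean, g$frr_sd))
  invisible(x)
}

#' @rdname tidy.hdca_model
#' @method tidy auth_cv
#' @export
tidy.auth_cv <- function(x, ...) x$folds

#' @rdname tidy.hdca_model
#' @method glance auth_cv
#' @export
glance.auth_cv <- function(x, ...) {
  f <- x$folds
  tibble::tibble(
    n_folds = nrow(f),
    acc_mean = mean(f$acc), acc_sd = sd(f$acc),
    far_mean = mean(f$far), far_sd = sd(f$far),
    frr_mean = mean(f$frr), frr_sd = sd(f$frr))
}

#' Train an authentication model on registration data
#'
#' Full registration pipeline for one user: select the user's channels from
#' their epochs, build pair-averaged contrast features for user and
#' imposter, and fit the HDCA model. The result bundles everything needed to
#' authenticate later sessions.
#'
#' @param user_epochs,imposter_epochs `epoch_set`s of the user and an
#'   imposter (any scenario) from the registration session.
#' @param n_channels,aggregate_mode Channel-selection settings.
#' @param feature_mode Feature construction mode, see
#'   [build_trial_features()].
#' @param n_windows,shrinkage,penalty,threshold HDCA settings.
#' @return A list of class `model_bundle`: `selected_channels` (indices),
#'   `channel_names`, `hdca`, `fingerprint` (rates, epoch window, feature
#'   mode), `metadata`.
#' @export
train_authenticator <- function(user_epochs, imposter_epochs, n_channels = 6,
                                aggregate_mode = "abs_sum",
                                feature_mode = "self_minus_nonself_mean",
                                n_windows = 10, shrinkage = 0.1,
                                penalty = 1e-2, threshold = 0) {
  map <- rank_and_select(pointwise_biserial(user_epochs), k = n_channels,
                         aggregate_mode = aggregate_mode)
  fu <- average_adjacent_trials(
    build_trial_features(user_epochs, channels = map$selected,
                         mode = feature_mode))
  fi <- average_adjacent_trials(
    build_trial_features(imposter_epochs, channels = map$selected,
                         mode = feature_mode))
  X <- bind_trials(fu$data, fi$data)
  y <- c(rep(TRUE, dim(fu$data)[1]), rep(FALSE, dim(fi$data)[1]))
  model <- fit_hdca(X, y, n_windows = n_windows, shrinkage = shrinkage,
                    penalty = penalty, threshold = threshold)
  model$channel_names <- user_epochs$channel_names[map$selected]
  structure(list(
    selected_channels = map$selected,
    channel_names = user_epochs$channel_names[map$selected],
    channel_map = map,
    hdca = model,
    fingerprint = list(format_version = 1L, rate_hz = user_epochs$rate_hz,
                       t0_s = user_epochs$t0_s,
                       n_samples = dim(user_epochs$data)[3],
                       feature_mode = feature_mode, n_windows = n_windows,
                       shrinkage = shrinkage, penalty = penalty,
                       threshold = threshold),
    metadata = list(subject_id = user_epochs$labels$subject_id[1],
                    imposter_id = imposter_epochs$labels$subject_id[1])
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> user %s\n", x$metadata$subject_id))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  print(x$hdca)
  invisible(x)
}

#' False rejection rate across sessions
#'
#' Scores a later session's user features with a model trained on the
#' registration session and reports the false rejection rate (percent of
#' the user's own authentication units rejected). No imposter data are
#' involved.
#'
#' @param bundle A [train_authenticator()] model bundle.
#' @param session_features Full-montage, pair-averaged `trial_features` from
#'   the later session.
#' @return FRR in percent.
#' @export
cross_session_frr <- function(bundle, session_features) {
  stopifnot(inherits(bundle, "model_bundle"),
            inherits(session_features, "trial_features"))
  if (dim(session_features$data)[1] == 0) {
    abort("session feature set is empty", class = "rsvpauth_invalid_parameter")
  }
  sel <- match(bundle$channel_names, session_features$channel_names)
  if (anyNA(sel)) {
    abort(sprintf("session data lack model channel(s): %s",
                  paste(bundle$channel_names[is.na(sel)], collapse = ", ")),
          class = "rsvpauth_channel_mismatch")
  }
  s <- score_features(session_features$data[, sel, , drop = FALSE],
                      bundle$hdca)
  100 * mean(!decide(s, bundle$fingerprint$threshold))
}

#' Between-session ERP correlation
#'
#' Pearson correlation between two sessions' average self-face ERPs on the
#' selected channels, concatenated across channels over the post-stimulus
#' window — a permanence measure of the evoked biometric.
#'
#' @param epochs1,epochs2 `epoch_set`s from the two sessions.
#' @param channels Channel indices or names (e.g. the selected 6).
#' @return Pearson correlation coefficient.
#' @export
session_correlation <- function(epochs1, epochs2, channels = NULL) {
  avg_self <- function(ep) {
    chs <- channels %||% seq_len(dim(ep$data)[2])
    if (is.character(chs)) chs <- match(chs, ep$channel_names)
    if (anyNA(chs)) abort("unknown channel name(s)",
                          class = "rsvpauth_channel_mismatch")
    post <- post_stimulus_index(ep)
    rows <- which(ep$labels$is_self)
    if (!length(rows)) abort("no self-face epochs",
                             class = "rsvpauth_invalid_parameter")
    as.numeric(colMeans(ep$data[rows, chs, post, drop = FALSE], dims = 1))
  }
  a <- avg_self(epochs1)
  b <- avg_self(epochs2)
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero-variance average ERP: correlation undefined",
          class = "rsvpauth_degenerate_input")
  }
  cor(a, b)
}

#' FAR/FRR trade-off over decision thresholds
#'
#' Sweeps the decision threshold over the observed score range and reports
#' FAR and FRR at each cut. As the threshold decreases FAR is non-decreasing
#' and FRR non-increasing.
#'
#' @param scores Numeric authentication scores.
#' @param labels `"user"`/`"imposter"` (or logical, `TRUE` = user).
#' @param thresholds Optional threshold grid; defaults to the sorted unique
#'   scores flanked by -Inf/Inf.
#' @return Tibble with `threshold`, `far`, `frr` (percent), sorted by
#'   decreasing threshold.
#' @export
threshold_sweep <- function(scores, labels, thresholds = NULL) {
  lab <- if (is.logical(labels)) labels else labels == "user"
  thresholds <- thresholds %||% c(Inf, rev(sort(unique(scores))), -Inf)
  tibble::tibble(
    threshold = thresholds,
    far = vapply(thresholds, function(t) 100 * mean(scores[!lab] >= t),
                 numeric(1)),
    frr = vapply(thresholds, function(t) 100 * mean(scores[lab] < t),
                 numeric(1)))
}

#' Cohort metrics table
#'
#' Assembles per-user, per-scenario authentication metrics into a report
#' with one data row per (user, scenario) and aggregate mean/std rows per
#' scenario plus a pooled (ensemble) row. Users missing a scenario are
#' flagged and excluded from that scenario's aggregates.
#'
#' @param per_user Tibble with columns `user`, `scenario`, `acc`, `far`,
#'   `frr` (percent) and optionally `n_test_user`, `n_test_imposter`.
#' @return Tibble with an extra `row_type` column (`"user"`, `"mean"`,
#'   `"std"`) and a `complete` flag.
#' @export
scenario_report <- function(per_user) {
  req <- c("user", "scenario", "acc", "far", "frr")
  if (!all(req %in% names(per_user))) {
    abort(sprintf("per_user must have columns %s", paste(req, collapse = ", ")),
          class = "rsvpauth_invalid_parameter")
  }
  per_user <- tibble::as_tibble(per_user)
  scen <- sort(unique(per_user$scenario))
  users <- unique(per_user$user)
  full <- tidyr::expand_grid(user = users, scenario = scen)
  data_rows <- dplyr::left_join(full, per_user, by = c("user", "scenario"))
  data_rows$row_type <- "user"
  data_rows$complete <- !is.na(data_rows$acc)
  agg <- function(rows, label, fun) {
    tibble::tibble(user = label, scenario = rows$scenario[1],
                   acc = fun(rows$acc), far = fun(rows$far),
                   frr = fun(rows$frr), row_type = label, complete = TRUE)
  }
  aggs <- dplyr::bind_rows(lapply(scen, function(s) {
    rows <- data_rows[data_rows$scenario == s & data_rows$complete, ]
    dplyr::bind_rows(agg(rows, "mean", mean), agg(rows, "std", sd))
  }))
  pooled <- data_rows[data_rows$complete, ]
  ens <- tibble::tibble(user = c("ensemble-mean", "ensemble-std"),
                        scenario = NA, acc = c(mean(pooled$acc), sd(pooled$acc)),
                        far = c(mean(pooled$far), sd(pooled$far)),
                        frr = c(mean(pooled$frr), sd(pooled$frr)),
                        row_type = c("mean", "std"), complete = TRUE)
  dplyr::bind_rows(data_rows, aggs, ens)
}
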