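#' Build per-trial classification features
#'
#' Converts the 10 image-epochs of each RSVP trial into one feature matrix of
#' selected channels x post-stimulus samples. The default mode
#' `self_minus_nonself_mean` subtracts the mean of the trial's non-self
#' epochs from its self epoch, isolating the self/non-self contrast that is
#' the biometric signature; `self_only` keeps the self epoch as is.
#'
#' @param epochs An `epoch_set` containing, for every (block, trial), exactly
#'   one self epoch and at least one non-self epoch.
#' @param channels Integer indices (or names) of the channels to retain;
#'   `NULL` keeps all.
#' @param mode `"self_minus_nonself_mean"` (default) or `"self_only"`.
#' @return A list of class `trial_features`: `data` (trials x channels x
#'   post-stimulus samples), `meta` (tibble with `unit` and list-column
#'   `trials` of contributing trial keys), `channel_names`, `rate_hz`,
#'   `mode`, `pair_averaged` (FALSE).
#' @export
build_trial_features <- function(epochs, channels = NULL,
                                 mode = c("self_minus_nonself_mean",
                                          "self_only")) {
  stopifnot(inherits(epochs, "epoch_set"))
  mode <- match.arg(mode)
  if (is.character(channels)) {
    channels <- match(channels, epochs$channel_names)
    if (anyNA(channels)) abort("unknown channel name(s)",
                               class = "rsvpauth_invalid_parameter")
  }
  channels <- channels %||% seq_len(dim(epochs$data)[2])
  post <- post_stimulus_index(epochs)
  lab <- epochs$labels
  key <- paste(lab$block, lab$trial, sep = ":")
  trials <- unique(key)
  out <- array(0, dim = c(length(trials), length(channels), length(post)))
  for (j in seq_along(trials)) {
    rows <- which(key == trials[j])
    self_row <- rows[lab$is_self[rows]]
    ns_rows <- rows[!lab$is_self[rows]]
    if (length(self_row) != 1L) {
      abort(sprintf("trial %s has %d self epochs (expected 1)",
                    trials[j], length(self_row)),
            class = "rsvpauth_feature_error")
    }
    self_mat <- epochs$data[self_row, channels, post]
    if (mode == "self_only") {
      out[j, , ] <- self_mat
    } else {
      if (length(ns_rows) == 0L) {
        abort(sprintf("trial %s has no non-self epochs", trials[j]),
              class = "rsvpauth_feature_error")
      }
      ns_mean <- colMeans(epochs$data[ns_rows, channels, post, drop = FALSE],
                          dims = 1)
      out[j, , ] <- self_mat - ns_mean
    }
  }
  structure(list(data = out,
                 meta = tibble::tibble(unit = seq_along(trials),
                                       trials = as.list(trials)),
                 channel_names = epochs$channel_names[channels],
                 rate_hz = epochs$rate_hz, mode = mode,
                 pair_averaged = FALSE),
            class = "trial_features")
}

#' @export
print.trial_features <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_features> %d %s x %d channels x %d samples (%s)\n",
              d[1], if (isTRUE(x$pair_averaged)) "averaged units" else "trials",
              d[2], d[3], x$mode))
  invisible(x)
}

# restrict a trial_features object to a channel subset (by index into its
# current channel set)
subset_channels <- function(features, channels) {
  features$data <- features$data[, channels, , drop = FALSE]
  features$channel_names <- features$channel_names[channels]
  features
}

#' Equal partition of the post-stimulus epoch into time windows
#'
#' @param n_samples Number of post-stimulus samples (600 at 600 Hz).
#' @param n_windows Number of contiguous windows (default 10, i.e. 100 ms
#'   each over 0--1000 ms).
#' @return Tibble with columns `window`, `start`, `end` (1-based, inclusive)
#'   forming a partition of `1:n_samples`.
#' @export
make_windows <- function(n_samples, n_windows = 10) {
  n_samples <- check_count(n_samples, "n_samples")
  n_windows <- check_count(n_windows, "n_windows")
  if (n_windows > n_samples) {
    abort("more windows than samples", class = "rsvpauth_invalid_parameter")
  }
  edges <- floor(seq(0, n_samples, length.out = n_windows + 1))
  tibble::tibble(window = seq_len(n_windows),
                 start = edges[-length(edges)] + 1L,
                 end = edges[-1])
}

# per-window channel means: trials x channels x samples -> list of
# trials x channels matrices, one per window
window_channel_means <- function(data, windows) {
  lapply(seq_len(nrow(windows)), function(k) {
    sel <- windows$start[k]:windows$end[k]
    if (length(sel) == 1L) data[, , sel, drop = TRUE]
    else rowMeans(data[, , sel, drop = FALSE], dims = 2)
  })
}

#' Fit per-window spatial Fisher discriminant weights
#'
#' For each time window, computes the channel means of every feature over
#' the window's samples and fits a Fisher linear discriminant between the
#' user and imposter classes:
#' \eqn{w = (\Sigma + \lambda \,\mathrm{tr}(\Sigma)/C \cdot I)^{-1}
#' (\mu_{user} - \mu_{imposter})}, where \eqn{\Sigma} is the pooled
#' within-class covariance over the C channels and \eqn{\lambda} the
#' shrinkage weight. Weights are normalized to unit length with the sign
#' fixed so the user-class mean projects at least as high as the
#' imposter-class mean; if the class means coincide the weight falls back
#' deterministically to the first coordinate axis.
#'
#' @param features A `trial_features` object (or trials x channels x samples
#'   array) pooling both classes.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = user class.
#' @param windows Window table from [make_windows()].
#' @param shrinkage Shrinkage weight \eqn{\lambda \ge 0} (default 0.1).
#' @return Matrix `W` (windows x channels) of unit-norm spatial weights.
#' @export
fit_spatial_weights <- function(features, labels, windows, shrinkage = 0.1) {
  data <- if (inherits(features, "trial_features")) features$data else features
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("each class needs at least 2 feature samples",
          class = "rsvpauth_invalid_parameter")
  }
  check_positive(shrinkage, "shrinkage", strict = FALSE)
  C <- dim(data)[2]
  wm <- window_channel_means(data, windows)
  W <- matrix(0, nrow = nrow(windows), ncol = C)
  for (k in seq_len(nrow(windows))) {
    X <- wm[[k]]
    mu1 <- colMeans(X[labels, , drop = FALSE])
    mu0 <- colMeans(X[!labels, , drop = FALSE])
    X1 <- sweep(X[labels, , drop = FALSE], 2, mu1)
    X0 <- sweep(X[!labels, , drop = FALSE], 2, mu0)
    Sp <- (crossprod(X1) + crossprod(X0)) / (nrow(X) - 2)
    reg <- Sp + shrinkage * (sum(diag(Sp)) / C) * diag(C)
    d <- mu1 - mu0
    w <- tryCatch(solve(reg, d), error = function(e) {
      abort("singular pooled covariance; use shrinkage > 0",
            class = "rsvpauth_singular_covariance")
    })
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      w <- c(1, rep(0, C - 1))   # coincident class means: deterministic axis
    } else {
      w <- w / nw
      if (sum(w * d) < 0) w <- -w
    }
    W[k, ] <- w
  }
  colnames(W) <- if (inherits(features, "trial_features"))
    features$channel_names else NULL
  W
}

#' Project features onto per-window spatial weights
#'
#' Compresses each feature to one score per time window:
#' \eqn{y_k = w_k \cdot \bar{x}_k} where \eqn{\bar{x}_k} is the vector of
#' channel means over window k's samples — the spatially weighted
#' single-channel signal averaged within the segment.
#'
#' @param features A `trial_features` object or trials x channels x samples
#'   array (a single feature may be passed as channels x samples).
#' @param model An `hdca_model` (or a list with `W` and `windows`).
#' @return Matrix of window scores, trials x windows.
#' @export
project_windows <- function(features, model) {
  data <- if (inherits(features, "trial_features")) features$data else features
  if (length(dim(data)) == 2L) {
    data <- array(data, dim = c(1, dim(data)))
  }
  if (dim(data)[2] != ncol(model$W)) {
    abort(sprintf("feature has %d channels but model expects %d",
                  dim(data)[2], ncol(model$W)),
          class = "rsvpauth_dimension_error")
  }
  if (dim(data)[3] < max(model$windows$end)) {
    abort("feature sample count shorter than the model's windows",
          class = "rsvpauth_dimension_error")
  }
  wm <- window_channel_means(data, model$windows)
  Y <- vapply(seq_len(nrow(model$windows)),
              function(k) as.numeric(wm[[k]] %*% model$W[k, ]),
              numeric(dim(data)[1]))
  matrix(Y, nrow = dim(data)[1])
}

#' Fit temporal weights by penalized logistic regression
#'
#' Combines the window scores into one authentication score
#' \eqn{Y_S = \sum_k v_k y_k + b} by maximizing the binomial log-likelihood
#' with an L2 penalty on `v` (intercept unpenalized):
#' minimize \eqn{-\sum_i \ell_i + (\mathrm{penalty}/2)\,\lVert v\rVert^2}.
#' Newton iterations stop when the gradient norm falls below `tol` or after
#' `maxit` iterations.
#'
#' @param Y Window-score matrix, trials x windows.
#' @param labels Logical or 0/1, `TRUE`/1 = user class.
#' @param penalty L2 penalty weight (default 1e-2; must be > 0 if the
#'   classes are separable).
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param maxit Maximum Newton iterations (default 1000).
#' @return List with `v` (length-N weights) and `intercept`.
#' @export
fit_temporal_weights <- function(Y, labels, penalty = 1e-2, tol = 1e-8,
                                 maxit = 1000) {
  Y <- as.matrix(Y)
  y <- as.numeric(as.logical(labels))
  if (all(y == 1) || all(y == 0)) {
    abort("both classes must be present", class = "rsvpauth_invalid_parameter")
  }
  check_positive(penalty, "penalty", strict = FALSE)
  n <- nrow(Y); N <- ncol(Y)
  X <- cbind(1, Y)
  pen <- c(0, rep(penalty, N))
  beta <- numeric(N + 1)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- as.numeric(crossprod(X, y - p)) - pen * beta
    if (sqrt(sum(g^2)) < tol) break
    wgt <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * wgt, X) + diag(pen, N + 1)
    step <- tryCatch(solve(H, g), error = function(e) {
      if (penalty == 0) {
        abort("logistic fit failed (perfect separation?); use penalty > 0",
              class = "rsvpauth_separation_error")
      }
      abort("logistic Newton step failed (singular Hessian)",
            class = "rsvpauth_fit_error")
    })
    beta <- beta + step
    if (!all(is.finite(beta)) || sqrt(sum(beta^2)) > 1e8) {
      abort("logistic weights diverging (perfect separation?); use penalty > 0",
            class = "rsvpauth_separation_error")
    }
  }
  # with no penalty the MLE does not exist under perfect separation: the
  # iterations stall at a saturated solution instead of diverging
  eta <- as.numeric(X %*% beta)
  if (penalty == 0 && all(y == (eta > 0)) && min(abs(eta)) > 10) {
    abort("perfect separation with zero penalty; use penalty > 0",
          class = "rsvpauth_separation_error")
  }
  list(v = beta[-1], intercept = beta[1])
}

#' Fit a full HDCA authentication model
#'
#' Two-stage hierarchical discriminant component analysis: per-window
#' spatial Fisher discriminant weights ([fit_spatial_weights()]) compress
#' the selected channels to one score per time window; penalized logistic
#' regression ([fit_temporal_weights()]) combines the window scores into the
#' authentication score \eqn{Y_S}.
#'
#' @inheritParams fit_spatial_weights
#' @inheritParams fit_temporal_weights
#' @param n_windows Number of equal time windows (default 10).
#' @param threshold Decision cut on \eqn{Y_S} (default 0, the posterior-0.5
#'   point; accept on `>=`).
#' @return A list of class `hdca_model`: `windows`, `W`, `v`, `intercept`,
#'   `threshold`, `shrinkage`, `penalty`, `channel_names`.
#' @export
fit_hdca <- function(features, labels, n_windows = 10, shrinkage = 0.1,
                     penalty = 1e-2, threshold = 0) {
  data <- if (inherits(features, "trial_features")) features$data else features
  windows <- make_windows(dim(data)[3], n_windows)
  W <- fit_spatial_weights(features, labels, windows, shrinkage)
  model <- structure(list(windows = windows, W = W, v = NULL,
                          intercept = NULL, threshold = threshold,
                          shrinkage = shrinkage, penalty = penalty,
                          channel_names = if (inherits(features, "trial_features"))
                            features$channel_names else NULL),
                     class = "hdca_model")
  Y <- project_windows(features, model)
  tw <- fit_temporal_weights(Y, labels, penalty = penalty)
  model$v <- tw$v
  model$intercept <- tw$intercept
  model
}

#' Score features and make accept/reject decisions
#'
#' `score_features()` returns \eqn{Y_S = \sum_k v_k y_k + b} for each
#' feature; `decide()` accepts a feature iff its score is greater than or
#' equal to the threshold (ties accept, by convention).
#'
#' @param features A `trial_features` object or array.
#' @param model A fitted `hdca_model`.
#' @param scores Numeric scores from `score_features()`.
#' @param threshold Decision threshold; defaults to the model's.
#' @return `score_features()`: numeric vector; `decide()`: logical vector
#'   (`TRUE` = accept).
#' @export
score_features <- function(features, model) {
  if (is.null(model$v)) {
    abort("model is not fitted", class = "rsvpauth_unfitted_model")
  }
  Y <- project_windows(features, model)
  as.numeric(Y %*% model$v) + model$intercept
}

#' @rdname score_features
#' @export
decide <- function(scores, threshold = 0) {
  scores >= threshold
}

#' @export
print.hdca_model <- function(x, ...) {
  cat(sprintf("<hdca_model> %d windows x %d channels%s\n",
              nrow(x$W), ncol(x$W),
              if (is.null(x$v)) " (spatial stage only)" else ""))
  if (!is.null(x$v)) {
    cat(sprintf("  |v| max at window %d; threshold %g\n",
                which.max(abs(x$v)), x$threshold))
  }
  invisible(x)
}

#' Tidy and summarize fitted objects
#'
#' `tidy()` on an `hdca_model` returns one row per (window, channel) with
#' the spatial weight and the window's temporal weight; on a `channel_map`
#' it returns the per-channel score table. `glance()` on an `hdca_model`
#' returns a one-row model summary.
#'
#' @param x An `hdca_model` or `channel_map`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hdca_model
#' @export
tidy.hdca_model <- function(x, ...) {
  N <- nrow(x$W); C <- ncol(x$W)
  tibble::tibble(
    window = rep(seq_len(N), each = C),
    channel = rep(colnames(x$W) %||% as.character(seq_len(C)), times = N),
    spatial_weight = as.numeric(t(x$W)),
    temporal_weight = if (is.null(x$v)) NA_real_ else rep(x$v, each = C)
  )
}

#' @rdname tidy.hdca_model
#' @method glance hdca_model
#' @export
glance.hdca_model <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$W), n_channels = ncol(x$W),
                 shrinkage = x$shrinkage, penalty = x$penalty,
                 threshold = x$threshold,
                 intercept = x$intercept %||% NA_real_,
                 peak_window = if (is.null(x$v)) NA_integer_
                               else which.max(abs(x$v)))
}
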