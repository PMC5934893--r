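test_that("trial features isolate the self/non-self contrast", {
  # identical self and non-self epochs cancel under the default mode
  arr <- array(rnorm(4 * 2 * 6), dim = c(4, 2, 6))
  arr[2, , ] <- arr[1, , ]; arr[3, , ] <- arr[1, , ]; arr[4, , ] <- arr[1, , ]
  ep <- manual_epochs(arr, c(TRUE, FALSE, FALSE, FALSE),
                      block = rep(1L, 4), trial = rep(1L, 4))
  f <- build_trial_features(ep)
  expect_lt(max(abs(f$data)), 1e-12)

  f_self <- build_trial_features(ep, mode = "self_only")
  expect_equal(f_self$data[1, , ], arr[1, , ])

  ep_bad <- manual_epochs(arr, rep(FALSE, 4), block = rep(1L, 4),
                          trial = rep(1L, 4))
  expect_error(build_trial_features(ep_bad), class = "rsvpauth_feature_error")
})

test_that("noiseless user features reproduce the contrast waveform", {
  sched <- generate_schedule(n_blocks = 2, seed = 7)
  prof <- quiet_profile(seed = 7)
  ct <- prof$self_contrast_components[[1]]
  ep <- extract_epochs(simulate_recording(prof, sched, 600, seed = 7))
  f <- build_trial_features(ep, channels = truth_channels)
  want <- outer(ct$topography[truth_channels], analytic_wave(ct, 600, 600))
  # interior trial; tolerance covers overlap edge effects from neighbors
  err <- max(abs(f$data[8, , ] - want))
  expect_lt(err, 0.3 * max(abs(want)))
  peak_got <- which.max(abs(f$data[8, 1, ]))
  peak_want <- which.max(abs(want[1, ]))
  expect_lte(abs(peak_got - peak_want), 1)
})

test_that("spatial weights solve the closed-form discriminant", {
  # classes separated only on channel 1 with symmetric isotropic scatter
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- array(0, dim = c(8, 2, 1))
  X[1:4, , 1] <- sweep(pts, 2, c(2, 0), "+")
  X[5:8, , 1] <- pts
  W <- fit_spatial_weights(X, rep(c(TRUE, FALSE), each = 4),
                           make_windows(1, 1), shrinkage = 0)
  expect_equal(as.numeric(W), c(1, 0), tolerance = 1e-12)

  # coincident class means: deterministic fallback axis
  X0 <- X; X0[1:4, , 1] <- pts
  W0 <- fit_spatial_weights(X0, rep(c(TRUE, FALSE), each = 4),
                            make_windows(1, 1), shrinkage = 0)
  expect_equal(as.numeric(W0), c(1, 0))
})

test_that("spatial weights parallel an independent pooled-covariance solve", {
  for (s in 1:25) {
    set.seed(s)
    n <- 30; C <- 4
    X <- array(rnorm(2 * n * C * 8), dim = c(2 * n, C, 8))
    X[1:n, , ] <- X[1:n, , ] + 0.8
    y <- rep(c(TRUE, FALSE), each = n)
    windows <- make_windows(8, 2)
    W <- fit_spatial_weights(X, y, windows, shrinkage = 0)
    for (k in 1:2) {
      M <- rowMeans(X[, , windows$start[k]:windows$end[k]], dims = 2)
      mu1 <- colMeans(M[y, ]); mu0 <- colMeans(M[!y, ])
      Sp <- ((n - 1) * cov(M[y, ]) + (n - 1) * cov(M[!y, ])) / (2 * n - 2)
      w_oracle <- solve(Sp, mu1 - mu0)
      cosine <- sum(W[k, ] * w_oracle) /
        sqrt(sum(W[k, ]^2) * sum(w_oracle^2))
      expect_gt(cosine, 1 - 1e-8)
    }
  }
})

test_that("singular covariance without shrinkage is a clear error", {
  X <- array(0, dim = c(8, 3, 2))          # zero variance everywhere
  X[1:4, 1, ] <- 1
  expect_error(fit_spatial_weights(X, rep(c(TRUE, FALSE), each = 4),
                                   make_windows(2, 1), shrinkage = 0),
               class = "rsvpauth_singular_covariance")
  # shrinkage alone cannot rescue an all-zero covariance with zero trace,
  # but any nonzero scatter plus shrinkage works
  X[, , ] <- X + array(rnorm(48, sd = 0.1), dim = dim(X))
  W <- fit_spatial_weights(X, rep(c(TRUE, FALSE), each = 4),
                           make_windows(2, 1), shrinkage = 0.1)
  expect_true(all(is.finite(W)))
})

test_that("window projection matches a naive two-loop oracle", {
  set.seed(11)
  data <- array(rnorm(5 * 3 * 12), dim = c(5, 3, 12))
  windows <- make_windows(12, 4)
  model <- list(W = matrix(rnorm(12), 4, 3), windows = windows)
  Y <- project_windows(data, model)
  for (tr in 1:5) for (k in 1:4) {
    acc <- 0
    for (i in 1:3) {
      acc <- acc + model$W[k, i] *
        mean(data[tr, i, windows$start[k]:windows$end[k]])
    }
    expect_lt(abs(Y[tr, k] - acc), 1e-12)
  }
  expect_equal(as.numeric(project_windows(array(0, dim = c(1, 3, 12)), model)),
               rep(0, 4))
  # identity row on one channel, single window: the channel's temporal mean
  m1 <- list(W = matrix(c(0, 1, 0), 1, 3), windows = make_windows(12, 1))
  expect_equal(as.numeric(project_windows(data, m1)),
               apply(data[, 2, ], 1, mean), tolerance = 1e-12)
  expect_error(project_windows(array(0, dim = c(1, 2, 12)), model),
               class = "rsvpauth_dimension_error")
})

test_that("temporal weights agree with a generic convex-optimizer oracle", {
  set.seed(21)
  n <- 400
  Y <- matrix(rnorm(n * 3), n, 3)
  y <- runif(n) < 0.5                     # labels independent of Y
  fit <- fit_temporal_weights(Y, y, penalty = 1e-2)
  obj <- function(beta) {
    eta <- beta[1] + Y %*% beta[-1]
    -sum(y * eta - log1p(exp(eta))) + 0.5 * 1e-2 * sum(beta[-1]^2)
  }
  oracle <- optim(rep(0, 4), obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-14))
  expect_equal(c(fit$intercept, fit$v), oracle$par, tolerance = 1e-4)
  expect_lt(max(abs(fit$v)), 0.3)         # near-null weights
})

test_that("temporal weights orient the user class upward and scale sanely", {
  Y <- matrix(c(rnorm(50, 2), rnorm(50, -2)), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 50)
  fit <- fit_temporal_weights(Y, y)
  s <- as.numeric(Y %*% fit$v) + fit$intercept
  expect_gt(mean(s[y]), mean(s[!y]))

  # duplicating every sample with a per-sample-scaled penalty changes nothing
  fit2 <- fit_temporal_weights(rbind(Y, Y), c(y, y), penalty = 2e-2)
  expect_equal(fit2$v, fit$v, tolerance = 1e-6)
  expect_equal(fit2$intercept, fit$intercept, tolerance = 1e-6)

  expect_error(fit_temporal_weights(Y, rep(TRUE, 100)),
               class = "rsvpauth_invalid_parameter")
})

test_that("separable data without penalty diverge with advice", {
  Y <- matrix(c(rep(1, 20), rep(-1, 20)), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 20)
  expect_error(fit_temporal_weights(Y, y, penalty = 0),
               class = "rsvpauth_separation_error")
  fit <- fit_temporal_weights(Y, y, penalty = 1e-2)  # default-penalty path
  expect_true(all(is.finite(fit$v)))
})

test_that("scores are affine in the feature and ties accept", {
  g <- gaussian_features(30, C = 3, S = 40, shift = 1.5, seed = 5)
  model <- fit_hdca(g$all, g$labels, n_windows = 4)
  f1 <- g$all[1, , , drop = FALSE]
  f2 <- g$all[31, , , drop = FALSE]
  s0 <- score_features(array(0, dim = dim(f1)), model)
  s12 <- score_features(f1 + f2, model)
  expect_equal(s12 - s0,
               (score_features(f1, model) - s0) +
                 (score_features(f2, model) - s0),
               tolerance = 1e-10)
  expect_true(decide(0, threshold = 0))   # boundary convention: accept
  expect_false(decide(-1e-12, threshold = 0))

  m0 <- model; m0$v <- rep(0, 4); m0$intercept <- 0
  expect_equal(score_features(f1, m0), 0)
  m_unfit <- model; m_unfit$v <- NULL
  expect_error(score_features(f1, m_unfit), class = "rsvpauth_unfitted_model")
})

test_that("one window and one channel reduce HDCA to logistic regression", {
  set.seed(31)
  n <- 60
  arr <- array(rnorm(n * 1 * 20), dim = c(n, 1, 20))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  arr[y, 1, ] <- arr[y, 1, ] + 1
  model <- fit_hdca(arr, y, n_windows = 1)
  means <- apply(arr[, 1, ], 1, mean)
  # direct penalized logistic fit on the epoch means (spatial stage is a
  # unit scalar here, up to sign)
  w <- as.numeric(model$W)
  direct <- fit_temporal_weights(matrix(w * means, ncol = 1), y)
  expect_equal(score_features(arr, model),
               as.numeric(w * means * direct$v + direct$intercept),
               tolerance = 1e-8)
})

test_that("scores are invariant to channel rotation when unregularized", {
  set.seed(41)
  n <- 80; C <- 4
  arr <- array(rnorm(n * C * 12), dim = c(n, C, 12))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  arr[y, 1, ] <- arr[y, 1, ] + 1
  Q <- qr.Q(qr(matrix(rnorm(C * C), C)))
  rot <- arr
  for (s in seq_len(12)) rot[, , s] <- arr[, , s] %*% t(Q)
  m1 <- fit_hdca(arr, y, n_windows = 3, shrinkage = 0)
  m2 <- fit_hdca(rot, y, n_windows = 3, shrinkage = 0)
  expect_equal(score_features(rot, m2), score_features(arr, m1),
               tolerance = 1e-8)
})

test_that("tidy and glance summarize fitted models", {
  g <- gaussian_features(20, C = 3, S = 40, shift = 1, seed = 6)
  model <- fit_hdca(g$all, g$labels, n_windows = 4)
  td <- tidy(model)
  expect_equal(nrow(td), 4 * 3)
  expect_true(all(c("window", "channel", "spatial_weight",
                    "temporal_weight") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_windows, 4)
  expect_equal(gl$peak_window, which.max(abs(model$v)))
})
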