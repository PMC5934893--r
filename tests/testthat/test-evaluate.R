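test_that("fold metrics follow the FAR/FRR/ACC accounting identities", {
  m <- rsvpauth:::fold_metrics(accept_user = rep(TRUE, 10),
                               accept_imposter = c(TRUE, rep(FALSE, 9)))
  expect_equal(m$far, 10)                  # 1 of 10 imposters accepted
  expect_equal(m$frr, 0)
  expect_equal(m$acc, 95)
  expect_equal(m$correct + m$false_accepts + m$false_rejects,
               m$n_user_test + m$n_imposter_test)
})

test_that("an always-accept classifier yields FAR 100, FRR 0, ACC 50", {
  g <- gaussian_features(30, shift = 0, seed = 2)
  cv <- crossvalidate(g$user, g$imposter, k = 5, repeats = 1, seed = 1,
                      selection = "none", threshold = -Inf)
  expect_true(all(cv$folds$far == 100))
  expect_true(all(cv$folds$frr == 0))
  expect_true(all(cv$folds$acc == 50))
})

test_that("cross-validation partitions each class exactly once per repeat", {
  g <- gaussian_features(40, shift = 1, seed = 3)
  cv <- crossvalidate(g$user, g$imposter, k = 5, repeats = 3, seed = 9,
                      selection = "none")
  expect_equal(nrow(cv$folds), 15)
  expect_true(all(cv$folds$n_user_test == 8))
  expect_true(all(cv$folds$n_imposter_test == 8))
  per_repeat <- dplyr::count(cv$scores, repeat_id)
  expect_true(all(per_repeat$n == 80))     # every sample tested once
  # accounting identity on every fold
  with(cv$folds, {
    expect_equal(acc, 100 * (1 - (false_accepts + false_rejects) /
                               (n_user_test + n_imposter_test)),
                 tolerance = 1e-12)
    expect_equal(far, 100 * false_accepts / n_imposter_test)
    expect_equal(frr, 100 * false_rejects / n_user_test)
  })
  expect_error(crossvalidate(g$user, g$imposter, k = 50, repeats = 1),
               class = "rsvpauth_invalid_parameter")
})

test_that("metrics are invariant to the ordering of test samples", {
  set.seed(5)
  scores <- rnorm(40)
  labels <- rep(c("user", "imposter"), 20)
  sw1 <- threshold_sweep(scores, labels, thresholds = c(-1, 0, 1))
  perm <- sample(40)
  sw2 <- threshold_sweep(scores[perm], labels[perm], thresholds = c(-1, 0, 1))
  expect_equal(sw1, sw2)
})

test_that("threshold sweep trades FAR against FRR monotonically", {
  set.seed(6)
  scores <- c(rnorm(50, 1), rnorm(50, -1))
  labels <- rep(c("user", "imposter"), each = 50)
  sw <- threshold_sweep(scores, labels)
  # thresholds descend: FAR must not decrease, FRR must not increase
  expect_true(all(diff(sw$far) >= 0))
  expect_true(all(diff(sw$frr) <= 0))
  expect_equal(sw$far[1], 0)               # +Inf threshold accepts no one
  expect_equal(sw$frr[1], 100)
})

test_that("separable classes cross-validate perfectly", {
  g <- gaussian_features(30, C = 4, S = 40, shift = 8, sd = 0.5, seed = 7)
  cv <- crossvalidate(g$user, g$imposter, k = 5, repeats = 2, seed = 4,
                      selection = "none")
  expect_true(all(cv$folds$acc == 100))
  expect_true(all(cv$folds$far == 0))
  expect_true(all(cv$folds$frr == 0))
})

test_that("training bundles authenticate a same-profile second session", {
  sched <- generate_schedule(n_blocks = 4, seed = 13)
  u <- quiet_profile(seed = 13)
  u$noise_pink_uV <- 2; u$noise_white_uV <- 1    # low-noise subject
  i1 <- make_subject_profile("imposter_scenario1", seed = 14,
                             config = profile_config(noise_pink_uV = 2,
                                                     noise_white_uV = 1))
  ep_u <- simulate_session_epochs(u, sched, rate_hz = 600, seed = 15)
  ep_i <- simulate_session_epochs(i1, sched, rate_hz = 600, seed = 16)
  bundle <- train_authenticator(ep_u, ep_i)
  expect_length(bundle$selected_channels, 6)

  ep_s2 <- simulate_session_epochs(u, sched, rate_hz = 600, seed = 17,
                                   session = 2)
  frr_same <- cross_session_frr(bundle, subject_features(ep_s2))
  expect_lte(frr_same, 10)

  other <- make_subject_profile("imposter_scenario2", seed = 18,
                                paired_user = u,
                                config = profile_config(noise_pink_uV = 2,
                                                        noise_white_uV = 1))
  ep_o2 <- simulate_session_epochs(other, sched, rate_hz = 600, seed = 19,
                                   session = 2)
  frr_other <- cross_session_frr(bundle, subject_features(ep_o2))
  expect_gte(frr_other, 90)

  empty <- subject_features(ep_s2)
  empty$data <- empty$data[0, , , drop = FALSE]
  expect_error(cross_session_frr(bundle, empty),
               class = "rsvpauth_invalid_parameter")
  wrong <- subject_features(ep_s2)
  wrong$channel_names <- paste0("X", seq_len(16))
  expect_error(cross_session_frr(bundle, wrong),
               class = "rsvpauth_channel_mismatch")
})

test_that("session correlation behaves as a Pearson coefficient", {
  set.seed(8)
  arr <- array(rnorm(20 * 3 * 10), dim = c(20, 3, 10))
  is_self <- rep(c(TRUE, FALSE), 10)
  ep1 <- manual_epochs(arr, is_self)
  expect_equal(session_correlation(ep1, ep1), 1)
  ep_neg <- manual_epochs(-arr, is_self)
  expect_equal(session_correlation(ep1, ep_neg), -1)
  ep_flat <- manual_epochs(array(1, dim = dim(arr)), is_self)
  expect_error(session_correlation(ep1, ep_flat),
               class = "rsvpauth_degenerate_input")
})

test_that("same-profile sessions correlate far above different profiles", {
  sched <- generate_schedule(seed = 23)
  res <- t(sapply(1:4, function(s) {
    u <- make_subject_profile("user", seed = 900 + s)
    other <- make_subject_profile("user", seed = 950 + s)
    ep1 <- simulate_session_epochs(u, sched, rate_hz = 600, seed = 910 + s)
    ep2 <- simulate_session_epochs(u, sched, rate_hz = 600, seed = 920 + s,
                                   session = 2)
    ep_o <- simulate_session_epochs(other, sched, rate_hz = 600,
                                    seed = 930 + s, session = 2)
    c(same = session_correlation(ep1, ep2, truth_channels),
      diff = session_correlation(ep1, ep_o, truth_channels))
  }))
  # permanence: the evoked signature is stable across sessions of one
  # subject and only weakly shared between subjects (common face response)
  expect_gt(mean(res[, "same"]), 0.65)
  expect_true(all(res[, "same"] > 0.45))
  expect_gt(mean(res[, "same"]), mean(res[, "diff"]) + 0.2)
})

test_that("scenario reports tabulate users plus aggregate rows", {
  per_user <- tidyr::expand_grid(user = sprintf("u%02d", 1:15),
                                 scenario = c(1, 2))
  set.seed(9)
  per_user$acc <- rnorm(30, 91, 2)
  per_user$far <- rnorm(30, 9, 2)
  per_user$frr <- rnorm(30, 8, 2)
  rep_tbl <- scenario_report(per_user)
  expect_equal(sum(rep_tbl$row_type == "user"), 30)
  m1 <- rep_tbl[rep_tbl$row_type == "mean" & !is.na(rep_tbl$scenario) &
                  rep_tbl$scenario == 1, ]
  expect_equal(m1$acc, mean(per_user$acc[per_user$scenario == 1]),
               tolerance = 1e-12)
  ens <- rep_tbl[rep_tbl$user == "ensemble-mean", ]
  expect_equal(ens$acc, mean(per_user$acc), tolerance = 1e-12)

  # a user missing one scenario is flagged and excluded from aggregates
  partial <- per_user[-1, ]
  rep2 <- scenario_report(partial)
  flagged <- rep2[rep2$row_type == "user" & !rep2$complete, ]
  expect_equal(nrow(flagged), 1)
  m1b <- rep2[rep2$row_type == "mean" & !is.na(rep2$scenario) &
                rep2$scenario == 1, ]
  expect_equal(m1b$acc, mean(partial$acc[partial$scenario == 1]),
               tolerance = 1e-12)
})
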