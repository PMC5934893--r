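# closed-form Chebyshev Type I magnitude at analog frequency ratio W,
# independent oracle for the designed filter's response
cheby_mag <- function(f_hz, fs, fp, ripple_db, n) {
  eps <- sqrt(10^(ripple_db / 10) - 1)
  W <- tan(pi * f_hz / fs) / tan(pi * fp / fs)   # bilinear-warped ratio
  Tn <- ifelse(W <= 1, cos(n * acos(pmin(W, 1))),
               cosh(n * acosh(pmax(W, 1))))
  1 / sqrt(1 + eps^2 * Tn^2)
}

test_that("low-pass design matches the analytic Chebyshev response", {
  spec <- filter_spec()
  flt <- rsvpauth:::design_cheby(spec, 2400)
  f <- c(0, 5, 20, 40, 44, 49, 60, 120)
  got <- Mod(rsvpauth:::filter_response(flt, 2 * pi * f / 2400))
  want <- cheby_mag(f, 2400, 40, spec$ripple_db, flt$n)
  expect_equal(got, want, tolerance = 1e-9)
  expect_lte(want[f == 49], 10^(-spec$atten_db / 20))  # stopband spec met
})

test_that("filtering preserves the passband and rejects the stopband", {
  t <- (0:47999) / 2400
  mk <- function(x) manual_recording(matrix(x, 1), 2400)
  mid <- 10000:38000
  r10 <- lowpass_filter(mk(sin(2 * pi * 10 * t)))
  # zero-phase pass squares the magnitude: within [ripple^2, 1]
  expect_gt(max(abs(r10$data[1, mid])), 10^(-2 * 0.5 / 20) - 0.01)
  expect_lt(max(abs(r10$data[1, mid])), 1.001)
  # zero phase: peak positions unmoved
  in10 <- sin(2 * pi * 10 * t)
  expect_lt(max(abs(r10$data[1, mid] - in10[mid] *
                      max(abs(r10$data[1, mid])))), 0.02)

  r60 <- lowpass_filter(mk(sin(2 * pi * 60 * t)))
  atten_db <- -20 * log10(max(abs(r60$data[1, mid])))
  expect_gte(atten_db, 40)                       # >= stopband attenuation
  # and matches the designed (squared) response itself
  flt <- rsvpauth:::design_cheby(filter_spec(), 2400)
  want <- Mod(rsvpauth:::filter_response(flt, 2 * pi * 60 / 2400))^2
  expect_lt(abs(max(abs(r60$data[1, mid])) - want), 0.15 * want)

  rdc <- lowpass_filter(mk(rep(1, 48000)))
  expect_equal(mean(rdc$data[1, mid]), 10^(-2 * 0.5 / 20), tolerance = 0.02)

  # causal single pass also meets the stopband, with nonzero delay allowed
  spec1 <- filter_spec(zero_phase = FALSE)
  r60c <- lowpass_filter(mk(sin(2 * pi * 60 * t)), spec1)
  expect_gte(-20 * log10(max(abs(r60c$data[1, mid]))), 40)
})

test_that("filter design errors are explicit", {
  expect_error(filter_spec(passband_hz = 50, stopband_hz = 49),
               class = "rsvpauth_invalid_parameter")
  expect_error(rsvpauth:::design_cheby(filter_spec(), 90),
               class = "rsvpauth_invalid_parameter")
})

test_that("downsampling averages consecutive sample blocks", {
  rec <- manual_recording(matrix(c(1, 2, 3, 4), 1), 2400)
  out <- downsample_by_averaging(rec, 4)
  expect_equal(as.numeric(out$data), 2.5)
  expect_equal(out$rate_hz, 600)

  rec2 <- manual_recording(matrix(rep(7, 100), 1), 2400)
  out2 <- downsample_by_averaging(rec2, 4)
  expect_equal(as.numeric(out2$data), rep(7, 25))

  # trailing remainder dropped
  rec3 <- manual_recording(matrix(1:10, 1), 100)
  expect_equal(ncol(downsample_by_averaging(rec3, 4)$data), 2)
  expect_error(downsample_by_averaging(rec3, 0),
               class = "rsvpauth_invalid_parameter")
})

test_that("downsampling commutes with channel permutation", {
  set.seed(2)
  rec <- manual_recording(matrix(rnorm(4 * 100), 4), 400)
  perm <- c(3, 1, 4, 2)
  a <- downsample_by_averaging(rec, 4)$data[perm, ]
  recp <- manual_recording(rec$data[perm, ], 400)
  b <- downsample_by_averaging(recp, 4)$data
  expect_equal(unname(a), unname(b))
})

test_that("epoching yields the paradigm's counts with baseline zeroed", {
  sched <- generate_schedule(n_blocks = 2, seed = 3)
  prof <- make_subject_profile("user", seed = 3)
  rec <- simulate_recording(prof, sched, rate_hz = 600, seed = 3)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data), c(200, 16, 720))
  expect_equal(sum(ep$labels$is_self), 20)
  # per-epoch, per-channel baseline mean is zero by construction
  bl <- rowMeans(ep$data[, , 1:120, drop = FALSE], dims = 2)
  expect_lt(max(abs(bl)), 1e-10)
})

test_that("epoching drops events without enough surrounding data, with count", {
  sched <- generate_schedule(1, 2, 10, inter_trial_gap_s = 0.5, seed = 1)
  prof <- manual_profile(white = 1)
  rec <- simulate_recording(prof, sched, rate_hz = 600, seed = 1,
                            lead_in_s = 0)  # first trial lacks baseline data
  expect_message(ep <- extract_epochs(rec), "dropped")
  expect_equal(dim(ep$data)[1] + ep$n_dropped, 20)
  expect_lt(dim(ep$data)[1], 20)
})

test_that("constant recordings epoch to all-zero after baseline correction", {
  sched <- generate_schedule(1, 1, 10, seed = 1)
  rec <- manual_recording(matrix(3.7, 2, 4000),
                          600, schedule = rsvpauth:::shift_schedule(sched, 1))
  ep <- extract_epochs(rec)
  expect_equal(max(abs(ep$data)), 0)
})

test_that("adjacent-trial averaging pairs trials as acquired", {
  arr <- array(rnorm(8 * 2 * 5), dim = c(8, 2, 5))
  f <- manual_features(arr)
  avg <- average_adjacent_trials(f)
  expect_equal(dim(avg$data), c(4, 2, 5))
  expect_equal(avg$data[1, , ], (arr[1, , ] + arr[2, , ]) / 2)
  expect_equal(avg$meta$trials[[3]], c(5L, 6L))

  # (x, x) -> x and (x, -x) -> 0
  two <- array(0, dim = c(2, 2, 5)); two[1, , ] <- arr[1, , ]
  two[2, , ] <- arr[1, , ]
  expect_equal(average_adjacent_trials(manual_features(two))$data[1, , ],
               arr[1, , ])
  two[2, , ] <- -arr[1, , ]
  expect_equal(max(abs(average_adjacent_trials(manual_features(two))$data)), 0)

  odd <- manual_features(arr[1:7, , , drop = FALSE])
  expect_warning(avg7 <- average_adjacent_trials(odd), "odd")
  expect_equal(dim(avg7$data)[1], 3)
  expect_error(average_adjacent_trials(manual_features(arr[1, , , drop = FALSE])),
               class = "rsvpauth_invalid_parameter")
})

test_that("200 single trials become 100 authentication units", {
  arr <- array(rnorm(200 * 3 * 10), dim = c(200, 3, 10))
  expect_equal(dim(average_adjacent_trials(manual_features(arr))$data)[1], 100)
})
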