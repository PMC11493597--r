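test_that("force steps are contiguous 50 N regions away from the boundary", {
  rate <- 1200
  zero <- sampled_signal(rep(0, 1000), rate, "N")
  expect_equal(nrow(detect_steps_grf(zero)), 0)

  # single embedded half-sine: duration matches the analytic 50 N crossings
  p <- half_sine_params(A = 2.5, Tc = 0.25)
  s <- embedded_stance(p, mass = 75, rate = rate)
  st <- detect_steps_grf(s)
  expect_equal(nrow(st), 1)
  dur <- (st$to_index - st$ic_index) / rate
  t1 <- (0.25 / pi) * asin(50 / (2.5 * 75 * 9.81))
  expect_lt(abs(dur - (0.25 - 2 * t1)), 2 / rate)

  # two stances separated by flight give exactly two ordered disjoint regions
  v2 <- c(rep(0, 100), s$values, rep(0, 100), s$values, rep(0, 100))
  st2 <- detect_steps_grf(sampled_signal(v2, rate, "N"))
  expect_equal(nrow(st2), 2)
  expect_true(st2$to_index[1] < st2$ic_index[2])
  for (i in 1:2) {
    expect_true(all(v2[st2$ic_index[i]:st2$to_index[i]] > 50))
  }
})

test_that("acceleration IC candidates must rise after and dip before contact", {
  rate <- 240
  flat <- sampled_signal(rep(0, 500), rate, "g")
  expect_equal(length(detect_ic_accel(flat)), 0)

  # a 0.18 g crossing that never rises to 0.5 g is rejected
  t <- seq(0, 2, by = 1 / rate)
  weak <- sampled_signal(-1 + 1.3 * exp(-(t - 1)^2 / (2 * 0.05^2)), rate, "g")
  expect_equal(length(detect_ic_accel(weak)), 0)

  # a proper contact: dip at -1 g before, rise above 0.5 g after
  strong <- sampled_signal(-1 + 2.2 * exp(-(t - 1)^2 / (2 * 0.05^2)), rate, "g")
  ics <- detect_ic_accel(strong)
  expect_equal(length(ics), 1)
  expect_gt(strong$values[ics], 0.18)
  expect_lte(strong$values[ics - 1], 0.18)
})

test_that("toe-off is the last downward -0.25 g crossing, with relaxation", {
  rate <- 240
  t <- seq(0, 1.5, by = 1 / rate)
  # one dip to -0.8 g between two contacts
  v <- 0.5 - 1.3 * exp(-(t - 0.75)^2 / (2 * 0.04^2))
  s <- sampled_signal(v, rate, "g")
  res <- detect_to_accel(s, 1L, length(v))
  # linear-scan oracle: last i with v[i] > -0.25 >= v[i+1]
  oracle <- max(which(v[-length(v)] > -0.25 & v[-1] <= -0.25)) + 1L
  expect_equal(res$to_index, oracle)
  expect_equal(res$threshold_g, -0.25)

  # shallow dip to -0.15 g found only after relaxing the threshold
  v2 <- 0.5 - 0.65 * exp(-(t - 0.75)^2 / (2 * 0.04^2))
  res2 <- detect_to_accel(sampled_signal(v2, rate, "g"), 1L, length(v2))
  expect_false(is.na(res2$to_index))
  expect_gt(res2$threshold_g, -0.25)

  # no dip below -0.04 g at all: unmatched after exhausting relaxation
  v3 <- 0.5 - 0.52 * exp(-(t - 0.75)^2 / (2 * 0.04^2))
  res3 <- detect_to_accel(sampled_signal(v3, rate, "g"), 1L, length(v3))
  expect_true(is.na(res3$to_index))

  expect_error(detect_to_accel(s, 10L, 10L), "next_ic_index")
})

test_that("step matching is one-to-one, tolerant and order-independent", {
  acc <- data.frame(ic_index = c(241, 481, 721), to_index = c(301, 541, 781),
                    rate = 240, source = "accel",
                    step_period_s = c(1, 1, 1), to_threshold_g = -0.25)
  grf <- data.frame(ic_index = (acc$ic_index - 1) * 5 + 1,
                    to_index = (acc$to_index - 1) * 5 + 1,
                    rate = 1200, source = "grf")
  m <- match_steps(acc, grf)
  expect_equal(nrow(m), 3)
  expect_equal(m$ic_dt_s, rep(0, 3))

  # an acceleration stance with no force stance within tolerance is dropped
  acc2 <- rbind(acc, data.frame(ic_index = 1201, to_index = 1261, rate = 240,
                                source = "accel", step_period_s = 1,
                                to_threshold_g = -0.25))
  m2 <- match_steps(acc2, grf)
  expect_equal(nrow(m2), 3)

  # reversing input row order changes nothing
  m3 <- match_steps(acc2[rev(seq_len(nrow(acc2))), ], grf[rev(seq_len(nrow(grf))), ])
  expect_equal(m3$accel_ic_index, m2$accel_ic_index)
  expect_equal(m3$grf_ic_index, m2$grf_ic_index)
})

test_that("step filtering enforces duration bounds and corruption heuristics", {
  rate <- 1000  # durations below are exact multiples of one sample
  durations <- c(0.15, 0.167, 0.3, 0.4, 0.41)
  # build one long BW signal holding five stances of the given durations
  vals <- c()
  ic <- to <- integer(0)
  for (d in durations) {
    vals <- c(vals, rep(0, 120))
    ic <- c(ic, length(vals) + 1L)
    vals <- c(vals, 2.4 * sin(pi * seq(0, 1, length.out = d * rate + 1)))
    to <- c(to, length(vals))
  }
  vals <- c(vals, rep(0, 120))
  bw <- sampled_signal(vals, rate, "BW")
  steps <- data.frame(accel_ic_index = ic, accel_to_index = to, accel_rate = rate,
                      grf_ic_index = ic, grf_to_index = to, grf_rate = rate,
                      ic_dt_s = 0, step_period_s = durations + 0.1)
  kept <- filter_steps(steps, bw)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$duration_s >= 0.167 & kept$duration_s <= 0.4))
  reasons <- attr(kept, "details")$filter_reason
  expect_equal(reasons[c(1, 5)], c("too_short", "too_long"))

  # NaN inside the stance window marks the step corrupted
  bw_nan <- bw
  bw_nan$values[ic[3] + 5] <- NaN
  expect_equal(nrow(filter_steps(steps, bw_nan)), 2)

  # a stance that never reaches 1.2 BW is flagged as fallen-away signal
  bw_low <- bw
  rng <- ic[3]:to[3]
  bw_low$values[rng] <- bw_low$values[rng] * 0.4
  kept_low <- filter_steps(steps, bw_low)
  expect_equal(attr(kept_low, "details")$filter_reason[3], "low_peak")
})

test_that("noiseless trials are recovered step for step across both sources", {
  cfg <- noiseless_config(n_subjects = 1, speeds = 2.78, duration = 12)
  co <- simulate_cohort(cfg)
  tr <- co$trials[[1]]
  rc <- run_config(cohort = cfg)
  pr <- process_trial(tr, rc)
  gt <- tr$ground_truth

  # every interior step matched (the trailing step has no next IC)
  expect_equal(nrow(pr$steps), nrow(gt) - 1)

  ic_det <- (pr$steps$accel_ic_index - 1) / pr$steps$accel_rate
  err <- vapply(ic_det, function(tt) min(abs(gt$accel_ic_time_s - tt)), numeric(1))
  expect_true(all(err <= 2 / 240))

  to_det <- (pr$steps$accel_to_index - 1) / pr$steps$accel_rate
  err_to <- vapply(to_det, function(tt) min(abs(gt$accel_to_time_s - tt)), numeric(1))
  expect_true(all(err_to <= 3 / 240))

  # force-side contact time (on the raw noiseless force) differs from truth
  # only by the analytic 50 N crossing offset
  raw_st <- detect_steps_grf(tr$grf)
  raw_dur <- (raw_st$to_index - raw_st$ic_index) / 1200
  ana <- gt$grf_to50_time_s - gt$grf_ic50_time_s
  expect_equal(length(raw_dur), nrow(gt))
  expect_true(all(abs(raw_dur - ana) <= 2 / 1200))
})
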