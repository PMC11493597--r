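test_that("acceleration plug-in inverts the dynamics in the trivial cases", {
  rate <- 240
  stances <- data.frame(ic_index = 11L, to_index = 70L, rate = rate,
                        source = "accel", step_period_s = 0.35,
                        to_threshold_g = -0.25)

  standing <- sampled_signal(rep(0, 100), rate, "g")
  est <- alcantara_characteristics(standing, 75, stances)
  expect_equal(est$est_active_peak_bw, 1)

  flight <- sampled_signal(rep(-1, 100), rate, "g")
  est2 <- alcantara_characteristics(flight, 75, stances)
  expect_equal(est2$est_active_peak_bw, 0)
  expect_equal(est2$est_impulse_bw_s, 0)
})

test_that("plug-in estimates recover true characteristics on noiseless steps", {
  cfg <- noiseless_config(n_subjects = 1, speeds = 2.78, duration = 10)
  co <- simulate_cohort(cfg)
  tr <- co$trials[[1]]
  pr <- process_trial(tr, run_config(cohort = cfg))
  gt <- tr$ground_truth

  est <- pr$est
  truth <- pr$characteristics
  # active peak from the acceleration curve equals the true active peak to
  # quadrature/filter precision
  expect_equal(est$est_active_peak_bw, truth$active_peak_bw, tolerance = 0.01)
  # impulse over the accel stance tracks the stance impulse (the windows
  # differ by the threshold offsets, so allow a coarser tolerance)
  expect_equal(est$est_impulse_bw_s, truth$impulse_bw_s, tolerance = 0.1)
})

test_that("plug-in characteristics commute with body-weight normalization", {
  cfg <- noiseless_config(n_subjects = 1, speeds = 2.78, duration = 6)
  tr <- simulate_cohort(cfg)$trials[[1]]
  pr <- process_trial(tr, run_config(cohort = cfg))
  a <- pr$accel_v
  m <- tr$subject$mass

  # computing in newtons then normalizing equals computing on (a + 1) directly
  est_bw <- alcantara_characteristics(a, m, pr$steps)
  curve_n <- pmax(m * GRAVITY_TEST * (a$values + 1), 0)
  i <- 1
  win <- curve_n[pr$steps$accel_ic_index[i]:pr$steps$accel_to_index[i]]
  expect_equal(max(win) / (m * GRAVITY_TEST), est_bw$est_active_peak_bw[i],
               tolerance = 1e-12)
})

test_that("plug-in regression is exact on linear targets and degenerates to the mean", {
  set.seed(20)
  n <- 60
  est <- data.frame(est_active_peak_bw = stats::rnorm(n, 2.4, 0.2),
                    est_contact_time_s = stats::rnorm(n, 0.26, 0.02),
                    est_impulse_bw_s = stats::rnorm(n, 0.37, 0.02),
                    est_step_frequency_hz = stats::rnorm(n, 2.8, 0.1))
  mass <- stats::rnorm(n, 74, 8)
  speed <- sample(c(2.22, 2.78), n, replace = TRUE)
  y <- 0.3 + 0.9 * est$est_active_peak_bw + 0.002 * mass + 0.05 * speed

  fit <- alcantara_regress(est, mass, speed, y, "active_peak")
  pred <- predict(fit, est, mass, speed)
  expect_equal(pred, y, tolerance = 1e-10)
  expect_equal(evaluate_predictions(pred, y)$r2, 1)

  # constant inputs: OLS reduces to the training mean
  est0 <- est; est0$est_active_peak_bw <- 2.4
  fit0 <- alcantara_regress(est0, rep(74, n), rep(2.78, n), y, "active_peak")
  expect_equal(predict(fit0, est0[1:5, ], rep(74, 5), rep(2.78, 5)),
               rep(mean(y), 5), tolerance = 1e-10)

  expect_error(alcantara_regress(est, mass, speed, y, "impact_peak"))
})

test_that("trunk CoM acceleration interpolates between neck and L5", {
  rate <- 240
  anthro <- anthropometric_model(trunk_com_fraction = 0.5)
  a <- sampled_signal(stats::rnorm(100), rate, "g")
  same <- trunk_com_acceleration(a, a, anthro)
  expect_equal(same$values, a$values)

  neck <- sampled_signal(rep(1, 100), rate, "g")
  l5 <- sampled_signal(rep(0, 100), rate, "g")
  expect_equal(trunk_com_acceleration(neck, l5, anthro)$values, rep(0.5, 100))

  # a linear acceleration field along the trunk: interpolation is exact at
  # any fraction
  f <- 0.4486
  anthro2 <- anthropometric_model(trunk_com_fraction = f)
  field <- function(pos) 2 - 3 * pos  # acceleration linear in position
  com <- trunk_com_acceleration(
    sampled_signal(rep(field(0), 10), rate, "g"),
    sampled_signal(rep(field(1), 10), rate, "g"), anthro2)
  expect_equal(com$values, rep(field(f), 10))

  short <- sampled_signal(rep(0, 50), rate, "g")
  expect_error(trunk_com_acceleration(neck, short, anthro), "mismatch")
})

test_that("segment-curve impact peaks scale with the trunk mass fraction", {
  expect_error(anthropometric_model(trunk_mass_fraction = 1.2), "trunk_mass_fraction")

  # idealized channels: no noise, no filtering, accelerometer at the force
  # rate, trunk channels equal to the whole-body acceleration
  cfg <- cohort_config(n_subjects = 2, speeds = c(2.22, 2.78), trial_duration = 10,
                       noise_sd_accel = 0, noise_sd_grf = 0, accel_rate = 1200,
                       impact_probability = 1, seed = 27)
  co <- simulate_cohort(cfg)
  anthro <- anthropometric_model()
  est_all <- c(); truth_all <- c()
  for (key in names(co$trials)) {
    tr <- co$trials[[key]]
    stances <- detect_steps_grf(tr$grf)
    stances$step_period_s <- c(diff(stances$ic_index), NA) / 1200
    bw <- normalize_to_bw(tr$grf, tr$subject$mass)
    truth <- vapply(seq_len(nrow(stances)), function(i) {
      impact_peak(bw$values[stances$ic_index[i]:stances$to_index[i]])
    }, numeric(1))
    a_com <- trunk_com_acceleration(tr$accel_neck_v, tr$accel_l5_v, anthro)
    est <- veras_impact_peak(a_com, anthro, stances)
    ii <- !is.na(est) & !is.na(truth)
    est_all <- c(est_all, est[ii])
    truth_all <- c(truth_all, truth[ii])
  }
  expect_gt(length(est_all), 20)
  # trunk channels equal the whole-body acceleration here, so the regression
  # slope of truth on estimate approximates 1 / trunk_mass_fraction
  slope <- stats::coef(stats::lm(truth_all ~ est_all))[2]
  expect_equal(unname(slope), 1 / anthro$trunk_mass_fraction, tolerance = 0.1)

  # flight: segment curve is zero
  flight <- sampled_signal(rep(-1, 100), 240, "g")
  st <- data.frame(ic_index = 10L, to_index = 60L, rate = 240, source = "accel",
                   step_period_s = 0.35, to_threshold_g = -0.25)
  seg <- pmax(anthro$trunk_mass_fraction * (flight$values + 1), 0)
  expect_true(all(seg == 0))
  expect_true(is.na(veras_impact_peak(flight, anthro, st)))
})

test_that("degenerate trunk fraction reproduces the whole-body estimate", {
  cfg <- noiseless_config(n_subjects = 1, speeds = 2.78, duration = 6)
  tr <- simulate_cohort(cfg)$trials[[1]]
  pr <- process_trial(tr, run_config(cohort = cfg))
  anthro1 <- anthropometric_model(trunk_mass_fraction = 0.999999)
  a <- pr$accel_v
  seg <- pmax(anthro1$trunk_mass_fraction * (a$values + 1), 0)
  whole <- pmax(a$values + 1, 0)
  expect_equal(seg, whole, tolerance = 1e-5)
})
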