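# shared fixtures built in code

default_mass <- 75

make_subject <- function(id = "S01", mass = default_mass, leg = 0.92, pref = 2.9) {
  subject_info(id, mass, leg, pref)
}

# a plain half-sine stance (no impact bump)
half_sine_params <- function(A = 2.5, Tc = 0.25, period = Tc + 0.11) {
  stance_params(A, contact_time = Tc, step_period = period)
}

# a stance with a distinct early impact bump
bump_params <- function(A = 2.4, I = 0.9, f = 0.05, w = 0.005, Tc = 0.26,
                        period = Tc + 0.11) {
  stance_params(A, I, f, w, Tc, period)
}

# embed one stance in flight padding and return the N-signal plus the offset
# (the stance starts exactly at `pad_s`, aligned to the sampling grid)
embedded_stance <- function(params, mass = default_mass, rate = 1200, pad_s = 0.2) {
  t <- seq(0, 2 * pad_s + params$contact_time, by = 1 / rate)
  sampled_signal(mass * GRAVITY_TEST * stance_force_bw(t - pad_s, params),
                 rate, "N", "grf")
}

GRAVITY_TEST <- 9.81

# steady-state amplitude of a sine in a filtered signal: least-squares fit of
# sin/cos at the known frequency over the central half of the record
fitted_amplitude <- function(values, rate, freq) {
  n <- length(values)
  idx <- seq.int(floor(n / 4), ceiling(3 * n / 4))
  t <- (idx - 1) / rate
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- stats::lm.fit(X, values[idx])$coefficients
  sqrt(sum(cf^2))
}

# small noiseless cohort reused by event-recovery tests
noiseless_config <- function(n_subjects = 2, speeds = c(2.22, 3.33),
                             duration = 15, seed = 31) {
  cohort_config(n_subjects = n_subjects, speeds = speeds,
                trial_duration = duration, noise_sd_accel = 0,
                noise_sd_grf = 0, seed = seed)
}

# independent trapezoid rule used as a quadrature oracle in tests
trapz_test <- function(v, rate) {
  n <- length(v)
  (sum(v) - (v[1] + v[n]) / 2) / rate
}
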