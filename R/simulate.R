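#' Subject metadata
#'
#' @param subject_id Unique subject identifier (string).
#' @param mass Body mass in kg (> 0).
#' @param leg_length Leg length in m, hip-to-ground during standing (> 0).
#' @param preferred_speed Self-selected running speed in m/s (> 0).
#' @return A `subject_info` list.
#' @export
subject_info <- function(subject_id, mass, leg_length, preferred_speed) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    stop("invariant violated: subject_id must be a non-empty string", call. = FALSE)
  }
  for (nm in c("mass", "leg_length", "preferred_speed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("invariant violated: %s must be strictly positive", nm), call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id, mass = mass, leg_length = leg_length,
                 preferred_speed = preferred_speed), class = "subject_info")
}

#' Per-step stance-phase parameters
#'
#' Parameters of the synthetic stance-phase vGRF waveform: a half-sine active
#' component of amplitude `active_peak` over the contact time, plus an optional
#' Gaussian impact bump of amplitude `impact_amp` centred at
#' `impact_frac * contact_time` with width (SD) `impact_width`.
#'
#' The waveform, normalized to body weight, is
#' \deqn{F(t)/mg = A \sin(\pi t / T_c) + I \exp(-(t - f T_c)^2 / (2 w^2)),
#'   \quad t \in [0, T_c].}
#'
#' @param active_peak Half-sine amplitude A in BW (> 0).
#' @param impact_amp Gaussian bump amplitude I in BW, or `NA` for no impact
#'   bump; must be smaller than `active_peak` when present.
#' @param impact_frac Bump centre as a fraction f of stance, in (0, 0.10].
#' @param impact_width Bump width w in s (> 0).
#' @param contact_time Stance duration T_c in s (> 0). Values outside
#'   [0.167, 0.4] s are permitted here and flagged downstream by the step
#'   filter, mirroring how out-of-range stances are handled in measured data.
#' @param step_period Initial-contact to next initial-contact duration in s;
#'   must exceed `contact_time`.
#' @return A `stance_params` list.
#' @export
stance_params <- function(active_peak, impact_amp = NA_real_, impact_frac = NA_real_,
                          impact_width = NA_real_, contact_time, step_period) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invariant violated: ", msg, call. = FALSE)
  chk(is.numeric(active_peak) && is.finite(active_peak) && active_peak > 0,
      "active_peak must be > 0")
  chk(is.numeric(contact_time) && is.finite(contact_time) && contact_time > 0,
      "contact_time must be > 0")
  chk(is.numeric(step_period) && is.finite(step_period) && step_period > contact_time,
      "step_period must exceed contact_time")
  has_impact <- !is.na(impact_amp)
  if (has_impact) {
    chk(impact_amp > 0, "impact_amp must be > 0 when present")
    chk(active_peak > impact_amp, "active_peak must exceed impact_amp")
    chk(is.finite(impact_frac) && impact_frac > 0 && impact_frac <= 0.10,
        "impact_frac must lie in (0, 0.10]")
    chk(is.finite(impact_width) && impact_width > 0, "impact_width must be > 0")
  }
  structure(list(active_peak = active_peak,
                 impact_amp = if (has_impact) impact_amp else NA_real_,
                 impact_frac = if (has_impact) impact_frac else NA_real_,
                 impact_width = if (has_impact) impact_width else NA_real_,
                 contact_time = contact_time, step_period = step_period),
            class = "stance_params")
}

#' Cohort simulation configuration
#'
#' Defaults describe the treadmill protocol the simulator emulates: several
#' fixed belt speeds per subject, force plate at 1200 Hz, sacral accelerometer
#' at 240 Hz, and an impact peak on roughly 41\% of steps.
#'
#' @param n_subjects Number of subjects.
#' @param speeds Belt speeds in m/s (defaults span 2.22--3.33 m/s).
#' @param trial_duration Trial length in s.
#' @param grf_rate Force-plate sampling rate in Hz.
#' @param accel_rate Accelerometer sampling rate in Hz.
#' @param noise_sd_accel Additive i.i.d. Gaussian noise SD on acceleration
#'   channels, in g.
#' @param noise_sd_grf Additive i.i.d. Gaussian noise SD on the force signal,
#'   in N.
#' @param impact_probability Per-step probability of an impact bump, in [0, 1].
#' @param gravity_subtracted Logical; if `TRUE` (default) acceleration channels
#'   use the gravity-subtracted convention (flight = -1 g, standing = 0 g), the
#'   convention under which the 0.18 g / -0.25 g event thresholds operate.
#' @param seed Integer seed; all randomness derives from it via named
#'   sub-streams, split per subject and trial.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 20L,
                          speeds = c(2.22, 2.50, 2.78, 3.33),
                          trial_duration = 30,
                          grf_rate = 1200,
                          accel_rate = 240,
                          noise_sd_accel = 0.05,
                          noise_sd_grf = 5,
                          impact_probability = 0.41,
                          gravity_subtracted = TRUE,
                          seed = 1L) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invariant violated: ", msg, call. = FALSE)
  chk(n_subjects >= 1, "n_subjects must be >= 1")
  chk(length(speeds) >= 1 && all(speeds > 0), "speeds must be positive")
  chk(grf_rate > 0 && accel_rate > 0, "sampling rates must be > 0")
  chk(trial_duration > 0, "trial_duration must be > 0")
  chk(impact_probability >= 0 && impact_probability <= 1,
      "impact_probability must lie in [0, 1]")
  chk(noise_sd_accel >= 0 && noise_sd_grf >= 0, "noise SDs must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), speeds = speeds,
                 trial_duration = trial_duration, grf_rate = grf_rate,
                 accel_rate = accel_rate, noise_sd_accel = noise_sd_accel,
                 noise_sd_grf = noise_sd_grf,
                 impact_probability = impact_probability,
                 gravity_subtracted = isTRUE(gravity_subtracted),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Continuous stance waveform, normalized to body weight
#'
#' Evaluates the stance-phase vGRF model (half-sine active component plus
#' optional Gaussian impact bump) at arbitrary times; zero outside
#' `[0, contact_time]` and clipped at zero.
#'
#' @param t Times in s (stance-local, 0 = initial contact).
#' @param params A [stance_params()] object.
#' @return vGRF in BW at each `t`.
#' @export
stance_force_bw <- function(t, params) {
  Tc <- params$contact_time
  f <- numeric(length(t))
  inside <- t >= 0 & t <= Tc
  ti <- t[inside]
  v <- params$active_peak * sin(pi * ti / Tc)
  if (!is.na(params$impact_amp)) {
    v <- v + params$impact_amp *
      exp(-(ti - params$impact_frac * Tc)^2 / (2 * params$impact_width^2))
  }
  f[inside] <- pmax(v, 0)
  f
}

#' Sampled stance-phase vGRF in newtons
#'
#' @param params A [stance_params()] object.
#' @param mass Body mass in kg (> 0).
#' @param rate Sampling rate in Hz.
#' @return A `sampled_signal` in N covering `[0, contact_time]`.
#' @export
simulate_stance_vgrf <- function(params, mass, rate) {
  stopifnot(inherits(params, "stance_params"))
  if (!is.numeric(mass) || mass <= 0) stop("invariant violated: mass must be > 0", call. = FALSE)
  t <- seq(0, params$contact_time, by = 1 / rate)
  sampled_signal(mass * GRAVITY * stance_force_bw(t, params), rate, "N", "stance_vgrf")
}

#' Closed-form stance impulse of the simulated waveform
#'
#' The half-sine integrates to \eqn{2 A T_c / \pi}; the Gaussian bump adds
#' \eqn{I w \sqrt{2\pi} [\Phi((T_c - f T_c)/w) - \Phi(-f T_c / w)]}, the exact
#' boundary-truncated Gaussian mass.
#'
#' @param params A [stance_params()] object.
#' @return Impulse in BW·s.
#' @export
closed_form_impulse <- function(params) {
  Tc <- params$contact_time
  imp <- 2 * params$active_peak * Tc / pi
  if (!is.na(params$impact_amp)) {
    mu <- params$impact_frac * Tc
    w <- params$impact_width
    imp <- imp + params$impact_amp * w * sqrt(2 * pi) *
      (stats::pnorm((Tc - mu) / w) - stats::pnorm(-mu / w))
  }
  imp
}

# local maxima indices of a vector (first difference changes sign + to -)
local_maxima_idx <- function(v) {
  d <- diff(v)
  which(d[-length(d)] > 0 & d[-1] < 0) + 1L
}

# prominence of peak i: drop from v[i] to the lowest point before the curve
# next exceeds v[i] (scanning forward); standard "forward valley" rule
peak_prominence_forward <- function(v, i) {
  n <- length(v)
  if (i >= n) return(0)
  after <- v[(i + 1L):n]
  exceed <- which(after > v[i])
  stop_at <- if (length(exceed)) exceed[1L] else length(after)
  v[i] - min(after[seq_len(stop_at)])
}

#' Analytic peak structure of a simulated stance
#'
#' Computes, from the continuous waveform on a fine grid with local
#' refinement: the active peak (global maximum) value and time, and the first
#' prominent local maximum within the impact window (the "true" impact peak),
#' if any.
#'
#' @param params A [stance_params()] object.
#' @param window_frac Impact window as a fraction of stance (default 0.10).
#' @param prominence Minimum prominence in BW for the impact peak (default 0.05).
#' @param grid_n Number of fine-grid points (default 20000).
#' @return List with `active_peak`, `active_time`, `impact_present`,
#'   `impact_peak` (NA when absent) and `impact_time`.
#' @export
stance_peak_info <- function(params, window_frac = 0.10, prominence = 0.05,
                             grid_n = 3000L) {
  Tc <- params$contact_time
  t <- seq(0, Tc, length.out = grid_n)
  v <- stance_force_bw(t, params)
  opt <- stats::optimize(function(tt) stance_force_bw(tt, params),
                         c(0.25 * Tc, 0.75 * Tc), maximum = TRUE,
                         tol = 1e-10)
  lm_idx <- local_maxima_idx(v)
  win_idx <- lm_idx[t[lm_idx] <= window_frac * Tc]
  impact_peak <- NA_real_
  impact_time <- NA_real_
  for (i in win_idx) {
    if (peak_prominence_forward(v, i) >= prominence) {
      # refine the apex between neighbouring grid points
      lo <- t[max(i - 1L, 1L)]; hi <- t[min(i + 1L, grid_n)]
      ref <- stats::optimize(function(tt) stance_force_bw(tt, params),
                             c(lo, hi), maximum = TRUE, tol = 1e-10)
      impact_peak <- ref$objective
      impact_time <- ref$maximum
      break
    }
  }
  list(active_peak = opt$objective, active_time = opt$maximum,
       impact_present = !is.na(impact_peak),
       impact_peak = impact_peak, impact_time = impact_time)
}

#' Analytic threshold-crossing times of a simulated stance
#'
#' First upward and last downward crossing times of the continuous normalized
#' waveform at a given level, located on a fine grid and refined with
#' `uniroot`. These are the event times that threshold-based detectors (50 N
#' on force, +0.18 g / -0.25 g on acceleration) estimate.
#'
#' @param params A [stance_params()] object.
#' @param level_bw Threshold level in BW (for acceleration thresholds in the
#'   gravity-subtracted convention, a threshold of `a` g corresponds to
#'   `1 + a` BW).
#' @param grid_n Number of fine-grid points (default 20000).
#' @return List with `first_up` and `last_down` times in s (NA if no crossing).
#' @export
stance_threshold_crossings <- function(params, level_bw, grid_n = 3000L) {
  Tc <- params$contact_time
  t <- seq(0, Tc, length.out = grid_n)
  v <- stance_force_bw(t, params) - level_bw
  up <- which(v[-length(v)] <= 0 & v[-1] > 0)
  dn <- which(v[-length(v)] > 0 & v[-1] <= 0)
  refine <- function(i) {
    stats::uniroot(function(tt) stance_force_bw(tt, params) - level_bw,
                   lower = t[i], upper = t[i + 1L], tol = 1e-10)$root
  }
  list(first_up = if (length(up)) refine(up[1L]) else NA_real_,
       last_down = if (length(dn)) refine(dn[length(dn)]) else NA_real_)
}

#' Vertical acceleration implied by a vGRF signal
#'
#' Whole-body dynamics: the centre-of-mass vertical acceleration in
#' gravity-subtracted g units is \eqn{a(t) = F(t)/(m g) - 1}, so flight phases
#' map to -1 g and quiet standing at body weight maps to 0 g.
#'
#' @param vgrf A `sampled_signal` in N (nonnegative).
#' @param mass Body mass in kg (> 0).
#' @return A `sampled_signal` in g units at the same rate.
#' @export
derive_vertical_acceleration <- function(vgrf, mass) {
  stopifnot(inherits(vgrf, "sampled_signal"))
  if (vgrf$units != "N") stop("unit error: vgrf must be in N", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0) stop("invariant violated: mass must be > 0", call. = FALSE)
  sampled_signal(vgrf$values / (mass * GRAVITY) - 1, vgrf$rate, "g", "accel_v")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# all per-step ground-truth quantities from one shared fine-grid evaluation
step_ground_truth <- function(p, mass, grid_n = 1500L) {
  Tc <- p$contact_time
  t <- seq(0, Tc, length.out = grid_n)
  v <- stance_force_bw(t, p)
  cross <- function(level) {
    d <- v - level
    up <- which(d[-length(d)] <= 0 & d[-1] > 0)
    dn <- which(d[-length(d)] > 0 & d[-1] <= 0)
    refine <- function(i) {
      stats::uniroot(function(tt) stance_force_bw(tt, p) - level,
                     lower = t[i], upper = t[i + 1L], tol = 1e-9)$root
    }
    c(if (length(up)) refine(up[1L]) else NA_real_,
      if (length(dn)) refine(dn[length(dn)]) else NA_real_)
  }
  pk <- stance_peak_info(p, grid_n = grid_n)
  c50 <- cross(50 / (mass * GRAVITY))
  cic <- cross(1 + 0.18)
  cto <- cross(1 - 0.25)
  list(peaks = pk, grf50 = c50, accel_ic = cic[1L], accel_to = cto[2L])
}

#' Draw per-step stance parameters
#'
#' Step-to-step variation around speed- and subject-dependent means: contact
#' time decreases and the active peak increases with running speed (linear
#' trends), with subject random intercepts supplied through `subject_effects`.
#' Impact bumps occur independently per step with probability
#' `impact_probability`, with amplitude, timing and width chosen so the bump
#' forms a distinct local maximum inside the first 10\% of stance (a detectable
#' impact peak by construction).
#'
#' @param n Number of steps to draw.
#' @param speed Running speed in m/s.
#' @param impact_probability Per-step probability of an impact bump.
#' @param subject_effects List with `peak_shift` (BW) and `ct_shift` (s)
#'   subject-level offsets; defaults to zero.
#' @return List of [stance_params()] objects. Uses the current RNG state.
#' @export
draw_stance_params <- function(n, speed, impact_probability = 0.41,
                               subject_effects = list(peak_shift = 0, ct_shift = 0)) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    A <- clamp(stats::rnorm(1, 2.44 + 0.25 * (speed - 2.9) + subject_effects$peak_shift, 0.06),
               1.8, 3.2)
    Tc <- clamp(stats::rnorm(1, 0.26 - 0.05 * (speed - 2.9) + subject_effects$ct_shift, 0.006),
                0.18, 0.38)
    flight <- clamp(stats::rnorm(1, 0.10 + 0.02 * (speed - 2.9), 0.006), 0.05, 0.2)
    if (stats::runif(1) < impact_probability) {
      # bump amplitude scales with the carrier's steepness (A / T_c) so the
      # impact transient stays a distinct shoulder across speeds -- impact
      # peaks grow with running speed, as observed in treadmill cohorts
      rel <- clamp(stats::rnorm(1, 0.60, 0.05), 0.45, 0.72)
      I <- min(rel * A * 0.26 / Tc, 0.65 * A)
      w <- min(0.0055, 0.026 * Tc)
      t_apex <- stats::runif(1, 2.8 * w, 0.078 * Tc)
      out[[i]] <- stance_params(A, I, t_apex / Tc, w, Tc, Tc + flight)
    } else {
      out[[i]] <- stance_params(A, contact_time = Tc, step_period = Tc + flight)
    }
  }
  out
}

#' Draw a cohort's subjects
#'
#' Subject-level latent traits (mass, leg length, preferred speed, and the
#' random intercepts shifting peak magnitude and contact time) persist across
#' all of a subject's trials, so subject-level data splitting is meaningful.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per subject, including the latent effects.
#' @export
draw_subjects <- function(config) {
  set.seed(sub_seed(config$seed, "subjects"))
  n <- config$n_subjects
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    mass_kg = round(clamp(stats::rnorm(n, 74.0, 11.9), 48, 108), 1),
    leg_length_m = round(clamp(stats::rnorm(n, 0.92, 0.05), 0.75, 1.10), 3),
    preferred_speed_ms = round(clamp(stats::rnorm(n, 2.9, 0.3), 2.3, 3.8), 2),
    peak_shift_bw = stats::rnorm(n, 0, 0.12),
    ct_shift_s = stats::rnorm(n, 0, 0.012),
    stringsAsFactors = FALSE
  )
}

# assemble continuous force (BW) of a sequence of steps onto a sampling grid
steps_force_bw <- function(step_starts, params_list, rate, n_samples) {
  f <- numeric(n_samples)
  for (k in seq_along(params_list)) {
    p <- params_list[[k]]
    i0 <- max(ceiling(step_starts[k] * rate) + 1L, 1L)
    i1 <- min(floor((step_starts[k] + p$contact_time) * rate) + 1L, n_samples)
    if (i1 >= i0) {
      tt <- (seq.int(i0, i1) - 1L) / rate - step_starts[k]
      f[i0:i1] <- f[i0:i1] + stance_force_bw(tt, p)
    }
  }
  f
}

#' Simulate one trial from explicit per-step parameters
#'
#' Lays out the given stances back-to-back (each step occupies its
#' `step_period`, stance first then flight), starting after an initial flight
#' phase, and renders force-plate and accelerometer channels plus the exact
#' per-step ground truth.
#'
#' @param subject A [subject_info()] object.
#' @param speed Trial speed in m/s.
#' @param config A [cohort_config()].
#' @param params_list List of [stance_params()] for the steps, in order.
#' @param initial_flight Lead-in flight time in s before the first contact.
#' @return A `trial_record` list with elements `subject`, `speed`, `grf` (N),
#'   `accel_v`, `accel_ap`, `accel_ml`, `accel_neck_v`, `accel_l5_v` (g) and
#'   `ground_truth` (data frame, one row per step). Uses the current RNG state
#'   for the noise draws.
#' @export
simulate_trial_from_params <- function(subject, speed, config, params_list,
                                       initial_flight = 0.15) {
  stopifnot(inherits(subject, "subject_info"), inherits(config, "cohort_config"))
  if (length(params_list) < 1L) {
    stop("trial too short: no complete step fits in trial_duration", call. = FALSE)
  }
  dur <- config$trial_duration
  starts <- initial_flight + cumsum(c(0, vapply(params_list, `[[`, 0, "step_period")))
  starts <- starts[seq_along(params_list)]

  n_grf <- floor(dur * config$grf_rate) + 1L
  n_acc <- floor(dur * config$accel_rate) + 1L
  f_grf <- steps_force_bw(starts, params_list, config$grf_rate, n_grf)
  f_acc <- steps_force_bw(starts, params_list, config$accel_rate, n_acc)

  m <- subject$mass
  grf <- m * GRAVITY * f_grf + stats::rnorm(n_grf, 0, config$noise_sd_grf)
  base_acc <- if (config$gravity_subtracted) f_acc - 1 else f_acc
  nz <- function(n) if (config$noise_sd_accel > 0) stats::rnorm(n, 0, config$noise_sd_accel) else numeric(n)
  accel_v <- base_acc + nz(n_acc)
  accel_ap <- nz(n_acc)
  accel_ml <- nz(n_acc)
  accel_neck <- base_acc + nz(n_acc)
  accel_l5 <- base_acc + nz(n_acc)

  gts <- lapply(params_list, step_ground_truth, mass = m)
  gcol <- function(f) vapply(gts, f, numeric(1))
  gt <- data.frame(
    step_index = seq_along(params_list),
    ic_time_s = starts,
    to_time_s = starts + vapply(params_list, `[[`, 0, "contact_time"),
    contact_time_s = vapply(params_list, `[[`, 0, "contact_time"),
    step_period_s = vapply(params_list, `[[`, 0, "step_period"),
    active_peak_bw = gcol(function(g) g$peaks$active_peak),
    impact_present = vapply(gts, function(g) g$peaks$impact_present, logical(1)),
    impact_peak_bw = gcol(function(g) g$peaks$impact_peak),
    impulse_bw_s = vapply(params_list, closed_form_impulse, numeric(1)),
    grf_ic50_time_s = starts + gcol(function(g) g$grf50[1L]),
    grf_to50_time_s = starts + gcol(function(g) g$grf50[2L]),
    accel_ic_time_s = starts + gcol(function(g) g$accel_ic),
    accel_to_time_s = starts + gcol(function(g) g$accel_to)
  )

  structure(list(
    subject = subject, speed = speed,
    grf = sampled_signal(grf, config$grf_rate, "N", "grf"),
    accel_v = sampled_signal(accel_v, config$accel_rate, "g", "accel_v"),
    accel_ap = sampled_signal(accel_ap, config$accel_rate, "g", "accel_ap"),
    accel_ml = sampled_signal(accel_ml, config$accel_rate, "g", "accel_ml"),
    accel_neck_v = sampled_signal(accel_neck, config$accel_rate, "g", "accel_neck_v"),
    accel_l5_v = sampled_signal(accel_l5, config$accel_rate, "g", "accel_l5_v"),
    ground_truth = gt
  ), class = "trial_record")
}

#' Simulate one trial
#'
#' Draws per-step stance parameters until the trial duration is filled (a step
#' counts when its full IC-to-next-IC period fits) and renders the trial. The
#' RNG stream is derived from the config seed, the subject id and the speed,
#' so trials are reproducible independently of cohort size.
#'
#' @param subject A [subject_info()] object.
#' @param speed Trial speed in m/s.
#' @param config A [cohort_config()].
#' @param subject_effects Optional list with `peak_shift`, `ct_shift`.
#' @return A `trial_record`; see [simulate_trial_from_params()].
#' @export
simulate_trial <- function(subject, speed, config,
                           subject_effects = list(peak_shift = 0, ct_shift = 0)) {
  set.seed(sub_seed(config$seed, paste0("trial:", subject$subject_id, ":", speed)))
  initial_flight <- 0.15
  params_list <- list()
  t <- initial_flight
  repeat {
    p <- draw_stance_params(1, speed, config$impact_probability, subject_effects)[[1L]]
    if (t + p$step_period > config$trial_duration) break
    params_list[[length(params_list) + 1L]] <- p
    t <- t + p$step_period
  }
  if (length(params_list) == 0L) {
    stop("trial too short: no complete step fits in trial_duration", call. = FALSE)
  }
  simulate_trial_from_params(subject, speed, config, params_list, initial_flight)
}

#' Simulate a cohort
#'
#' One trial per (subject, speed) pair. Subject latent traits persist across
#' that subject's trials.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_sim` list with `subjects` (data frame), `trials` (list of
#'   `trial_record`), and `ground_truth` (combined data frame with
#'   `subject_id` and `speed` columns prepended).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- draw_subjects(config)
  trials <- list()
  gt_all <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    subj <- subject_info(s$subject_id, s$mass_kg, s$leg_length_m, s$preferred_speed_ms)
    eff <- list(peak_shift = s$peak_shift_bw, ct_shift = s$ct_shift_s)
    for (sp in config$speeds) {
      tr <- simulate_trial(subj, sp, config, eff)
      key <- paste(s$subject_id, format(sp), sep = "@")
      trials[[key]] <- tr
      gt_all[[key]] <- cbind(subject_id = s$subject_id, speed = sp, tr$ground_truth)
    }
  }
  structure(list(subjects = subjects, trials = trials,
                 ground_truth = do.call(rbind, c(gt_all, list(make.row.names = FALSE))),
                 config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects x %d speeds = %d trials, %d steps total\n",
              nrow(x$subjects), length(x$config$speeds), length(x$trials),
              nrow(x$ground_truth)))
  invisible(x)
}
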