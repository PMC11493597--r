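#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase, so event timing is preserved). Edge transients are suppressed
#' with odd-reflection padding of length `3 * order` samples at each end.
#' Because the filter runs twice, the effective magnitude response is
#' `|H(f)|^2`: unity at DC and 1/2 at the cutoff frequency.
#'
#' Defaults mirror the preprocessing conventions used for force-plate and
#' accelerometer data: order 5, with 30 Hz cutoff for force and 60 Hz for
#' acceleration.
#'
#' @param x A `sampled_signal`.
#' @param order Filter order (default 5).
#' @param cutoff Cutoff frequency in Hz; must lie in (0, rate/2).
#' @return Filtered `sampled_signal`, same length, rate and units.
#' @export
butterworth_lowpass <- function(x, order = 5L, cutoff) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= x$rate / 2) {
    stop("parameter error: cutoff must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(order, 2 * cutoff / x$rate, type = "low")
  v <- x$values
  n <- length(v)
  npad <- min(3L * order, n - 1L)
  front <- 2 * v[1L] - v[(npad + 1L):2L]
  back <- 2 * v[n] - v[(n - 1L):(n - npad)]
  ext <- c(front, v, back)
  # one pass with the filter started in steady state at the signal's first
  # level, so constants pass through exactly (unit DC gain)
  run <- function(z) {
    z0 <- z[1L]
    as.numeric(signal::filter(bf$b, bf$a, z,
                              init.x = rep(z0, length(bf$b) - 1L),
                              init.y = rep(z0, length(bf$a) - 1L)))
  }
  y <- rev(run(rev(run(ext))))
  out <- x
  out$values <- y[(npad + 1L):(npad + n)]
  out
}

#' Normalize a force signal to body weight
#'
#' @param grf A `sampled_signal` in N.
#' @param mass Body mass in kg (> 0); g = 9.81 m/s^2 exactly.
#' @return A `sampled_signal` in BW.
#' @export
normalize_to_bw <- function(grf, mass) {
  stopifnot(inherits(grf, "sampled_signal"))
  if (grf$units != "N") stop("unit error: input must be in N", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0) stop("invariant violated: mass must be > 0", call. = FALSE)
  out <- grf
  out$values <- grf$values / (mass * GRAVITY)
  out$units <- "BW"
  out
}

#' Resample a signal by linear interpolation
#'
#' Interpolates onto a uniform grid at `target_rate` over the common time
#' support; endpoints are preserved and degree-1 signals are reproduced
#' exactly.
#'
#' @param x A `sampled_signal`.
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return A `sampled_signal` at `target_rate`.
#' @export
resample_to <- function(x, target_rate) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("parameter error: target_rate must be > 0", call. = FALSE)
  }
  if (isTRUE(all.equal(target_rate, x$rate))) return(x)
  t_old <- signal_times(x)
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate)
  out <- x
  out$values <- stats::approx(t_old, x$values, xout = t_new)$y
  out$rate <- target_rate
  out
}

trial_csv_columns <- c("time_s", "grf_n", "accel_v_g", "accel_ap_g", "accel_ml_g")
trial_csv_optional <- c("accel_neck_v_g", "accel_l5_v_g")

#' Write a trial to long-form CSV
#'
#' One row per sample time; the force channel and the acceleration channels
#' keep their own sampling grids, so each row carries values only for the
#' channels sampled at that time (others are empty). Columns: `time_s`,
#' `grf_n`, `accel_v_g`, `accel_ap_g`, `accel_ml_g` and, when present,
#' `accel_neck_v_g`, `accel_l5_v_g`.
#'
#' @param record A `trial_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(record, path) {
  stopifnot(inherits(record, "trial_record"))
  t_grf <- signal_times(record$grf)
  t_acc <- signal_times(record$accel_v)
  has_trunk <- !is.null(record$accel_neck_v)
  na_ <- function(n) rep(NA_real_, n)
  df_grf <- data.frame(time_s = t_grf, grf_n = record$grf$values,
                       accel_v_g = na_(length(t_grf)), accel_ap_g = na_(length(t_grf)),
                       accel_ml_g = na_(length(t_grf)))
  df_acc <- data.frame(time_s = t_acc, grf_n = na_(length(t_acc)),
                       accel_v_g = record$accel_v$values,
                       accel_ap_g = record$accel_ap$values,
                       accel_ml_g = record$accel_ml$values)
  if (has_trunk) {
    df_grf$accel_neck_v_g <- na_(nrow(df_grf)); df_grf$accel_l5_v_g <- na_(nrow(df_grf))
    df_acc$accel_neck_v_g <- record$accel_neck_v$values
    df_acc$accel_l5_v_g <- record$accel_l5_v$values
  }
  df <- rbind(df_grf, df_acc)
  df <- df[order(df$time_s, is.na(df$grf_n)), , drop = FALSE]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# pull one channel (rows where the column is non-missing) and infer its rate
extract_channel <- function(df, col, units, label) {
  keep <- !is.na(df[[col]])
  if (sum(keep) < 2L) return(NULL)
  tt <- df$time_s[keep]
  rate <- 1 / stats::median(diff(tt))
  sampled_signal(df[[col]][keep], rate, units, label)
}

#' Read a trial from long-form CSV
#'
#' Inverse of [write_trial()]. Subject metadata and speed are supplied
#' separately (they live in the cohort metadata table).
#'
#' @param path CSV path.
#' @param subject A [subject_info()] (optional).
#' @param speed Trial speed in m/s (optional).
#' @return A `trial_record` (without ground truth).
#' @export
read_trial <- function(path, subject = NULL, speed = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- trial_csv_columns
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), c(required, trial_csv_optional))
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  rec <- list(
    subject = subject, speed = speed,
    grf = extract_channel(df, "grf_n", "N", "grf"),
    accel_v = extract_channel(df, "accel_v_g", "g", "accel_v"),
    accel_ap = extract_channel(df, "accel_ap_g", "g", "accel_ap"),
    accel_ml = extract_channel(df, "accel_ml_g", "g", "accel_ml"),
    accel_neck_v = if ("accel_neck_v_g" %in% names(df))
      extract_channel(df, "accel_neck_v_g", "g", "accel_neck_v") else NULL,
    accel_l5_v = if ("accel_l5_v_g" %in% names(df))
      extract_channel(df, "accel_l5_v_g", "g", "accel_l5_v") else NULL,
    ground_truth = NULL
  )
  structure(rec, class = "trial_record")
}

#' Write a simulated cohort to a directory
#'
#' Writes one trial CSV per (subject, speed), a `metadata.csv` cohort table
#' (`subject_id`, `mass_kg`, `leg_length_m`, `speed_ms`, `trial_path`) and a
#' `ground_truth.csv` with the exact per-step characteristics and event times.
#'
#' @param cohort A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (key in names(cohort$trials)) {
    tr <- cohort$trials[[key]]
    fn <- paste0("trial_", gsub("[@.]", "_", key), ".csv")
    write_trial(tr, file.path(dir, fn))
    meta[[key]] <- data.frame(subject_id = tr$subject$subject_id,
                              mass_kg = tr$subject$mass,
                              leg_length_m = tr$subject$leg_length,
                              speed_ms = tr$speed, trial_path = fn,
                              stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, c(meta, list(make.row.names = FALSE))),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  out_gt <- data.frame(subject_id = gt$subject_id, speed = gt$speed,
                       step_index = gt$step_index, ic_time_s = gt$ic_time_s,
                       to_time_s = gt$to_time_s, active_peak_bw = gt$active_peak_bw,
                       impact_peak_bw = gt$impact_peak_bw,
                       impulse_bw_s = gt$impulse_bw_s,
                       contact_time_s = gt$contact_time_s)
  utils::write.csv(out_gt, file.path(dir, "ground_truth.csv"), row.names = FALSE, na = "")
  invisible(dir)
}
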