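#' Subject-specific features
#'
#' @param subject A [subject_info()] object.
#' @return Named numeric vector: `mass_kg`, `leg_length_m`.
#' @export
subject_features <- function(subject) {
  stopifnot(inherits(subject, "subject_info"))
  if (is.null(subject$leg_length) || is.na(subject$leg_length)) {
    stop("required field missing: leg_length", call. = FALSE)
  }
  c(mass_kg = subject$mass, leg_length_m = subject$leg_length)
}

#' Domain-specific features of one step
#'
#' Step frequency (reciprocal of the IC-to-next-IC period) and the trapezoidal
#' impulse of the vertical acceleration over the stance window and over the
#' entire step.
#'
#' @param accel_v A `sampled_signal` in g (filtered).
#' @param ic_index,to_index Acceleration-detected stance bounds (samples).
#' @param step_period_s IC-to-next-IC period in s.
#' @return Named numeric vector: `step_frequency_hz`, `accel_impulse_stance`,
#'   `accel_impulse_step`.
#' @export
domain_features <- function(accel_v, ic_index, to_index, step_period_s) {
  stopifnot(inherits(accel_v, "sampled_signal"))
  n <- length(accel_v$values)
  end_step <- min(ic_index + round(step_period_s * accel_v$rate), n)
  c(step_frequency_hz = 1 / step_period_s,
    accel_impulse_stance = trapz_rate(accel_v$values[ic_index:to_index], accel_v$rate),
    accel_impulse_step = trapz_rate(accel_v$values[ic_index:end_step], accel_v$rate))
}

# tsfresh-style autocorrelation at lag l (overall mean/variance normalization)
autocorr_lag <- function(v, l) {
  n <- length(v)
  if (l >= n) return(0)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 == 0) return(0)
  sum((v[1:(n - l)] - m) * (v[(l + 1):n] - m)) / ((n - l) * s2)
}

#' General time-series features of one window
#'
#' A frozen, deterministic catalogue of descriptors (catalogue version
#' `"v1"`): mean, SD, min, max, median, skewness, kurtosis, RMS, absolute
#' energy, number of mean-crossings, autocorrelation at lags 1/5/10, dominant
#' DFT frequency (Hz) and its magnitude, linear-trend slope, and window
#' duration. Spectral features are reported in Hz, and the duration feature in
#' seconds, so values are comparable across windows of different lengths.
#'
#' @param values Numeric window (>= 4 samples).
#' @param rate Sampling rate in Hz.
#' @param prefix Feature-name prefix, typically the axis label.
#' @return Named numeric vector of features.
#' @export
general_ts_features <- function(values, rate, prefix = "x") {
  v <- as.numeric(values)
  n <- length(v)
  if (n < 4L) stop("window too short: need at least 4 samples", call. = FALSE)
  m <- mean(v)
  centered <- v - m
  s2 <- mean(centered^2)

  # mean-crossings: sign changes of the mean-centred signal (zeros dropped)
  sg <- sign(centered)
  sg <- sg[sg != 0]
  crossings <- if (length(sg) > 1L) sum(diff(sg) != 0) else 0

  # dominant non-DC DFT component
  X <- stats::fft(v)
  kmax <- floor(n / 2)
  if (kmax >= 1L) {
    mags <- 2 * Mod(X[2:(kmax + 1L)]) / n
    kbest <- which.max(mags)
    dom_hz <- kbest * rate / n
    dom_mag <- mags[kbest]
  } else {
    dom_hz <- 0; dom_mag <- 0
  }

  t <- (seq_len(n) - 1) / rate
  slope <- if (stats::var(t) > 0) stats::cov(t, v) / stats::var(t) else 0

  feats <- c(
    mean = m,
    sd = sqrt(s2),
    min = min(v),
    max = max(v),
    median = stats::median(v),
    skewness = if (s2 > 0) e1071::skewness(v, type = 1) else 0,
    kurtosis = if (s2 > 0) e1071::kurtosis(v, type = 1) else 0,
    rms = sqrt(mean(v^2)),
    abs_energy = sum(v^2),
    mean_crossings = crossings,
    autocorr_lag1 = autocorr_lag(v, 1L),
    autocorr_lag5 = autocorr_lag(v, 5L),
    autocorr_lag10 = autocorr_lag(v, 10L),
    domfreq_hz = dom_hz,
    domfreq_mag = dom_mag,
    trend_slope = slope,
    duration_s = n / rate
  )
  names(feats) <- paste(prefix, names(feats), sep = "_")
  feats
}

#' Per-step feature table for one trial
#'
#' Assembles subject, domain and general time-series features (all three
#' acceleration axes) for every retained step of a trial. General features
#' use the acceleration-detected stance window when `window_kind = "stance"`,
#' or the IC-to-next-IC window when `window_kind = "entire_step"`.
#'
#' @param trial A `trial_record` (filtered acceleration channels).
#' @param steps Data frame from [filter_steps()].
#' @param window_kind `"stance"` or `"entire_step"`.
#' @param include_speed Logical; add the trial speed as a feature.
#' @return Data frame keyed by `subject_id`, `speed`, `step_index`, one
#'   feature per remaining column; feature categories (subject / general /
#'   domain / speed) in attribute `"categories"`; `window_kind` in attribute
#'   `"window_kind"`.
#' @export
trial_feature_table <- function(trial, steps, window_kind = c("stance", "entire_step"),
                                include_speed = FALSE) {
  window_kind <- match.arg(window_kind)
  stopifnot(inherits(trial, "trial_record"))
  sf <- subject_features(trial$subject)
  axes <- list(accel_v = trial$accel_v, accel_ap = trial$accel_ap,
               accel_ml = trial$accel_ml)
  n_sig <- length(trial$accel_v$values)
  rows <- vector("list", nrow(steps))
  for (i in seq_len(nrow(steps))) {
    ic <- steps$accel_ic_index[i]
    to <- steps$accel_to_index[i]
    end <- if (window_kind == "stance") to else
      min(ic + round(steps$step_period_s[i] * trial$accel_v$rate), n_sig)
    df <- domain_features(trial$accel_v, ic, to, steps$step_period_s[i])
    gen <- unlist(lapply(names(axes), function(ax) {
      general_ts_features(axes[[ax]]$values[ic:end], axes[[ax]]$rate, prefix = ax)
    }))
    feats <- c(sf, df, gen)
    if (include_speed) feats <- c(feats, speed_ms = trial$speed)
    rows[[i]] <- feats
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(subject_id = trial$subject$subject_id, speed = trial$speed,
                    step_index = seq_len(nrow(steps)), mat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  cats <- c(rep("subject", length(sf)), rep("domain", 3L),
            rep("general", ncol(mat) - length(sf) - 3L - as.integer(include_speed)),
            if (include_speed) "speed")
  names(cats) <- colnames(mat)
  attr(out, "categories") <- cats
  attr(out, "window_kind") <- window_kind
  out
}

feature_key_cols <- c("subject_id", "speed", "step_index")

#' Clean a feature table
#'
#' Drops feature columns containing any missing value or taking a single
#' constant value, and one-hot encodes categorical (character or factor)
#' feature columns. Key columns are exempt.
#'
#' @param table Feature data frame (keyed by `subject_id`, `speed`,
#'   `step_index`).
#' @return Cleaned data frame; dropped column names in attribute `"dropped"`,
#'   updated categories in `"categories"`.
#' @export
clean_features <- function(table) {
  cats <- attr(table, "categories")
  keys <- intersect(feature_key_cols, names(table))
  feat_cols <- setdiff(names(table), keys)

  # one-hot encode categorical features first
  for (col in feat_cols) {
    x <- table[[col]]
    if (is.character(x) || is.factor(x)) {
      lv <- sort(unique(as.character(x)))
      for (l in lv) {
        nm <- paste(col, l, sep = "_")
        table[[nm]] <- as.numeric(as.character(x) == l)
        if (!is.null(cats)) cats[nm] <- cats[[col]]
      }
      table[[col]] <- NULL
      cats <- cats[names(cats) != col]
    }
  }
  feat_cols <- setdiff(names(table), keys)

  dropped <- character(0)
  for (col in feat_cols) {
    x <- table[[col]]
    if (anyNA(x) || length(unique(x)) <= 1L) {
      dropped <- c(dropped, col)
      table[[col]] <- NULL
    }
  }
  attr(table, "dropped") <- dropped
  attr(table, "categories") <- cats[setdiff(names(cats), dropped)]
  table
}

#' Fit a standardization scaler on training rows
#'
#' Per-column z-score parameters (mean and population SD) computed on the
#' training table only; one-hot indicator columns (0/1-valued) are exempt.
#'
#' @param train Cleaned feature data frame (training rows only).
#' @return A `feature_scaler` with `center`, `scale` and `exempt` columns.
#' @export
fit_scaler <- function(train) {
  keys <- intersect(feature_key_cols, names(train))
  feat_cols <- setdiff(names(train), keys)
  is_indicator <- vapply(feat_cols, function(col) {
    all(train[[col]] %in% c(0, 1))
  }, logical(1))
  num_cols <- feat_cols[!is_indicator]
  center <- vapply(num_cols, function(col) mean(train[[col]]), numeric(1))
  scale <- vapply(num_cols, function(col) {
    sqrt(mean((train[[col]] - mean(train[[col]]))^2))
  }, numeric(1))
  structure(list(center = center, scale = scale,
                 exempt = feat_cols[is_indicator]),
            class = "feature_scaler")
}

#' Apply a standardization scaler
#'
#' Columns whose training SD was zero cannot be standardized and are dropped
#' with a warning.
#'
#' @param table Feature data frame.
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @return Standardized data frame.
#' @export
apply_scaler <- function(table, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  zero_sd <- names(scaler$scale)[scaler$scale == 0]
  if (length(zero_sd)) {
    warning("dropping zero-variance column(s) in training fold: ",
            paste(zero_sd, collapse = ", "), call. = FALSE)
  }
  for (col in names(scaler$center)) {
    if (col %in% zero_sd) {
      table[[col]] <- NULL
    } else if (col %in% names(table)) {
      table[[col]] <- (table[[col]] - scaler$center[[col]]) / scaler$scale[[col]]
    }
  }
  table
}

#' Standardize train and further tables with a train-fitted scaler
#'
#' @param train Training feature table (cleaned).
#' @param ... Further tables (validation / test) transformed with the same
#'   scaler.
#' @return List with `train`, `others` (list) and `scaler`.
#' @export
standardize_features <- function(train, ...) {
  scaler <- fit_scaler(train)
  list(train = apply_scaler(train, scaler),
       others = lapply(list(...), apply_scaler, scaler = scaler),
       scaler = scaler)
}
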