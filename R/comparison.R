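#' Trunk anthropometric model
#'
#' Trunk segment mass as a fraction of body mass and the trunk
#' centre-of-mass position as a fraction of the neck-to-L5 segment length from
#' the cranial end. Defaults follow standard anthropometric tables.
#'
#' @param trunk_mass_fraction Fraction of body mass in (0, 1) (default 0.4346).
#' @param trunk_com_fraction CoM position fraction in (0, 1) (default 0.4486).
#' @return An `anthropometric_model` list.
#' @export
anthropometric_model <- function(trunk_mass_fraction = 0.4346,
                                 trunk_com_fraction = 0.4486) {
  for (nm in c("trunk_mass_fraction", "trunk_com_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("invariant violated: ", nm, " must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(list(trunk_mass_fraction = trunk_mass_fraction,
                 trunk_com_fraction = trunk_com_fraction),
            class = "anthropometric_model")
}

#' Acceleration-derived step characteristics (sacral plug-in method)
#'
#' Estimates the vGRF as the product of sacral acceleration and body mass --
#' in the gravity-subtracted convention, \eqn{\hat F(t) = m g (a(t) + 1)},
#' clipped at zero -- and computes the active peak, contact time, impulse and
#' step frequency on that curve over the acceleration-detected stances with
#' the same operators used for the force-plate ground truth.
#'
#' @param accel_v A `sampled_signal` in g (filtered, gravity-subtracted).
#' @param mass Body mass in kg.
#' @param stances Data frame of acceleration-detected stances
#'   ([detect_stances_accel()] or the `accel_*` columns of matched steps).
#' @return Data frame: `est_active_peak_bw`, `est_contact_time_s`,
#'   `est_impulse_bw_s`, `est_step_frequency_hz`, one row per stance.
#' @export
alcantara_characteristics <- function(accel_v, mass, stances) {
  stopifnot(inherits(accel_v, "sampled_signal"))
  if (accel_v$units != "g") stop("unit error: input must be in g", call. = FALSE)
  est_bw <- pmax(accel_v$values + 1, 0)
  ic <- if ("accel_ic_index" %in% names(stances)) stances$accel_ic_index else stances$ic_index
  to <- if ("accel_to_index" %in% names(stances)) stances$accel_to_index else stances$to_index
  n <- nrow(stances)
  out <- data.frame(est_active_peak_bw = NA_real_, est_contact_time_s = NA_real_,
                    est_impulse_bw_s = NA_real_, est_step_frequency_hz = NA_real_)
  out <- out[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    win <- est_bw[ic[i]:to[i]]
    out$est_active_peak_bw[i] <- active_peak(win)
    out$est_contact_time_s[i] <- contact_time(ic[i], to[i], accel_v$rate)
    out$est_impulse_bw_s[i] <- stance_impulse(win, accel_v$rate)
    out$est_step_frequency_hz[i] <- 1 / stances$step_period_s[i]
  }
  out
}

# which estimated characteristic feeds which target
alcantara_feature_for <- c(active_peak = "est_active_peak_bw",
                           contact_time = "est_contact_time_s",
                           impulse = "est_impulse_bw_s")

#' Linear-regression comparison model on acceleration-derived characteristics
#'
#' Ordinary least squares of a target on its matched acceleration-derived
#' characteristic plus body mass and speed. Supports the active peak, contact
#' time and impulse targets (the impact peak is handled by
#' [veras_impact_peak()]).
#'
#' @param est Data frame from [alcantara_characteristics()] (training rows).
#' @param mass Per-row body mass in kg.
#' @param speed Per-row speed in m/s.
#' @param y Training target values.
#' @param target One of `"active_peak"`, `"contact_time"`, `"impulse"`.
#' @return An `alcantara_model` (wrapping an `lm` fit).
#' @export
alcantara_regress <- function(est, mass, speed, y, target) {
  target <- match.arg(target, names(alcantara_feature_for))
  feat <- alcantara_feature_for[[target]]
  df <- data.frame(est = est[[feat]], mass = mass, speed = speed, y = y)
  fit <- stats::lm(y ~ est + mass + speed, data = df)
  structure(list(fit = fit, target = target, feature = feat),
            class = "alcantara_model")
}

#' @export
predict.alcantara_model <- function(object, est, mass, speed, ...) {
  nd <- data.frame(est = est[[object$feature]], mass = mass, speed = speed)
  as.numeric(stats::predict(object$fit, newdata = nd))
}

#' Trunk centre-of-mass acceleration
#'
#' Linear interpolation between the acceleration at the base of the neck and
#' at the base of the L5 disc, at the trunk CoM fraction from the cranial end:
#' \eqn{a_{com}(t) = (1 - f) a_{neck}(t) + f a_{L5}(t)}.
#'
#' @param accel_neck_v,accel_l5_v `sampled_signal`s in g, time-aligned and
#'   equal length.
#' @param anthro An [anthropometric_model()].
#' @return A `sampled_signal` in g.
#' @export
trunk_com_acceleration <- function(accel_neck_v, accel_l5_v, anthro) {
  stopifnot(inherits(accel_neck_v, "sampled_signal"),
            inherits(accel_l5_v, "sampled_signal"),
            inherits(anthro, "anthropometric_model"))
  if (length(accel_neck_v$values) != length(accel_l5_v$values) ||
      accel_neck_v$rate != accel_l5_v$rate) {
    stop("length/rate mismatch between neck and L5 channels", call. = FALSE)
  }
  f <- anthro$trunk_com_fraction
  sampled_signal((1 - f) * accel_neck_v$values + f * accel_l5_v$values,
                 accel_neck_v$rate, "g", "accel_trunk_com")
}

#' Segment-curve impact-peak estimates (trunk-segment method)
#'
#' Builds the single-segment force curve \eqn{S(t) = m_{trunk} g (a_{com}(t)
#' + 1)}, expressed in multiples of total body weight, and extracts its impact
#' peak over each stance with the same impact-peak operator used for the
#' ground truth. Steps without a detectable segment-curve impact peak are
#' returned as `NA` (excluded from the regression).
#'
#' @param a_com Trunk CoM acceleration (`sampled_signal`, g).
#' @param anthro An [anthropometric_model()].
#' @param stances Acceleration-detected stances (as in
#'   [alcantara_characteristics()]).
#' @param window_frac,prominence_bw Impact-peak settings; the prominence scale
#'   is the segment curve's own (default `0.05 * trunk_mass_fraction`).
#' @return Numeric vector of estimated impact peaks in BW (of the segment
#'   curve), `NA` where none was found.
#' @export
veras_impact_peak <- function(a_com, anthro, stances, window_frac = 0.10,
                              prominence_bw = NULL) {
  stopifnot(inherits(a_com, "sampled_signal"), inherits(anthro, "anthropometric_model"))
  if (is.null(prominence_bw)) prominence_bw <- 0.05 * anthro$trunk_mass_fraction
  seg_bw <- pmax(anthro$trunk_mass_fraction * (a_com$values + 1), 0)
  ic <- if ("accel_ic_index" %in% names(stances)) stances$accel_ic_index else stances$ic_index
  to <- if ("accel_to_index" %in% names(stances)) stances$accel_to_index else stances$to_index
  vapply(seq_len(nrow(stances)), function(i) {
    impact_peak(seg_bw[ic[i]:to[i]], window_frac, prominence_bw)
  }, numeric(1))
}

#' OLS mapping from segment-curve impact peaks to vGRF impact peaks
#'
#' @param est Estimated segment-curve impact peaks (training rows; `NA`s are
#'   dropped together with their targets).
#' @param y True vGRF impact peaks.
#' @return A `veras_model` (wrapping an `lm` fit).
#' @export
veras_regress <- function(est, y) {
  keep <- !is.na(est) & !is.na(y)
  fit <- stats::lm(y ~ est, data = data.frame(est = est[keep], y = y[keep]))
  structure(list(fit = fit), class = "veras_model")
}

#' @export
predict.veras_model <- function(object, est, ...) {
  as.numeric(stats::predict(object$fit, newdata = data.frame(est = est)))
}
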