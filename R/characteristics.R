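#' Active peak of a stance
#'
#' The maximum of the normalized vGRF over the stance window. The impact
#' region is not excluded: by definition the impact peak is the smaller of
#' the two maxima, so the global maximum is the active peak.
#'
#' @param stance_vgrf Numeric vector (stance window) or a `sampled_signal` in BW.
#' @return Active peak in BW.
#' @export
active_peak <- function(stance_vgrf) {
  v <- if (inherits(stance_vgrf, "sampled_signal")) stance_vgrf$values else stance_vgrf
  if (length(v) == 0L) stop("empty stance window", call. = FALSE)
  max(v)
}

#' Impact peak of a stance
#'
#' The value at the first local maximum (strict sign change of the first
#' difference) whose index lies within the first `window_frac` of the stance
#' samples and whose prominence -- the drop to the lowest point before the
#' signal next exceeds it -- is at least `prominence_bw`. Returns `NA` when no
#' such maximum exists (no impact peak on this step).
#'
#' @param stance_vgrf Numeric vector (stance window) or a `sampled_signal` in BW.
#' @param window_frac Fraction of stance searched (default 0.10).
#' @param prominence_bw Minimum prominence in BW (default 0.05).
#' @return Impact peak in BW, or `NA_real_` when absent.
#' @export
impact_peak <- function(stance_vgrf, window_frac = 0.10, prominence_bw = 0.05) {
  v <- if (inherits(stance_vgrf, "sampled_signal")) stance_vgrf$values else stance_vgrf
  n <- length(v)
  if (n < 3L) return(NA_real_)
  idx <- local_maxima_idx(v)
  idx <- idx[idx <= ceiling(window_frac * n)]
  for (i in idx) {
    if (peak_prominence_forward(v, i) >= prominence_bw) return(v[i])
  }
  NA_real_
}

#' Stance impulse
#'
#' Trapezoidal time-integral of the normalized vGRF over the stance window.
#'
#' @param stance_vgrf Numeric vector (stance window) or `sampled_signal` in BW.
#' @param rate Sampling rate in Hz (taken from the signal when omitted).
#' @return Impulse in BW·s.
#' @export
stance_impulse <- function(stance_vgrf, rate = NULL) {
  if (inherits(stance_vgrf, "sampled_signal")) {
    rate <- stance_vgrf$rate
    v <- stance_vgrf$values
  } else {
    v <- stance_vgrf
    if (is.null(rate)) stop("rate must be supplied for a bare vector", call. = FALSE)
  }
  trapz_rate(v, rate)
}

#' Contact time of a stance interval
#'
#' @param ic_index Initial-contact sample index.
#' @param to_index Toe-off sample index (must exceed `ic_index`).
#' @param rate Sampling rate in Hz.
#' @return Contact time in s.
#' @export
contact_time <- function(ic_index, to_index, rate) {
  if (!(to_index > ic_index)) {
    stop("precondition violated: to_index must exceed ic_index", call. = FALSE)
  }
  (to_index - ic_index) / rate
}

#' Per-step vGRF characteristics of filtered steps
#'
#' Applies the four characteristic operators to the force-detected stance
#' window of each retained step.
#'
#' @param steps Data frame from [filter_steps()] (or [match_steps()]).
#' @param vgrf_bw The trial's force signal in BW.
#' @param window_frac,prominence_bw Impact-peak settings, see [impact_peak()].
#' @return Data frame with `step_index`, `active_peak_bw`, `impact_peak_bw`
#'   (`NA` = absent), `impulse_bw_s`, `contact_time_s`.
#' @export
extract_characteristics <- function(steps, vgrf_bw, window_frac = 0.10,
                                    prominence_bw = 0.05) {
  stopifnot(inherits(vgrf_bw, "sampled_signal"))
  if (vgrf_bw$units != "BW") stop("unit error: vgrf must be in BW", call. = FALSE)
  n <- nrow(steps)
  out <- data.frame(step_index = seq_len(n), active_peak_bw = NA_real_,
                    impact_peak_bw = NA_real_, impulse_bw_s = NA_real_,
                    contact_time_s = NA_real_)
  for (i in seq_len(n)) {
    win <- vgrf_bw$values[steps$grf_ic_index[i]:steps$grf_to_index[i]]
    out$active_peak_bw[i] <- active_peak(win)
    out$impact_peak_bw[i] <- impact_peak(win, window_frac, prominence_bw)
    out$impulse_bw_s[i] <- stance_impulse(win, vgrf_bw$rate)
    out$contact_time_s[i] <- contact_time(steps$grf_ic_index[i],
                                          steps$grf_to_index[i], vgrf_bw$rate)
  }
  out
}
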