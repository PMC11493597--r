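#' Detect stance intervals from the force signal
#'
#' One stance interval per contiguous region where the (filtered,
#' un-normalized) vGRF exceeds the 50 N threshold: the initial contact is the
#' first sample above threshold, the toe-off the last. Regions touching the
#' signal boundary are discarded as incomplete.
#'
#' @param vgrf A `sampled_signal` in N.
#' @param threshold_n Step-detection threshold in N (default 50).
#' @return Data frame of stance intervals: `ic_index`, `to_index`, `rate`,
#'   `source = "grf"` (possibly zero rows).
#' @export
detect_steps_grf <- function(vgrf, threshold_n = 50) {
  stopifnot(inherits(vgrf, "sampled_signal"))
  if (vgrf$units != "N") stop("unit error: input must be in N", call. = FALSE)
  above <- vgrf$values > threshold_n
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(vgrf$values)
  data.frame(ic_index = starts[keep], to_index = ends[keep],
             rate = rep(vgrf$rate, sum(keep)),
             source = rep("grf", sum(keep)), stringsAsFactors = FALSE)
}

#' Detect initial contacts from vertical acceleration
#'
#' Candidate initial contacts are upward crossings of the +0.18 g threshold on
#' the filtered, gravity-subtracted vertical acceleration. A candidate is kept
#' only if (i) the signal rises to at least `rise_g` within `rise_window_s`
#' after the crossing (the expected post-contact increase), (ii) the signal
#' was at or below 0 g at some point within `pre_window_s` before it (the
#' expected pre-contact decrease), and (iii) it is separated from the previous
#' retained contact by at least `refractory_s`.
#'
#' @param accel_v A `sampled_signal` in g.
#' @param threshold_g IC threshold in g (default 0.18).
#' @param rise_g Required post-crossing rise in g (default 0.5).
#' @param rise_window_s Window for the rise constraint in s (default 0.10).
#' @param pre_window_s Window for the pre-contact constraint in s (default 0.10).
#' @param refractory_s Minimum separation between contacts in s (default 0.2).
#' @return Integer vector of IC sample indices (first sample above threshold).
#' @export
detect_ic_accel <- function(accel_v, threshold_g = 0.18, rise_g = 0.5,
                            rise_window_s = 0.10, pre_window_s = 0.10,
                            refractory_s = 0.2) {
  stopifnot(inherits(accel_v, "sampled_signal"))
  if (accel_v$units != "g") stop("unit error: input must be in g", call. = FALSE)
  v <- accel_v$values
  n <- length(v)
  cand <- which(v[-n] <= threshold_g & v[-1] > threshold_g) + 1L
  w_rise <- max(1L, round(rise_window_s * accel_v$rate))
  w_pre <- max(1L, round(pre_window_s * accel_v$rate))
  ok <- vapply(cand, function(i) {
    rise <- max(v[i:min(i + w_rise, n)]) >= rise_g
    pre <- min(v[max(i - w_pre, 1L):i]) <= 0
    rise && pre
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) return(integer(0))
  gap <- round(refractory_s * accel_v$rate)
  keep <- cand[1L]
  for (i in cand[-1L]) if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
  keep
}

#' Detect a toe-off from vertical acceleration
#'
#' Finds the last downward crossing of the -0.25 g threshold between an
#' initial contact and the next one. If no crossing exists the threshold is
#' relaxed in +0.05 g increments up to -0.05 g; if still none, the step is
#' flagged unmatched.
#'
#' @param accel_v A `sampled_signal` in g.
#' @param ic_index IC sample index.
#' @param next_ic_index Next IC sample index (must exceed `ic_index`).
#' @param threshold_g Starting TO threshold in g (default -0.25).
#' @param relax_step_g Relaxation increment in g (default 0.05).
#' @param relax_max_g Relaxation ceiling in g (default -0.05).
#' @return List with `to_index` (NA when unmatched) and `threshold_g` used.
#' @export
detect_to_accel <- function(accel_v, ic_index, next_ic_index,
                            threshold_g = -0.25, relax_step_g = 0.05,
                            relax_max_g = -0.05) {
  stopifnot(inherits(accel_v, "sampled_signal"))
  if (!(ic_index < next_ic_index)) {
    stop("precondition violated: ic_index must be < next_ic_index", call. = FALSE)
  }
  v <- accel_v$values
  i0 <- ic_index + 1L
  i1 <- min(next_ic_index - 1L, length(v))
  if (i1 <= i0) return(list(to_index = NA_integer_, threshold_g = threshold_g))
  seg <- v[i0:i1]
  for (thr in seq(threshold_g, relax_max_g, by = relax_step_g)) {
    dn <- which(seg[-length(seg)] > thr & seg[-1] <= thr)
    if (length(dn)) {
      return(list(to_index = i0 + dn[length(dn)], threshold_g = thr))
    }
  }
  list(to_index = NA_integer_, threshold_g = relax_max_g)
}

#' Acceleration-detected stance intervals
#'
#' Combines [detect_ic_accel()] and [detect_to_accel()]: consecutive ICs
#' delimit steps; each step's toe-off is searched between its IC and the next.
#' The final IC has no successor and is dropped (incomplete step). Steps whose
#' toe-off search fails even after threshold relaxation are dropped.
#'
#' @param accel_v A `sampled_signal` in g (filtered).
#' @param ... Passed to [detect_ic_accel()].
#' @return Data frame: `ic_index`, `to_index`, `rate`, `source = "accel"`,
#'   `step_period_s`, `to_threshold_g`.
#' @export
detect_stances_accel <- function(accel_v, ...) {
  ics <- detect_ic_accel(accel_v, ...)
  if (length(ics) < 2L) {
    return(data.frame(ic_index = integer(0), to_index = integer(0),
                      rate = numeric(0), source = character(0),
                      step_period_s = numeric(0), to_threshold_g = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(length(ics) - 1L), function(k) {
    to <- detect_to_accel(accel_v, ics[k], ics[k + 1L])
    data.frame(ic_index = ics[k], to_index = to$to_index, rate = accel_v$rate,
               source = "accel",
               step_period_s = (ics[k + 1L] - ics[k]) / accel_v$rate,
               to_threshold_g = to$threshold_g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$to_index), , drop = FALSE]
}

#' Match acceleration-detected steps to force-detected steps
#'
#' Greedy one-to-one matching by nearest initial-contact time, accepting pairs
#' with |IC time difference| within `tol_s`. Because pairs are ranked by their
#' absolute time difference, the matching is symmetric and independent of
#' input ordering. Unmatched entries on either side are dropped.
#'
#' The default tolerance (0.10 s) exceeds the structural lag of the
#' acceleration-threshold IC behind the 50 N force crossing while staying well
#' under half a step period, so pairing remains unambiguous.
#'
#' @param accel_stances Data frame from [detect_stances_accel()].
#' @param grf_stances Data frame from [detect_steps_grf()].
#' @param tol_s Matching tolerance in s (default 0.10).
#' @return Data frame of matched steps: acceleration and force interval
#'   columns (`accel_*`, `grf_*`), `ic_dt_s`, and `step_period_s`.
#' @export
match_steps <- function(accel_stances, grf_stances, tol_s = 0.10) {
  if (nrow(accel_stances) == 0L || nrow(grf_stances) == 0L) {
    return(data.frame())
  }
  t_a <- (accel_stances$ic_index - 1L) / accel_stances$rate
  t_g <- (grf_stances$ic_index - 1L) / grf_stances$rate
  pairs <- expand.grid(a = seq_along(t_a), g = seq_along(t_g))
  pairs$dt <- abs(t_a[pairs$a] - t_g[pairs$g])
  pairs <- pairs[pairs$dt <= tol_s, , drop = FALSE]
  pairs <- pairs[order(pairs$dt, pairs$a, pairs$g), , drop = FALSE]
  used_a <- logical(length(t_a)); used_g <- logical(length(t_g))
  sel <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; g <- pairs$g[r]
    if (!used_a[a] && !used_g[g]) {
      used_a[a] <- TRUE; used_g[g] <- TRUE; sel[r] <- TRUE
    }
  }
  pairs <- pairs[sel, , drop = FALSE]
  if (!nrow(pairs)) return(data.frame())
  pairs <- pairs[order(t_a[pairs$a]), , drop = FALSE]
  out <- data.frame(
    accel_ic_index = accel_stances$ic_index[pairs$a],
    accel_to_index = accel_stances$to_index[pairs$a],
    accel_rate = accel_stances$rate[pairs$a],
    grf_ic_index = grf_stances$ic_index[pairs$g],
    grf_to_index = grf_stances$to_index[pairs$g],
    grf_rate = grf_stances$rate[pairs$g],
    ic_dt_s = t_a[pairs$a] - t_g[pairs$g],
    step_period_s = accel_stances$step_period_s[pairs$a],
    stringsAsFactors = FALSE
  )
  out
}

#' Filter matched steps
#'
#' Retains steps whose force-detected stance duration lies in
#' `[min_duration_s, max_duration_s]`, whose stance window contains no missing
#' samples, and whose stance peak reaches at least `min_peak_bw` (the
#' data-corruption heuristic for a signal falling away).
#'
#' @param steps Data frame from [match_steps()].
#' @param vgrf_bw The trial's force signal in BW (filtered, normalized).
#' @param min_duration_s Minimum stance duration in s (default 0.167).
#' @param max_duration_s Maximum stance duration in s (default 0.4).
#' @param min_peak_bw Minimum stance peak in BW (default 1.2).
#' @return The retained rows of `steps`, with a `duration_s` column added; the
#'   full table with per-step `filter_reason` is attached as attribute
#'   `"details"`.
#' @export
filter_steps <- function(steps, vgrf_bw, min_duration_s = 0.167,
                         max_duration_s = 0.4, min_peak_bw = 1.2) {
  if (!nrow(steps)) return(steps)
  stopifnot(inherits(vgrf_bw, "sampled_signal"))
  if (vgrf_bw$units != "BW") stop("unit error: vgrf must be in BW", call. = FALSE)
  dur <- (steps$grf_to_index - steps$grf_ic_index) / steps$grf_rate
  reason <- character(nrow(steps))
  for (i in seq_len(nrow(steps))) {
    win <- vgrf_bw$values[steps$grf_ic_index[i]:steps$grf_to_index[i]]
    if (dur[i] < min_duration_s) {
      reason[i] <- "too_short"
    } else if (dur[i] > max_duration_s) {
      reason[i] <- "too_long"
    } else if (anyNA(win)) {
      reason[i] <- "missing_samples"
    } else if (max(win) < min_peak_bw) {
      reason[i] <- "low_peak"
    }
  }
  steps$duration_s <- dur
  details <- steps
  details$filter_reason <- reason
  out <- steps[reason == "", , drop = FALSE]
  attr(out, "details") <- details
  out
}
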