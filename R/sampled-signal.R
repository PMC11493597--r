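#' Uniformly sampled signal
#'
#' Light-weight container for one uniformly sampled channel: a numeric vector
#' plus its sampling rate, physical units and an axis label. All signal
#' operations in the package consume and return this class.
#'
#' @param values Numeric vector of samples (length >= 2).
#' @param rate Sampling rate in Hz (> 0).
#' @param units One of `"N"` (newton), `"BW"` (multiples of body weight) or
#'   `"g"` (gravity-subtracted acceleration in g units, so free flight reads
#'   -1 g and quiet standing 0 g).
#' @param label Optional axis label, e.g. `"grf"` or `"accel_v"`.
#'
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, rate, units = c("N", "BW", "g"), label = "") {
  units <- match.arg(units)
  if (!is.numeric(values) || length(values) < 2L) {
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         units = units, label = as.character(label)),
    class = "sampled_signal"
  )
}

#' Sample times of a signal
#'
#' @param x A `sampled_signal`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  (seq_along(x$values) - 1) / x$rate
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz [%s], range [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$rate, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

# trapezoidal integral of a sampled vector at a given rate
trapz_rate <- function(values, rate) {
  n <- length(values)
  if (n < 2L) return(0)
  (sum(values) - (values[1L] + values[n]) / 2) / rate
}

# deterministic sub-seed derived from a base seed and a stream name, so each
# stage/subject gets its own reproducible stream that does not shift when the
# cohort grows
sub_seed <- function(seed, name) {
  h <- 0
  for (cc in utf8ToInt(as.character(name))) h <- (h * 131 + cc) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

GRAVITY <- 9.81
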