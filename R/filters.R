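#' Fourth-order zero-lag Butterworth low-pass filter
#'
#' A second-order Butterworth low-pass is applied forward and backward
#' (`filtfilt` scheme): the net response is fourth order with exactly zero
#' phase lag, the standard reading of "fourth-order zero-lag" in
#' biomechanics. Edge transients are controlled by odd (point-symmetric)
#' signal reflection of at least `3 / fc` seconds at both ends; the padding
#' is stripped so the output length equals the input length.
#'
#' @param x a [uniform_series()].
#' @param fc cut-off frequency in Hz, `0 < fc < fs / 2`.
#' @param base_order order of the single-pass filter (default 2; the
#'   two-pass cascade doubles it).
#' @return Filtered [uniform_series()] on the same grid.
#' @examples
#' x <- uniform_series(sin(2 * pi * 0.1 * seq(0, 60, by = 1 / 64)), 0, 64)
#' y <- zero_lag_lowpass(x, fc = 0.5)
#' @export
zero_lag_lowpass <- function(x, fc, base_order = 2) {
  if (!inherits(x, "uniform_series")) stop_input("expected a uniform_series")
  fs <- x$fs
  if (fc <= 0 || fc >= fs / 2) {
    stop_param("fc must satisfy 0 < fc < fs/2 = ", fs / 2, " Hz")
  }
  v <- x$values
  n <- length(v)
  npad <- min(n - 1L, as.integer(ceiling(3 / fc * fs)))
  if (npad > 0L) {
    left <- 2 * v[1] - v[seq(npad + 1L, 2L)]
    right <- 2 * v[n] - v[seq(n - 1L, n - npad)]
    vp <- c(left, v, right)
  } else {
    vp <- v
  }
  bw <- signal::butter(base_order, fc / (fs / 2), type = "low")
  fwd <- as.numeric(signal::filter(bw, vp))
  bck <- rev(as.numeric(signal::filter(bw, rev(fwd))))
  uniform_series(bck[(npad + 1L):(npad + n)], x$t0, fs)
}

#' Decision signal
#'
#' `BW_0.5(-mean_roll)`: the negated bilateral mean roll rate, low-passed at
#' 0.5 Hz. The negation flips the positive direction to anterior so that a
#' local maximum (positive rotation) marks a switch from a left to a right
#' turn and a minimum the reverse. The local extrema of this signal are the
#' candidate turn switch points.
#'
#' @param mean bilateral mean roll rate, a [uniform_series()] from
#'   [mean_roll()].
#' @param fc cut-off in Hz (default 0.5).
#' @param base_order see [zero_lag_lowpass()].
#' @return A [uniform_series()].
#' @export
decision_signal <- function(mean, fc = 0.5, base_order = 2) {
  zero_lag_lowpass(uniform_series(-mean$values, mean$t0, mean$fs),
                   fc = fc, base_order = base_order)
}

#' Fine-tuning signal
#'
#' `BW_3.0(-mean_roll)`: same construction as [decision_signal()] but with a
#' 3.0 Hz cut-off. The 0.5 Hz decision signal is strongly smoothed; switch
#' timestamps are therefore refined by searching the matching extremum of
#' this less-smoothed signal in a window around each detected switch.
#'
#' @inheritParams decision_signal
#' @param fc cut-off in Hz (default 3.0).
#' @return A [uniform_series()].
#' @export
fine_tune_signal <- function(mean, fc = 3.0, base_order = 2) {
  zero_lag_lowpass(uniform_series(-mean$values, mean$t0, mean$fs),
                   fc = fc, base_order = base_order)
}

#' Local extrema of a uniform series
#'
#' Interior samples strictly greater (maximum) or smaller (minimum) than both
#' neighbors. Plateaus of equal values yield a single extremum at the
#' plateau's first sample. The returned list strictly alternates max/min:
#' consecutive extrema of the same kind are merged, keeping the more extreme
#' one (ties keep the earlier).
#'
#' @param x a [uniform_series()].
#' @return A data.frame with columns `index` (1-based sample index), `t`
#'   (seconds), `value`, `kind` (`"max"`/`"min"`). Empty for fewer than 3
#'   samples.
#' @examples
#' find_local_extrema(uniform_series(c(0, 1, 1, 0, -1, 0), 0, 1))
#' @export
find_local_extrema <- function(x) {
  if (!inherits(x, "uniform_series")) stop_input("expected a uniform_series")
  empty <- data.frame(index = integer(0), t = numeric(0),
                      value = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE)
  v <- x$values
  if (length(v) < 3L) return(empty)
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(empty)
  starts <- cumsum(c(1L, r$lengths[-k]))
  rv <- r$values
  idx <- integer(0)
  kind <- character(0)
  for (i in 2:(k - 1L)) {
    if (rv[i] > rv[i - 1L] && rv[i] > rv[i + 1L]) {
      idx <- c(idx, starts[i]); kind <- c(kind, "max")
    } else if (rv[i] < rv[i - 1L] && rv[i] < rv[i + 1L]) {
      idx <- c(idx, starts[i]); kind <- c(kind, "min")
    }
  }
  if (!length(idx)) return(empty)
  tt <- series_time(x)
  # enforce strict max/min alternation: merge same-kind runs, keep the extreme
  ki <- integer(0)
  for (j in seq_along(idx)) {
    if (length(ki) && kind[ki[length(ki)]] == kind[j]) {
      prev <- ki[length(ki)]
      better <- if (kind[j] == "max") v[idx[j]] > v[idx[prev]] else v[idx[j]] < v[idx[prev]]
      if (better) ki[length(ki)] <- j
    } else {
      ki <- c(ki, j)
    }
  }
  data.frame(index = idx[ki], t = tt[idx[ki]], value = v[idx[ki]],
             kind = kind[ki], stringsAsFactors = FALSE)
}
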