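#' Scalar signal on a uniform time grid
#'
#' Sample `k` (0-based) lives at time `t0 + k / fs`. All filtered signals
#' (mean roll rate, decision signal, fine-tuning signal) are `uniform_series`.
#'
#' @param values numeric vector.
#' @param t0 time of the first sample, seconds.
#' @param fs sampling rate, Hz (> 0).
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, t0, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_param("fs must be a positive scalar")
  }
  structure(list(t0 = as.numeric(t0), fs = as.numeric(fs),
                 values = as.numeric(values)),
            class = "uniform_series")
}

#' Sample times of a uniform series
#' @param x a [uniform_series()].
#' @return Numeric vector of timestamps in seconds.
#' @export
series_time <- function(x) {
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              length(x$values), x$fs, x$t0,
              x$t0 + (length(x$values) - 1L) / x$fs))
  invisible(x)
}

#' Resample a gyroscope stream onto a uniform grid
#'
#' Linear interpolation of each channel onto the grid `t0 + k / fs` spanning
#' the recorded time range (no extrapolation). Bluetooth streams may carry
#' timing jitter; all filtering assumes a uniform grid, so this runs first.
#'
#' @param stream a [gyro_stream()].
#' @param fs target sampling rate in Hz, within \[1, 200\] (default 64).
#' @param t_start,t_end optional window (seconds) to resample over; defaults
#'   to the full recorded span. Used to put two boots on a common grid.
#' @return Named list of [uniform_series()], one per channel
#'   (`gyro_x`, `gyro_y`, `gyro_z`).
#' @examples
#' s <- gyro_stream(c(0, 0.5, 1), c(0, 1, 0), c(0, 0, 0), c(0, 1, 0), "left")
#' resample_uniform(s, fs = 4)$gyro_x$values  # 0, 0.5, 1, 0.5, 0
#' @export
resample_uniform <- function(stream, fs = 64, t_start = NULL, t_end = NULL) {
  if (!inherits(stream, "gyro_stream")) stop_input("expected a gyro_stream")
  if (fs < 1 || fs > 200) stop_param("fs must lie in [1, 200] Hz")
  t0 <- if (is.null(t_start)) stream$t[1] else t_start
  t1 <- if (is.null(t_end)) stream$t[length(stream$t)] else t_end
  if (t0 < stream$t[1] - 1e-9 || t1 > stream$t[length(stream$t)] + 1e-9) {
    stop_input("resampling window extends beyond the recording (no extrapolation)")
  }
  if (t1 - t0 < 1) stop_input("recording span ", signif(t1 - t0, 3), " s is shorter than 1 s")
  grid <- seq(t0, t1, by = 1 / fs)
  one <- function(v) {
    uniform_series(approx(stream$t, v, xout = grid, rule = 1)$y, t0, fs)
  }
  list(gyro_x = one(stream$gyro_x),
       gyro_y = one(stream$gyro_y),
       gyro_z = one(stream$gyro_z))
}

#' Bilateral mean roll rate
#'
#' Element-wise mean of the left and right roll-rate series. Averaging the
#' two boots suppresses unilateral rotations (e.g. skating pushes) so that
#' high roll rates are restricted to parallel turning.
#'
#' @param left,right [uniform_series()] on identical grids.
#' @return A [uniform_series()] on the same grid.
#' @export
mean_roll <- function(left, right) {
  if (!inherits(left, "uniform_series") || !inherits(right, "uniform_series")) {
    stop_input("mean_roll expects two uniform_series")
  }
  if (abs(left$t0 - right$t0) > 1e-9 || left$fs != right$fs ||
      length(left$values) != length(right$values)) {
    stop_input("left/right grids differ (t0, fs and length must match)")
  }
  uniform_series((left$values + right$values) / 2, left$t0, left$fs)
}
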