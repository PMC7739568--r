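#' Construct a single-boot gyroscope stream
#'
#' A `gyro_stream` holds one boot's timestamped 3-axis angular-velocity
#' record. Axis convention (boot-fixed, right-handed): x = yaw (superior),
#' y = pitch (left), z = roll (posterior). Edging rotations happen about the
#' roll axis, which is the only channel the detector uses.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param gyro_x,gyro_y,gyro_z angular velocities in rad/s, same length as `t`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `gyro_stream` (a list with the five fields).
#' @examples
#' t <- seq(0, 2, by = 1 / 64)
#' s <- gyro_stream(t, 0 * t, 0 * t, sin(2 * pi * t), side = "left")
#' stream_fs(s)
#' @export
gyro_stream <- function(t, gyro_x, gyro_y, gyro_z, side = c("left", "right")) {
  side <- match.arg(side)
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop_input("gyro_stream needs at least 2 samples, got ", n)
  if (length(gyro_x) != n || length(gyro_y) != n || length(gyro_z) != n) {
    stop_input("all gyro channels must have the same length as t")
  }
  if (anyNA(t) || any(diff(t) <= 0)) {
    stop_input("timestamps must be strictly increasing and free of NA")
  }
  structure(
    list(side = side, t = t,
         gyro_x = as.numeric(gyro_x),
         gyro_y = as.numeric(gyro_y),
         gyro_z = as.numeric(gyro_z)),
    class = "gyro_stream"
  )
}

#' Nominal sampling rate of a stream
#'
#' Recovered as `1 / median(diff(t))`. Bluetooth transport can drop or jitter
#' samples, so the median interval is used rather than the mean.
#'
#' @param stream a [gyro_stream()].
#' @return Sampling rate in Hz.
#' @export
stream_fs <- function(stream) {
  dt <- median(diff(stream$t))
  if (dt < 1 / 200 || dt > 1 / 10) {
    stop_input("median sampling interval ", signif(dt, 3),
               " s outside the supported range [1/200, 1/10] s")
  }
  1 / dt
}

#' Read a boot gyroscope CSV
#'
#' Expected header: `time_s,gyro_x,gyro_y,gyro_z` (comma separator, decimal
#' point, UTF-8). `units = "deg/s"` converts the rates to rad/s on read.
#'
#' @param path CSV file path.
#' @param side `"left"` or `"right"`.
#' @param units `"rad/s"` (default) or `"deg/s"`.
#' @return A [gyro_stream()].
#' @export
read_gyro_csv <- function(path, side = c("left", "right"), units = c("rad/s", "deg/s")) {
  side <- match.arg(side)
  units <- match.arg(units)
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "gyro_x", "gyro_y", "gyro_z")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop_input("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  k <- if (units == "deg/s") pi / 180 else 1
  gyro_stream(d$time_s, k * d$gyro_x, k * d$gyro_y, k * d$gyro_z, side = side)
}

#' Write a boot gyroscope CSV
#'
#' @param stream a [gyro_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(stream, path) {
  d <- data.frame(time_s = stream$t, gyro_x = stream$gyro_x,
                  gyro_y = stream$gyro_y, gyro_z = stream$gyro_z)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a stream at transmission gaps
#'
#' Filtering across a long dropout fabricates signal, so recordings are split
#' into independently processed segments wherever consecutive samples are
#' more than `max_gap` seconds apart.
#'
#' @param stream a [gyro_stream()].
#' @param max_gap gap threshold in seconds (default 0.5).
#' @return List of `gyro_stream` segments (possibly of length one).
#' @export
split_on_gaps <- function(stream, max_gap = 0.5) {
  brk <- which(diff(stream$t) > max_gap)
  if (!length(brk)) return(list(stream))
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(stream$t))
  out <- list()
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    if (length(idx) < 2L) next
    out[[length(out) + 1L]] <- gyro_stream(
      stream$t[idx], stream$gyro_x[idx], stream$gyro_y[idx], stream$gyro_z[idx],
      side = stream$side
    )
  }
  out
}

# roll-rate channel of a stream as (t, value), honoring axis map and sign
roll_channel <- function(stream, roll_axis = "z", roll_sign = 1) {
  ch <- switch(roll_axis,
    x = stream$gyro_x, y = stream$gyro_y, z = stream$gyro_z,
    stop_param("roll_axis must be one of x, y, z")
  )
  list(t = stream$t, values = roll_sign * ch)
}
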