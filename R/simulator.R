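#' One simulated segment
#'
#' Styles:
#' * `carved_short` — parallel short turns, defaults 1.04 +/- 0.41 s
#'   duration (the short-turn timing observed on groomed slopes).
#' * `carved_long` — parallel long turns, defaults 2.97 +/- 0.43 s.
#' * `drifted` — parallel skidded turns: longer, slower, lower roll-rate
#'   dynamics, so some turns fall below the detector's rate thresholds.
#' * `snowplow` — wedge technique: the legs' roll rotations are not
#'   synchronized and the dominant rotation is yaw, which is outside the
#'   detector's design envelope (the expected failure mode).
#' * `stop` — standing still: small oscillations around zero.
#' * `straight` — straight gliding: near-zero roll rate plus noise.
#'
#' @param style one of the above.
#' @param n_turns number of turns (parallel and snowplow styles).
#' @param turn_duration,turn_duration_sd mean/SD turn duration, seconds.
#' @param edging_amplitude,edging_amplitude_sd mean/SD peak roll rate of the
#'   edging bursts, rad/s.
#' @param duration segment length in seconds (`stop` / `straight` only).
#' @return Named list describing the segment.
#' @export
sim_segment <- function(style = c("carved_long", "carved_short", "drifted",
                                  "snowplow", "stop", "straight"),
                        n_turns = 10,
                        turn_duration = NULL, turn_duration_sd = NULL,
                        edging_amplitude = NULL, edging_amplitude_sd = NULL,
                        duration = 10) {
  style <- match.arg(style)
  defaults <- list(
    carved_long  = c(dur = 2.97, dur_sd = 0.43, amp = 1.5,  amp_sd = 0.3),
    carved_short = c(dur = 1.04, dur_sd = 0.41, amp = 1.5,  amp_sd = 0.3),
    drifted      = c(dur = 2.5,  dur_sd = 0.6,  amp = 0.45, amp_sd = 0.2),
    snowplow     = c(dur = 2.5,  dur_sd = 0.5,  amp = 0.35, amp_sd = 0.15),
    stop         = c(dur = 0,    dur_sd = 0,    amp = 0,    amp_sd = 0),
    straight     = c(dur = 0,    dur_sd = 0,    amp = 0,    amp_sd = 0)
  )[[style]]
  list(style = style,
       n_turns = n_turns,
       turn_duration = if (is.null(turn_duration)) defaults[["dur"]] else turn_duration,
       turn_duration_sd = if (is.null(turn_duration_sd)) defaults[["dur_sd"]] else turn_duration_sd,
       edging_amplitude = if (is.null(edging_amplitude)) defaults[["amp"]] else edging_amplitude,
       edging_amplitude_sd = if (is.null(edging_amplitude_sd)) defaults[["amp_sd"]] else edging_amplitude_sd,
       duration = duration)
}

#' Simulator configuration
#'
#' @param seed integer seed; the whole run is reproducible from it.
#' @param fs sampling rate, Hz.
#' @param segments list of [sim_segment()] descriptions, emitted in order
#'   with a short quiet glide between them.
#' @param noise_sd white-noise SD added to every channel, rad/s.
#' @param saddle_probability probability that a turn of at least 2.4 s
#'   receives a mid-turn counter-oscillation (the saddle artifact of long
#'   turns).
#' @param saddle_amplitude amplitude of that counter-oscillation, rad/s.
#'   Kept below the switch-rate threshold so the artifact mimics within-turn
#'   noise, not a spurious switch.
#' @param saddle_period period of the counter-oscillation, seconds. Chosen
#'   slow enough (2 s) that the 0.5 Hz decision filter does not erase it.
#' @param stop_oscillation_amplitude amplitude of post-stop oscillations,
#'   rad/s (small: the skier is standing).
#' @param leg_asymmetry per-turn left/right amplitude imbalance fraction.
#' @param edge_change_halfwidth half-width of the edge-change roll burst,
#'   seconds. A long turn holds a stable edge angle mid-turn (roll rate near
#'   zero) while the edge change itself is quick, so each burst extends at
#'   most this far into the adjacent turns; turns shorter than twice this
#'   value have no plateau.
#' @param bumpy_noise_amplitude amplitude (rad/s, per tone) of the slow
#'   two-tone surface disturbance added to each leg in `drifted` segments —
#'   the bumpy-snow conditions under which low-dynamics turns get lost.
#' @param inter_segment_gap quiet seconds between segments.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, fs = 64,
                       segments = list(sim_segment("carved_short", n_turns = 16),
                                       sim_segment("stop", duration = 10),
                                       sim_segment("carved_long", n_turns = 9)),
                       noise_sd = 0.02,
                       saddle_probability = 0.15,
                       saddle_amplitude = 0.25,
                       saddle_period = 2.0,
                       stop_oscillation_amplitude = 0.04,
                       leg_asymmetry = 0.1,
                       edge_change_halfwidth = 0.8,
                       bumpy_noise_amplitude = 0.35,
                       inter_segment_gap = 2.0) {
  if (fs <= 0) stop_param("fs must be > 0")
  if (noise_sd < 0 || saddle_amplitude < 0 || stop_oscillation_amplitude < 0) {
    stop_param("amplitudes must be >= 0")
  }
  if (saddle_probability < 0 || saddle_probability > 1) {
    stop_param("saddle_probability must lie in [0, 1]")
  }
  for (s in segments) {
    if (s$style %in% c("stop", "straight")) {
      if (s$duration <= 0) stop_param("segment duration must be > 0")
    } else if (s$n_turns < 0 || s$turn_duration <= 0) {
      stop_param("segments need n_turns >= 0 and turn_duration > 0")
    }
  }
  structure(list(seed = seed, fs = fs, segments = segments,
                 noise_sd = noise_sd,
                 saddle_probability = saddle_probability,
                 saddle_amplitude = saddle_amplitude,
                 saddle_period = saddle_period,
                 stop_oscillation_amplitude = stop_oscillation_amplitude,
                 leg_asymmetry = leg_asymmetry,
                 edge_change_halfwidth = edge_change_halfwidth,
                 bumpy_noise_amplitude = bumpy_noise_amplitude,
                 inter_segment_gap = inter_segment_gap),
            class = "sim_config")
}

default_sim_config <- function() unclass(sim_config())

#' Simulate a two-boot gyroscope recording with ground truth
#'
#' The roll-rate model is pendular edging: the boot's edge angle swings from
#' one extreme to the other across each turn switch, so the roll RATE is a
#' train of smooth unimodal bursts of alternating sign, each burst peaking
#' at the flat-ski instant — the ground-truth switch time. Between switches
#' (maximum edge angle, mid-turn) the rate passes through zero. Per-turn
#' amplitude and duration are drawn from the segment's distributions; the
#' two legs share the waveform up to a per-turn amplitude imbalance
#' (`leg_asymmetry`), which the bilateral mean cancels.
#'
#' Artifacts emulated: mid-turn saddle / counter-oscillations in long turns
#' (labeled `noise` by a correct detector), small oscillations around zero
#' after stopping, straight-gliding noise, and an unsynchronized-leg
#' snowplow mode (independent per-leg burst trains with random sign
#' relation and a dominant yaw channel) on which roll-axis detection is
#' expected to fail.
#'
#' Truth events are one record per turn: the turn's closing switch time and
#' the turn's direction (a positive decision-signal burst at the closing
#' switch closes a left turn).
#'
#' @param config a [sim_config()].
#' @return List of class `ski_sim`: `left` / `right` ([gyro_stream()]s),
#'   `truth` (data.frame `run_id`, `switch_time_s`, `direction`, `style`),
#'   `segments` (annotation data.frame), `config`.
#' @export
simulate_run <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_param("expected a sim_config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  fs <- config$fs
  dt <- 1 / fs
  # ds-space targets per leg (decision-signal sign convention); roll = -ds
  left_ds <- numeric(0)
  right_ds <- numeric(0)
  yaw <- numeric(0)
  truth <- list()
  seg_rows <- list()
  t_cursor <- 0
  last_sign <- -1  # first switch of the first segment flips it to +1

  append_quiet <- function(dur) {
    n <- round(dur * fs)
    left_ds <<- c(left_ds, numeric(n))
    right_ds <<- c(right_ds, numeric(n))
    yaw <<- c(yaw, numeric(n))
    t_cursor <<- t_cursor + n * dt
  }

  for (seg in config$segments) {
    seg_start <- t_cursor
    if (seg$style %in% c("stop", "straight")) {
      n <- round(seg$duration * fs)
      tt <- seg_start + (seq_len(n) - 1L) * dt
      base <- if (seg$style == "stop") {
        f <- runif(1, 0.2, 0.5)
        config$stop_oscillation_amplitude * sin(2 * pi * f * (tt - seg_start) + runif(1, 0, 2 * pi))
      } else {
        numeric(n)
      }
      left_ds <- c(left_ds, base)
      right_ds <- c(right_ds, base)
      yaw <- c(yaw, numeric(n))
      t_cursor <- t_cursor + n * dt
    } else if (seg$n_turns > 0) {
      durations <- draw_durations(seg$n_turns, seg$turn_duration, seg$turn_duration_sd)
      n_sw <- seg$n_turns + 1L
      amps <- pmax(0.05, rnorm(n_sw, seg$edging_amplitude, seg$edging_amplitude_sd))
      lead <- durations[1] / 2
      tail_dur <- durations[seg$n_turns] / 2
      tau <- seg_start + lead + c(0, cumsum(durations))
      signs <- last_sign * (-1)^(seq_len(n_sw))
      seg_end <- tau[n_sw] + tail_dur
      n <- round((seg_end - seg_start) / dt)
      tt <- seg_start + (seq_len(n) - 1L) * dt

      if (seg$style == "snowplow") {
        # wedge technique: the legs' roll rotations are not synchronized —
        # each leg's burst times jitter independently around the body's
        # turn rhythm and the sign relation between the legs is random per
        # switch, so the bilateral mean largely cancels; the dominant
        # rotation is yaw, which the roll-axis detector never sees
        jit <- function() {
          tj <- tau + c(0, rnorm(n_sw - 1L, 0, 0.3))
          sort(pmax(seg_start + 0.1, tj))
        }
        tau_l <- jit(); tau_r <- jit()
        amps_l <- pmax(0.05, rnorm(n_sw, seg$edging_amplitude, seg$edging_amplitude_sd))
        amps_r <- pmax(0.05, rnorm(n_sw, seg$edging_amplitude, seg$edging_amplitude_sd))
        flip_r <- sample(c(1, -1), n_sw, replace = TRUE)
        we <- config$edge_change_halfwidth
        base_l <- burst_train(tt, tau_l, signs, amps_l, lead, tail_dur, we)
        base_r <- burst_train(tt, tau_r, signs * flip_r, amps_r, lead, tail_dur, we)
        yaw_seg <- burst_train(tt, tau_l, signs, rep(1.5, n_sw), lead, tail_dur, we)
        left_ds <- c(left_ds, base_l)
        right_ds <- c(right_ds, base_r)
        yaw <- c(yaw, yaw_seg)
      } else {
        base <- burst_train(tt, tau, signs, amps, lead, tail_dur,
                            config$edge_change_halfwidth)
        # saddle artifact: one slow counter-oscillation cycle on the
        # stable-edge plateau mid-turn
        for (j in seq_len(seg$n_turns)) {
          if (durations[j] >= 2.4 && runif(1) < config$saddle_probability) {
            m <- (tau[j] + tau[j + 1L]) / 2
            w <- min(config$saddle_period,
                     max(0.6, durations[j] - 2 * config$edge_change_halfwidth))
            inw <- tt >= m - w / 2 & tt <= m + w / 2
            base[inw] <- base[inw] +
              config$saddle_amplitude * sin(2 * pi * (tt[inw] - (m - w / 2)) / w)
          }
        }
        asym <- rnorm(n_sw, 0, config$leg_asymmetry)
        scale_l <- approx(tau, 1 + asym, xout = tt, rule = 2)$y
        scale_r <- approx(tau, 1 - asym, xout = tt, rule = 2)$y
        seg_l <- base * scale_l
        seg_r <- base * scale_r
        if (seg$style == "drifted" && config$bumpy_noise_amplitude > 0) {
          # bumpy-surface disturbance: slow two-tone wobble per leg; with
          # the low roll-rate dynamics of drifted turns it spawns the extra
          # extrema between switches that finalize turn sequences early
          seg_l <- seg_l + two_tone(tt, config$bumpy_noise_amplitude)
          seg_r <- seg_r + two_tone(tt, config$bumpy_noise_amplitude)
        }
        left_ds <- c(left_ds, seg_l)
        right_ds <- c(right_ds, seg_r)
        yaw <- c(yaw, numeric(n))
      }

      # truth: one record per turn, stamped at its closing switch
      for (j in seq_len(seg$n_turns)) {
        truth[[length(truth) + 1L]] <- data.frame(
          run_id = "run1",
          switch_time_s = tau[j + 1L],
          direction = if (signs[j + 1L] > 0) "left" else "right",
          style = seg$style, stringsAsFactors = FALSE
        )
      }
      last_sign <- signs[n_sw]
      t_cursor <- seg_start + n * dt
    }
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      style = seg$style, t_start = seg_start, t_end = t_cursor,
      stringsAsFactors = FALSE
    )
    append_quiet(config$inter_segment_gap)
  }

  n_tot <- length(left_ds)
  tt <- (seq_len(n_tot) - 1L) * dt
  noise <- function() rnorm(n_tot, 0, config$noise_sd)
  mk_stream <- function(ds_target, side) {
    gyro_stream(
      t = tt,
      gyro_x = yaw + noise(),                  # yaw: quiet except snowplow
      gyro_y = 0.5 * noise(),                  # pitch: low-level noise only
      gyro_z = -ds_target + noise(),           # roll; ds-space = -roll
      side = side
    )
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(run_id = character(0), switch_time_s = numeric(0),
               direction = character(0), style = character(0),
               stringsAsFactors = FALSE)
  structure(list(left = mk_stream(left_ds, "left"),
                 right = mk_stream(right_ds, "right"),
                 truth = truth_df,
                 segments = do.call(rbind, seg_rows),
                 config = config),
            class = "ski_sim")
}

# Per-turn durations: shifted lognormal with the requested mean and SD.
# Durations are positive and right-skewed with a physical floor (an edge
# change cannot be arbitrarily fast), which an unbounded normal violates.
draw_durations <- function(n, mean, sd, floor = 0.4) {
  if (sd <= 0) return(rep(mean, n))
  d0 <- min(floor, 0.5 * mean)
  m <- mean - d0
  s2 <- log(1 + (sd / m)^2)
  mu <- log(m) - s2 / 2
  d0 + exp(rnorm(n, mu, sqrt(s2)))
}

# slow two-tone disturbance (random 0.6-1.3 Hz tones, random phases)
two_tone <- function(tt, amp) {
  f <- runif(2, 0.6, 1.3)
  ph <- runif(2, 0, 2 * pi)
  amp * (sin(2 * pi * f[1] * tt + ph[1]) + sin(2 * pi * f[2] * tt + ph[2])) / 2
}

# Burst train in ds-space: unimodal edge-change lobes peaking at the switch
# times tau with signs/amps per switch. Each lobe extends at most w_edge
# seconds into the adjacent turns; any remaining mid-turn time is a
# stable-edge plateau at zero roll rate.
burst_train <- function(tt, tau, signs, amps, lead, tail_dur, w_edge = Inf) {
  v <- numeric(length(tt))
  n_sw <- length(tau)
  # lead-in quarter lobe up to the first switch
  w0 <- min(lead, w_edge)
  in_lead <- tt >= tau[1] - w0 & tt < tau[1]
  v[in_lead] <- signs[1] * amps[1] *
    sin(pi / 2 * (tt[in_lead] - (tau[1] - w0)) / w0)
  for (k in seq_len(n_sw - 1L)) {
    m <- (tau[k] + tau[k + 1L]) / 2
    w1 <- min(m - tau[k], w_edge)
    h1 <- tt >= tau[k] & tt < tau[k] + w1
    v[h1] <- signs[k] * amps[k] * cos(pi / 2 * (tt[h1] - tau[k]) / w1)
    w2 <- min(tau[k + 1L] - m, w_edge)
    h2 <- tt >= tau[k + 1L] - w2 & tt < tau[k + 1L]
    v[h2] <- signs[k + 1L] * amps[k + 1L] *
      sin(pi / 2 * (tt[h2] - (tau[k + 1L] - w2)) / w2)
  }
  wt <- min(tail_dur, w_edge)
  in_tail <- tt >= tau[n_sw] & tt <= tau[n_sw] + wt
  v[in_tail] <- signs[n_sw] * amps[n_sw] *
    cos(pi / 2 * pmin(1, (tt[in_tail] - tau[n_sw]) / wt))
  v
}

#' Project simulator ground truth into the evaluation reference format
#'
#' @param run a `ski_sim` from [simulate_run()].
#' @return data.frame with columns `run_id`, `switch_time_s`, `direction`,
#'   `style` — one row per true turn.
#' @export
truth_to_reference <- function(run) {
  if (!inherits(run, "ski_sim")) stop_input("expected a ski_sim")
  run$truth
}

#' @export
print.ski_sim <- function(x, ...) {
  cat(sprintf("<ski_sim> %d true turn(s), %.1f s, %d segment(s), seed %d\n",
              nrow(x$truth), x$left$t[length(x$left$t)],
              nrow(x$segments), x$config$seed))
  invisible(x)
}
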