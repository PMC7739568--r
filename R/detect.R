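#' Detect turns from two boot gyroscope streams
#'
#' The full pipeline: resample both boots onto a common uniform grid over
#' their time overlap, average the roll channels, build the 0.5 Hz decision
#' signal and 3.0 Hz fine-tuning signal, find and label the decision-signal
#' extrema, merge switch runs into turns and turn sequences, and fine-tune
#' every switch timestamp. Transmission gaps longer than
#' `config$sampling$max_gap_s` split the recording into independently
#' processed pieces (sequence numbering continues across pieces).
#' Deterministic for fixed input and configuration.
#'
#' @param left,right [gyro_stream()] objects for the two boots (any order;
#'   the bilateral mean is symmetric).
#' @param config configuration list from [default_config()] /
#'   [load_config()].
#' @return A `ski_turns` data.frame (see [build_turns()]) with attributes
#'   `sequences` ([sequence_summary()] table) and `n_extrema`.
#' @examples
#' run <- simulate_run(sim_config(seed = 7, segments = list(
#'   sim_segment("carved_long", n_turns = 6)), noise_sd = 0))
#' detect_turns(run$left, run$right)
#' @export
detect_turns <- function(left, right, config = default_config()) {
  fs <- config$sampling$fs
  max_gap <- config$sampling$max_gap_s
  unit_k <- if (identical(config$sampling$units, "deg/s")) pi / 180 else 1

  t_lo <- max(left$t[1], right$t[1])
  t_hi <- min(left$t[length(left$t)], right$t[length(right$t)])
  if (t_hi - t_lo < 1) {
    stop_input("streams share less than 1 s of overlap (",
               signif(t_hi - t_lo, 3), " s)")
  }

  spans <- common_spans(left, right, t_lo, t_hi, max_gap)
  params <- config_labeling_params(config)

  all_turns <- list()
  n_extrema <- 0L
  next_id <- 1L
  for (sp in spans) {
    if (sp[2] - sp[1] < 1) next
    rl <- resample_uniform(left, fs, t_start = sp[1], t_end = sp[2])
    rr <- resample_uniform(right, fs, t_start = sp[1], t_end = sp[2])
    roll_of <- function(r) {
      ch <- r[[paste0("gyro_", config$sampling$roll_axis)]]
      uniform_series(unit_k * config$sampling$roll_sign * ch$values, ch$t0, ch$fs)
    }
    m <- mean_roll(roll_of(rl), roll_of(rr))
    ds <- decision_signal(m, fc = config$filter$fc_decision,
                          base_order = config$filter$base_order)
    ft <- fine_tune_signal(m, fc = config$filter$fc_fine,
                           base_order = config$filter$base_order)
    ext <- find_local_extrema(ds)
    n_extrema <- n_extrema + nrow(ext)
    lab <- label_extrema(ext, params)
    turns <- build_turns(lab, direction_convention = config$direction_convention,
                         start_id = next_id)
    if (nrow(turns)) {
      turns <- fine_tune_switches(turns, lab[lab$label == "switch", , drop = FALSE],
                                  ft, p = config$fine_tune$p)
      next_id <- max(turns$sequence_id) + 1L
      all_turns[[length(all_turns) + 1L]] <- turns
    }
  }

  out <- if (length(all_turns)) do.call(rbind, all_turns) else
    build_turns(data.frame(t = numeric(0), value = numeric(0),
                           kind = character(0), label = character(0),
                           rule_id = character(0)))
  class(out) <- c("ski_turns", "data.frame")
  attr(out, "sequences") <- sequence_summary(out)
  attr(out, "n_extrema") <- n_extrema
  out
}

# time spans inside [t_lo, t_hi] where neither stream has a gap > max_gap
common_spans <- function(left, right, t_lo, t_hi, max_gap) {
  spans_of <- function(s) {
    segs <- split_on_gaps(s, max_gap)
    lapply(segs, function(g) c(g$t[1], g$t[length(g$t)]))
  }
  la <- spans_of(left)
  rb <- spans_of(right)
  out <- list()
  for (a in la) {
    for (b in rb) {
      lo <- max(a[1], b[1], t_lo)
      hi <- min(a[2], b[2], t_hi)
      if (hi > lo) out[[length(out) + 1L]] <- c(lo, hi)
    }
  }
  out[order(vapply(out, `[`, numeric(1), 1))]
}
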