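#' Build turns and turn sequences from labeled extrema
#'
#' Consecutive `switch` extrema are merged into turns if and only if no
#' `eliminated` extremum interrupts them; `noise` extrema (by definition
#' within a turn) are ignored and never interrupt. A maximal uninterrupted
#' run of `k >= 2` switches yields `k - 1` seamlessly tiling turns — the
#' run's first switch is the sequence entry (the first edge change out of
#' the fall line) and opens the first turn but is not itself a counted turn.
#' Each `eliminated` interruption starts a new turn sequence; sequence ids
#' start at `start_id` and increase by 1 per sequence that yields turns.
#' Isolated single switches produce no turn.
#'
#' Direction follows the decision-signal sign convention (positive roll axis
#' posterior): a local maximum is a switch from a left to a right turn, a
#' minimum the reverse. With `direction_convention = "opening"` a turn is
#' named by the direction entered at its opening switch; `"closing"` names
#' it by the switch that ends it. Both conventions assign identical labels
#' whenever the signs alternate (which the labeling rules guarantee).
#'
#' A turn sequence requires strictly alternating switch signs. The labeling
#' rules enforce this in almost all cases, but a rule-5 switch separated
#' from its neighbor only by noise extrema can occasionally repeat a sign
#' on noisy data; `alternation = "split"` (default) then starts a new
#' sequence at the offending switch — the same effect an eliminated
#' extremum has — while `"error"` raises an internal-consistency error.
#'
#' @param labeled data.frame from [label_extrema()].
#' @param direction_convention `"opening"` (default) or `"closing"`.
#' @param start_id first sequence id (default 1).
#' @param alternation `"split"` (default) or `"error"`; see above.
#' @return data.frame of class `ski_turns` with columns `sequence_id`,
#'   `turn_index`, `t_start`, `t_end`, `direction`.
#' @export
build_turns <- function(labeled, direction_convention = c("opening", "closing"),
                        start_id = 1L, alternation = c("split", "error")) {
  direction_convention <- match.arg(direction_convention)
  alternation <- match.arg(alternation)
  if (nrow(labeled) && anyNA(labeled$label)) {
    stop_input("build_turns requires fully labeled extrema")
  }
  runs <- switch_runs(labeled)
  # enforce strict sign alternation within each run
  runs <- do.call(c, c(list(list()), lapply(runs, function(run) {
    vv <- run$value
    brk <- which(vv[-1] * vv[-length(vv)] >= 0)
    if (!length(brk)) return(list(run))
    if (alternation == "error") {
      stop_internal("switch signs do not alternate within a run; ",
                    "labeling produced an inconsistent sequence")
    }
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(vv))
    lapply(seq_along(starts), function(i) run[starts[i]:ends[i], , drop = FALSE])
  })))
  out <- list()
  seq_id <- start_id - 1L
  for (run in runs) {
    k <- nrow(run)
    if (k < 2L) next
    vv <- run$value
    seq_id <- seq_id + 1L
    for (j in seq_len(k - 1L)) {
      v_open <- vv[j]
      dir <- if (direction_convention == "opening") {
        if (v_open > 0) "right" else "left"
      } else {
        if (vv[j + 1L] > 0) "left" else "right"
      }
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = seq_id, turn_index = j,
        t_start = run$t[j], t_end = run$t[j + 1L],
        direction = dir, stringsAsFactors = FALSE
      )
    }
  }
  turns <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence_id = integer(0), turn_index = integer(0),
               t_start = numeric(0), t_end = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  class(turns) <- c("ski_turns", "data.frame")
  turns
}

# maximal runs of switch extrema uninterrupted by eliminated ones
switch_runs <- function(labeled) {
  runs <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(labeled))) {
    lab <- labeled$label[i]
    if (identical(lab, "switch")) {
      cur <- c(cur, i)
    } else if (identical(lab, "eliminated")) {
      if (length(cur)) runs[[length(runs) + 1L]] <- labeled[cur, , drop = FALSE]
      cur <- integer(0)
    }
    # noise: ignored, does not interrupt
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- labeled[cur, , drop = FALSE]
  runs
}

#' Fine-tune switch timestamps on the 3 Hz signal
#'
#' For every switch timestamp `t_i` of every sequence, searches the global
#' maximum (for maxima) or minimum (for minima) of the fine-tuning signal
#' inside the asymmetric epsilon neighborhood
#' `[t_i - p (t_i - t_(i-1)), t_i + p (t_(i+1) - t_i)]`, where the neighbors
#' are the adjacent switches of the same sequence, and replaces `t_i` by the
#' winning sample time. The first/last switch of a sequence has only one
#' neighbor; its window falls back to the symmetric
#' `[t_i - p g, t_i + p g]` with `g` the gap to that neighbor. Timestamps are
#' reported at grid resolution (no sub-sample interpolation). If a refined
#' timestamp would break the strict ordering within its sequence the
#' original timestamp is kept, so tiling and alternation still hold.
#'
#' @param turns a `ski_turns` data.frame from [build_turns()].
#' @param switch_extrema the labeled extrema restricted to
#'   `label == "switch"` (needed for each switch's max/min kind).
#' @param ft the fine-tuning signal, a [uniform_series()] covering all
#'   switch times.
#' @param p neighborhood fraction in `[0, 1]` (default 0.6). `p = 0` leaves
#'   every timestamp unchanged.
#' @return The turns with adjusted `t_start` / `t_end`.
#' @export
fine_tune_switches <- function(turns, switch_extrema, ft, p = 0.6) {
  if (p < 0 || p > 1) stop_param("p must lie in [0, 1]")
  if (!nrow(turns) || p == 0) return(turns)
  tt <- series_time(ft)
  kind_at <- function(tm) {
    j <- which.min(abs(switch_extrema$t - tm))
    if (!length(j) || abs(switch_extrema$t[j] - tm) > 0.5 / ft$fs + 1e-9) {
      stop_input("switch at t = ", tm, " s not found among switch extrema")
    }
    switch_extrema$kind[j]
  }
  refine <- function(tm, lo, hi, kind) {
    i0 <- which(tt >= lo - 1e-9 & tt <= hi + 1e-9)
    if (!length(i0)) return(tm)
    vals <- ft$values[i0]
    j <- if (kind == "max") which.max(vals) else which.min(vals)
    tt[i0[j]]
  }
  out <- turns
  for (s in unique(turns$sequence_id)) {
    rows <- which(turns$sequence_id == s)
    times <- c(turns$t_start[rows[1]], turns$t_end[rows])
    m <- length(times)
    new_times <- times
    for (i in seq_len(m)) {
      gap_prev <- if (i > 1L) times[i] - times[i - 1L] else NA_real_
      gap_next <- if (i < m) times[i + 1L] - times[i] else NA_real_
      if (is.na(gap_prev)) gap_prev <- gap_next
      if (is.na(gap_next)) gap_next <- gap_prev
      if (is.na(gap_prev)) next  # single switch: nothing to anchor on
      cand <- refine(times[i], times[i] - p * gap_prev, times[i] + p * gap_next,
                     kind_at(times[i]))
      if (i > 1L && cand <= new_times[i - 1L]) cand <- times[i]
      new_times[i] <- cand
    }
    out$t_start[rows] <- new_times[-m]
    out$t_end[rows] <- new_times[-1L]
  }
  out
}

#' Summarize turn sequences
#'
#' @param turns a `ski_turns` data.frame.
#' @return data.frame with one row per sequence: `sequence_id`, `n_turns`,
#'   `t_start`, `t_end`, `mean_duration` (s).
#' @export
sequence_summary <- function(turns) {
  if (!nrow(turns)) {
    return(data.frame(sequence_id = integer(0), n_turns = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      mean_duration = numeric(0)))
  }
  ids <- sort(unique(turns$sequence_id))
  do.call(rbind, lapply(ids, function(s) {
    rows <- turns[turns$sequence_id == s, , drop = FALSE]
    data.frame(sequence_id = s, n_turns = nrow(rows),
               t_start = min(rows$t_start), t_end = max(rows$t_end),
               mean_duration = mean(rows$t_end - rows$t_start))
  }))
}

#' @export
print.ski_turns <- function(x, ...) {
  s <- sequence_summary(x)
  cat(sprintf("<ski_turns> %d turn(s) in %d sequence(s)\n", nrow(x), nrow(s)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
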