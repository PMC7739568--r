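#' Confusion counts for one detector-vs-reference comparison
#'
#' `actual` is defined as `TP + FN` and `detected` as `TP + FP`. (Published
#' evaluations of this kind occasionally print an actual-turn column that
#' disagrees with `TP + FN` by a count or two; this package always derives
#' `actual` from the counts so the three metrics stay mutually consistent.)
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return List of class `confusion_counts` with fields `TP`, `FP`, `FN`,
#'   `actual`, `detected`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop_input("counts must be non-negative")
  structure(list(TP = tp, FP = fp, FN = fn,
                 actual = tp + fn, detected = tp + fp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  (actual %d, detected %d)\n",
              x$TP, x$FP, x$FN, x$actual, x$detected))
  invisible(x)
}

# accept turns (t_end + direction), reference (switch_time_s + direction) or
# plain (time + direction) tables as event lists
as_events <- function(x) {
  if (!is.data.frame(x)) stop_input("expected a data.frame of events")
  time <- if (!is.null(x$time)) x$time
          else if (!is.null(x$switch_time_s)) x$switch_time_s
          else if (!is.null(x$t_end)) x$t_end
          else stop_input("event table needs a time, switch_time_s or t_end column")
  if (is.null(x$direction)) stop_input("event table needs a direction column")
  d <- data.frame(time = as.numeric(time),
                  direction = as.character(x$direction),
                  stringsAsFactors = FALSE)
  d[order(d$time), , drop = FALSE]
}

#' Match detected turns against reference turns
#'
#' One-to-one matching of detected events to reference events. A pair may
#' match only if the directions agree and the absolute time difference is
#' smaller than half the mean duration of the actual turns of the run; each
#' detection and each reference is used at most once. `TP` is the number of
#' matched pairs, `FP` the unmatched detections, `FN` the unmatched
#' references. The comparison time of a detected turn is its (fine-tuned)
#' closing switch timestamp.
#'
#' `mode = "greedy"` (default) pairs candidates in increasing order of
#' `abs(dt)`; `mode = "optimal"` computes a maximum-cardinality matching
#' over the feasible pairs (augmenting paths). The two coincide whenever
#' reference events are at least a full tolerance window apart, which the
#' half-mean-duration tolerance guarantees for seamlessly tiling turns.
#'
#' @param detected data.frame of detected turns (`t_end` + `direction`, or
#'   `time` + `direction`).
#' @param reference data.frame of reference turns (`switch_time_s` +
#'   `direction`, or `time` + `direction`).
#' @param run_mean_duration mean actual-turn duration of the run, seconds
#'   (> 0); the matching tolerance is half of it.
#' @param mode `"greedy"` or `"optimal"`.
#' @return A [confusion_counts()].
#' @export
match_events <- function(detected, reference, run_mean_duration,
                         mode = c("greedy", "optimal")) {
  mode <- match.arg(mode)
  if (!is.numeric(run_mean_duration) || run_mean_duration <= 0) {
    stop_param("run_mean_duration must be > 0")
  }
  det <- as_events(detected)
  ref <- as_events(reference)
  tol <- run_mean_duration / 2
  nd <- nrow(det)
  nr <- nrow(ref)
  if (nd == 0L || nr == 0L) {
    return(confusion_counts(0L, nd, nr))
  }
  dt <- abs(outer(det$time, ref$time, `-`))
  ok <- dt < tol & outer(det$direction, ref$direction, `==`)
  tp <- if (mode == "greedy") greedy_tp(dt, ok) else max_matching_tp(ok)
  confusion_counts(tp, nd - tp, nr - tp)
}

greedy_tp <- function(dt, ok) {
  pairs <- which(ok, arr.ind = TRUE)
  if (!nrow(pairs)) return(0L)
  d <- dt[pairs]
  ord <- order(d, pairs[, 2], pairs[, 1])  # |dt|, then reference, then detection
  used_d <- logical(nrow(dt))
  used_r <- logical(ncol(dt))
  tp <- 0L
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_d[i] && !used_r[j]) {
      used_d[i] <- TRUE; used_r[j] <- TRUE; tp <- tp + 1L
    }
  }
  tp
}

# Kuhn's augmenting-path maximum bipartite matching on the feasibility matrix
max_matching_tp <- function(ok) {
  nd <- nrow(ok); nr <- ncol(ok)
  match_r <- rep(0L, nr)
  try_aug <- function(i, seen) {
    for (j in which(ok[i, ])) {
      if (!seen[j]) {
        seen[j] <- TRUE
        if (match_r[j] == 0L || Recall(match_r[j], seen)) {
          match_r[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(nd)) {
    if (try_aug(i, logical(nr))) tp <- tp + 1L
  }
  tp
}

#' Turn-count precision
#'
#' `P = TP / (TP + FP)`: the proportion of detected turns that are actual
#' turns.
#'
#' @param c a [confusion_counts()].
#' @return Fraction in `[0, 1]`; `NaN` with a warning if nothing was
#'   detected.
#' @export
precision <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FP == 0) {
    warning("no detections; precision is undefined (NaN)")
    return(NaN)
  }
  c$TP / (c$TP + c$FP)
}

#' Recall
#'
#' `R = TP / (TP + FN)`: the proportion of actual turns that were detected.
#'
#' @inheritParams precision
#' @return Fraction in `[0, 1]`; `NaN` with a warning if there are no actual
#'   turns.
#' @export
recall <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0) {
    warning("no actual turns; recall is undefined (NaN)")
    return(NaN)
  }
  c$TP / (c$TP + c$FN)
}

#' Detected-to-actual turn-count ratio
#'
#' `detected / actual = (TP + FP) / (TP + FN)`. Above 1 the detector
#' overestimates the number of actual turns, below 1 it underestimates; 1
#' only says the counts agree, not that the right turns were found.
#'
#' @inheritParams precision
#' @return Positive fraction (may exceed 1); `NaN` with a warning if there
#'   are no actual turns.
#' @export
ratio <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$actual == 0) {
    warning("no actual turns; ratio is undefined (NaN)")
    return(NaN)
  }
  c$detected / c$actual
}

#' Evaluate detected turns against a reference, per run and pooled
#'
#' The matching tolerance of each run is half the mean duration of its
#' actual turns, computed as the mean difference of consecutive reference
#' switch times; runs with fewer than two reference turns fall back to
#' `default_turn_duration`. Pooled counts are the sums over runs.
#'
#' @param detected data.frame of detected turns; a `run_id` column pairs it
#'   with the reference (with a single reference run it may be omitted).
#' @param reference data.frame with columns `run_id`, `switch_time_s`,
#'   `direction`.
#' @param mode matching mode, see [match_events()].
#' @param default_turn_duration fallback tolerance basis in seconds.
#' @return List with `per_run` (data.frame: `run_id`, `AT`, `TP`, `FP`,
#'   `FN`, `Ratio`, `Precision`, `Recall`) and `pooled` (one-row data.frame,
#'   same columns).
#' @export
evaluate_runs <- function(detected, reference, mode = c("greedy", "optimal"),
                          default_turn_duration = 2.0) {
  mode <- match.arg(mode)
  if (is.null(reference$run_id)) reference$run_id <- "run1"
  run_ids <- unique(reference$run_id)
  if (is.null(detected$run_id)) {
    if (length(run_ids) > 1L) {
      stop_input("detected turns carry no run_id but the reference has ",
                 length(run_ids), " runs")
    }
    detected$run_id <- rep(run_ids[1], nrow(detected))
  }
  orphan <- setdiff(unique(detected$run_id), run_ids)
  if (length(orphan)) {
    stop_input("run_id(s) in detected but not in reference: ",
               paste(orphan, collapse = ", "))
  }
  rows <- lapply(run_ids, function(rid) {
    ref <- reference[reference$run_id == rid, , drop = FALSE]
    det <- detected[detected$run_id == rid, , drop = FALSE]
    st <- sort(as_events(ref)$time)
    mean_dur <- if (length(st) >= 2L) mean(diff(st)) else default_turn_duration
    cc <- match_events(det, ref, run_mean_duration = mean_dur, mode = mode)
    metrics_row(rid, cc)
  })
  per_run <- do.call(rbind, rows)
  tot <- confusion_counts(sum(per_run$TP), sum(per_run$FP), sum(per_run$FN))
  list(per_run = per_run, pooled = metrics_row("pooled", tot))
}

metrics_row <- function(id, cc) {
  data.frame(
    run_id = id, AT = cc$actual, TP = cc$TP, FP = cc$FP, FN = cc$FN,
    Ratio = suppressWarnings(ratio(cc)),
    Precision = suppressWarnings(precision(cc)),
    Recall = suppressWarnings(recall(cc)),
    stringsAsFactors = FALSE
  )
}
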