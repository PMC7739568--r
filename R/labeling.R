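#' Labeling parameters
#'
#' Thresholds for the heuristic extremum-labeling rules. The rule-1
#' "high rotation rate" bound and the rule-3a low-rate bound are tunables the
#' original method leaves unstated; the shipped defaults were calibrated on
#' simulated runs so that clean parallel turns (edging amplitude >= 0.5
#' rad/s) are all kept while post-stop oscillations (amplitude <= 0.05
#' rad/s) are all eliminated.
#'
#' @param min_switch_rate rule 1: minimum `abs` decision-signal value (rad/s)
#'   for a pair of consecutive extrema to qualify as switches (default 0.2).
#' @param min_gap,max_gap rule 1: a qualifying pair must be more than
#'   `min_gap` and less than `max_gap` seconds apart (defaults 0.3 and 5.0).
#' @param low_rate_threshold rule 3a: extrema below this `abs` value (rad/s)
#'   are eliminated (default 0.1).
#' @param theta1,theta2 rule 3c two-threshold elimination: an unlabeled
#'   extremum with `abs(delta value) <= theta1` (rad/s) and time gap
#'   `<= theta2` (s) to its predecessor is eliminated. Defaults (0.05, 1.0)
#'   come from [train_elimination_thresholds()] on a seeded simulated corpus.
#' @return A list of class `labeling_params`.
#' @export
labeling_params <- function(min_switch_rate = 0.2, min_gap = 0.3, max_gap = 5.0,
                            low_rate_threshold = 0.1, theta1 = 0.05, theta2 = 1.0) {
  if (!(min_gap > 0 && min_gap < max_gap)) {
    stop_param("need 0 < min_gap < max_gap")
  }
  if (min_switch_rate < 0 || low_rate_threshold < 0 || theta1 < 0 || theta2 < 0) {
    stop_param("rate/time thresholds must be non-negative")
  }
  structure(list(min_switch_rate = min_switch_rate, min_gap = min_gap,
                 max_gap = max_gap, low_rate_threshold = low_rate_threshold,
                 theta1 = theta1, theta2 = theta2),
            class = "labeling_params")
}

# add empty label/rule_id columns if absent
as_labeled <- function(extrema) {
  if (is.null(extrema$label)) extrema$label <- rep(NA_character_, nrow(extrema))
  if (is.null(extrema$rule_id)) extrema$rule_id <- rep(NA_character_, nrow(extrema))
  extrema
}

# rule-1 pair predicate, shared by rules 1 and 2
r1_pair_ok <- function(v1, v2, dt, params) {
  abs(v1) >= params$min_switch_rate && abs(v2) >= params$min_switch_rate &&
    v1 * v2 < 0 && dt > params$min_gap && dt < params$max_gap
}

#' Rule 1: label switch pairs
#'
#' Each pair of consecutive extrema with high rotation rate on both sides,
#' opposite sign, and a time distance strictly between `min_gap` and
#' `max_gap` has both members labeled `switch`. An extremum may qualify with
#' either neighbor.
#'
#' @param extrema data.frame from [find_local_extrema()] (optionally already
#'   carrying `label` / `rule_id` columns).
#' @param params a [labeling_params()].
#' @return The data.frame with `label` / `rule_id` columns updated.
#' @export
rule1_switch_pairs <- function(extrema, params = labeling_params()) {
  e <- as_labeled(extrema)
  n <- nrow(e)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (r1_pair_ok(e$value[i], e$value[i + 1L], e$t[i + 1L] - e$t[i], params)) {
        for (j in c(i, i + 1L)) {
          if (is.na(e$label[j])) {
            e$label[j] <- "switch"
            e$rule_id[j] <- "1"
          }
        }
      }
    }
  }
  e
}

#' Rule 2: label within-turn noise
#'
#' In every window of four consecutive extrema whose outer two satisfy the
#' rule-1 pair conditions with each other, whose inner two are not labeled
#' `switch`, and whose inner absolute values are both smaller than both
#' outer absolute values, the inner two are labeled `noise`. This captures
#' the saddle / counter-oscillation artifacts of long turns.
#'
#' @inheritParams rule1_switch_pairs
#' @return Updated data.frame.
#' @export
rule2_noise <- function(extrema, params = labeling_params()) {
  e <- as_labeled(extrema)
  n <- nrow(e)
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      o1 <- i; o2 <- i + 3L
      i1 <- i + 1L; i2 <- i + 2L
      inner_not_switch <- !identical(e$label[i1], "switch") &&
        !identical(e$label[i2], "switch")
      if (r1_pair_ok(e$value[o1], e$value[o2], e$t[o2] - e$t[o1], params) &&
          inner_not_switch &&
          max(abs(e$value[c(i1, i2)])) < min(abs(e$value[c(o1, o2)]))) {
        for (j in c(i1, i2)) {
          if (is.na(e$label[j])) {
            e$label[j] <- "noise"
            e$rule_id[j] <- "2"
          }
        }
      }
    }
  }
  e
}

#' Rule 3: eliminate outside-turn extrema
#'
#' Three sub-rules applied in order to the still-unlabeled extrema:
#' * 3a — absolute value below `low_rate_threshold` (small oscillations while
#'   standing, gliding or skiing straight);
#' * 3b — same decision-signal sign as the immediately preceding extremum
#'   (no alternation, so no edge change);
#' * 3c — the learned two-threshold rule:
#'   `abs(delta value) <= theta1` and time gap `<= theta2` to the preceding
#'   extremum.
#'
#' Earlier labels are never overwritten; differences in 3b/3c are always
#' taken to the immediate predecessor extremum regardless of its label.
#'
#' @inheritParams rule1_switch_pairs
#' @return Updated data.frame (`rule_id` records `"3a"`, `"3b"` or `"3c"`).
#' @export
rule3_eliminate <- function(extrema, params = labeling_params()) {
  e <- as_labeled(extrema)
  n <- nrow(e)
  if (n == 0L) return(e)
  # 3a
  for (i in seq_len(n)) {
    if (is.na(e$label[i]) && abs(e$value[i]) < params$low_rate_threshold) {
      e$label[i] <- "eliminated"; e$rule_id[i] <- "3a"
    }
  }
  # 3b
  if (n >= 2L) {
    for (i in 2:n) {
      if (is.na(e$label[i]) && sign(e$value[i]) == sign(e$value[i - 1L])) {
        e$label[i] <- "eliminated"; e$rule_id[i] <- "3b"
      }
    }
  }
  # 3c
  if (n >= 2L) {
    for (i in 2:n) {
      if (is.na(e$label[i]) &&
          abs(e$value[i] - e$value[i - 1L]) <= params$theta1 &&
          (e$t[i] - e$t[i - 1L]) <= params$theta2) {
        e$label[i] <- "eliminated"; e$rule_id[i] <- "3c"
      }
    }
  }
  e
}

#' Rule 4: eliminate extrema stranded between eliminated neighbors
#'
#' Applied iteratively until no label changes, because an elimination in one
#' pass can expose new candidates. An unlabeled extremum is eliminated when
#' every neighbor is eliminated or (still) unlabeled and at least one
#' neighbor is already eliminated; at the first/last extremum the single
#' existing neighbor decides.
#'
#' @inheritParams rule1_switch_pairs
#' @return Updated data.frame.
#' @export
rule4_eliminate_isolated <- function(extrema) {
  e <- as_labeled(extrema)
  n <- nrow(e)
  if (n == 0L) return(e)
  repeat {
    lab <- e$label
    fire <- logical(n)
    for (i in seq_len(n)) {
      if (!is.na(lab[i])) next
      neigh <- lab[c(if (i > 1L) i - 1L, if (i < n) i + 1L)]
      ok <- is.na(neigh) | neigh == "eliminated"
      if (length(neigh) && all(ok) && any(neigh == "eliminated", na.rm = TRUE)) {
        fire[i] <- TRUE
      }
    }
    if (!any(fire)) break
    e$label[fire] <- "eliminated"
    e$rule_id[fire] <- "4"
  }
  e
}

#' Rule 5: remaining extrema become switches
#'
#' @inheritParams rule1_switch_pairs
#' @return Fully labeled data.frame (no `NA` labels remain).
#' @export
rule5_remaining_switch <- function(extrema) {
  e <- as_labeled(extrema)
  un <- is.na(e$label)
  e$label[un] <- "switch"
  e$rule_id[un] <- "5"
  e
}

#' Label decision-signal extrema
#'
#' Runs the heuristic rules in their fixed order — 1 (switch pairs),
#' 2 (within-turn noise), 3a/3b/3c (elimination), 4 to fixpoint, 5
#' (remaining become switches) — and returns every extremum carrying exactly
#' one label from `{switch, noise, eliminated}` plus the id of the rule that
#' assigned it. Deterministic for fixed input and parameters; earlier labels
#' are never overwritten.
#'
#' @param extrema data.frame from [find_local_extrema()] of the decision
#'   signal.
#' @param params a [labeling_params()].
#' @return The input data.frame with `label` and `rule_id` columns.
#' @export
label_extrema <- function(extrema, params = labeling_params()) {
  e <- rule1_switch_pairs(extrema, params)
  e <- rule2_noise(e, params)
  e <- rule3_eliminate(e, params)
  e <- rule4_eliminate_isolated(e)
  rule5_remaining_switch(e)
}

#' Export labeled extrema to CSV (debugging aid)
#'
#' @param labeled data.frame from [label_extrema()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(labeled, path) {
  write.csv(labeled[, c("t", "value", "kind", "label", "rule_id")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
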