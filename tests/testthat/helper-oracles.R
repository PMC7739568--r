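# Independent oracles and fixture builders. The oracles are deliberate
# re-transcriptions of the rules with no code shared with the package.

# build an extrema data.frame from times and values; kinds follow the
# zigzag implied by the values (labeling never reads `kind`, fine-tuning does)
make_extrema <- function(t, v, label = NULL, rule_id = NULL) {
  n <- length(v)
  kind <- character(n)
  if (n == 0L) {
    kind <- character(0)
  } else if (n == 1L) {
    kind <- "max"
  } else {
    kind[1] <- if (v[1] > v[2]) "max" else "min"
    for (i in seq_len(n)[-1]) kind[i] <- if (kind[i - 1] == "max") "min" else "max"
  }
  d <- data.frame(index = seq_len(n), t = t, value = v, kind = kind,
                  stringsAsFactors = FALSE)
  if (!is.null(label)) d$label <- label
  if (!is.null(rule_id)) d$rule_id <- rule_id
  d
}

# literal brute-force transcription of labeling rules 1-5
oracle_label <- function(t, v, p) {
  n <- length(v)
  lab <- rep(NA_character_, n)
  opposite <- function(a, b) (a < 0 && b > 0) || (a > 0 && b < 0)
  pair_rule1 <- function(i, j) {
    gap <- t[j] - t[i]
    abs(v[i]) >= p$min_switch_rate && abs(v[j]) >= p$min_switch_rate &&
      opposite(v[i], v[j]) && gap > p$min_gap && gap < p$max_gap
  }
  # rule 1: consecutive pairs
  i <- 1L
  while (i < n) {
    if (pair_rule1(i, i + 1L)) {
      if (is.na(lab[i])) lab[i] <- "switch"
      if (is.na(lab[i + 1L])) lab[i + 1L] <- "switch"
    }
    i <- i + 1L
  }
  # rule 2: 4-windows
  if (n >= 4L) {
    for (a in 1:(n - 3L)) {
      d <- a + 3L
      inner <- c(a + 1L, a + 2L)
      if (pair_rule1(a, d) &&
          !("switch" %in% lab[inner]) &&
          abs(v[inner[1]]) < abs(v[a]) && abs(v[inner[1]]) < abs(v[d]) &&
          abs(v[inner[2]]) < abs(v[a]) && abs(v[inner[2]]) < abs(v[d])) {
        for (j in inner) if (is.na(lab[j])) lab[j] <- "noise"
      }
    }
  }
  # rule 3a
  for (i in seq_len(n)) {
    if (is.na(lab[i]) && abs(v[i]) < p$low_rate_threshold) lab[i] <- "eliminated"
  }
  # rule 3b
  for (i in seq_len(n)) {
    if (i >= 2L && is.na(lab[i]) &&
        ((v[i] >= 0 && v[i - 1L] >= 0 && (v[i] > 0) == (v[i - 1L] > 0)) ||
         (v[i] < 0 && v[i - 1L] < 0))) {
      lab[i] <- "eliminated"
    }
  }
  # rule 3c
  for (i in seq_len(n)) {
    if (i >= 2L && is.na(lab[i]) &&
        abs(v[i] - v[i - 1L]) <= p$theta1 && (t[i] - t[i - 1L]) <= p$theta2) {
      lab[i] <- "eliminated"
    }
  }
  # rule 4, simultaneous update to fixpoint: every existing neighbor must be
  # eliminated or still unlabeled, and at least one must be eliminated
  repeat {
    newly <- integer(0)
    for (i in seq_len(n)) {
      if (!is.na(lab[i])) next
      nb <- c(if (i > 1L) lab[i - 1L], if (i < n) lab[i + 1L])
      if (!length(nb)) next
      all_ok <- TRUE
      has_elim <- FALSE
      for (x in nb) {
        if (!is.na(x) && x != "eliminated") all_ok <- FALSE
        if (!is.na(x) && x == "eliminated") has_elim <- TRUE
      }
      if (all_ok && has_elim) newly <- c(newly, i)
    }
    if (!length(newly)) break
    lab[newly] <- "eliminated"
  }
  # rule 5
  lab[is.na(lab)] <- "switch"
  lab
}

# exhaustive maximum-cardinality matching over feasible pairs
oracle_max_matching <- function(det_t, det_d, ref_t, ref_d, tol) {
  nr <- length(ref_t)
  nd <- length(det_t)
  best <- 0L
  recurse <- function(j, used_d, count) {
    if (count + (nr - j + 1L) <= best) return()
    if (j > nr) {
      if (count > best) best <<- count
      return()
    }
    recurse(j + 1L, used_d, count)  # leave reference j unmatched
    for (i in seq_len(nd)) {
      if (!used_d[i] && det_d[i] == ref_d[j] && abs(det_t[i] - ref_t[j]) < tol) {
        used_d[i] <- TRUE
        recurse(j + 1L, used_d, count + 1L)
        used_d[i] <- FALSE
      }
    }
  }
  recurse(1L, logical(nd), 0L)
  best
}

# clean carved simulation used by several tests
clean_carved_sim <- function(seed, n_turns = 10, duration = 2, duration_sd = 0) {
  sim_config(seed = seed, noise_sd = 0, saddle_probability = 0,
             segments = list(sim_segment("carved_long", n_turns = n_turns,
                                         turn_duration = duration,
                                         turn_duration_sd = duration_sd)))
}
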