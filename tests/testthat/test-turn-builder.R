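switches <- function(t, v, label = "switch") {
  make_extrema(t, v, label = rep(label, length.out = length(v)),
               rule_id = rep("1", length(v)))
}

test_that("an uninterrupted run of k switches yields k-1 tiling turns", {
  e <- switches(1:4, c(1, -0.9, 1.1, -1))
  turns <- build_turns(e)
  expect_equal(nrow(turns), 3L)
  expect_equal(turns$sequence_id, rep(1L, 3))
  expect_equal(turns$t_start, 1:3)
  expect_equal(turns$t_end, 2:4)
  expect_equal(turns$direction, c("right", "left", "right"))
})

test_that("eliminated extrema split sequences; noise is ignored", {
  e <- rbind(switches(c(1, 2), c(1, -1)),
             switches(3, 0.02, label = "eliminated"),
             switches(c(4, 5), c(1, -1)))
  turns <- build_turns(e)
  expect_equal(nrow(turns), 2L)
  expect_equal(turns$sequence_id, c(1L, 2L))
  expect_equal(turns$turn_index, c(1L, 1L))

  e <- rbind(switches(1, 1),
             switches(c(1.8, 2.2), c(-0.1, 0.1), label = "noise"),
             switches(3, -1))
  turns <- build_turns(e)
  expect_equal(nrow(turns), 1L)
  expect_equal(turns[1, c("t_start", "t_end")], data.frame(t_start = 1, t_end = 3),
               ignore_attr = TRUE)
})

test_that("isolated single switches produce no turn", {
  e <- rbind(switches(1, 1),
             switches(2, 0.01, label = "eliminated"),
             switches(c(3, 4, 5), c(1, -1, 1)))
  turns <- build_turns(e)
  expect_equal(nrow(turns), 2L)
  expect_equal(unique(turns$sequence_id), 1L)  # only the yielding run gets an id
})

test_that("opening and closing direction conventions agree", {
  e <- switches(1:5, c(1, -1, 1, -1, 1))
  a <- build_turns(e, direction_convention = "opening")
  b <- build_turns(e, direction_convention = "closing")
  expect_equal(a$direction, b$direction)
  # a positive (max) closing switch ends a left turn
  expect_equal(b$direction[2], "left")
})

test_that("same-sign adjacency splits the sequence by default and can error", {
  e <- rbind(switches(1, 1),
             switches(2, -0.15, label = "noise"),
             switches(3, 0.8), switches(4, -0.9))
  turns <- build_turns(e)  # split at the repeated sign
  expect_equal(nrow(turns), 1L)
  expect_equal(turns$t_start, 3)
  expect_error(build_turns(e, alternation = "error"),
               class = "skiturn_internal_error")
})

test_that("build_turns requires full labeling", {
  e <- make_extrema(1:2, c(1, -1), label = c("switch", NA), rule_id = c("1", NA))
  expect_error(build_turns(e), class = "skiturn_input_error")
})

test_that("fine tuning with p = 0 leaves timestamps unchanged", {
  sim <- simulate_run(clean_carved_sim(21))
  cfg <- default_config()
  cfg$fine_tune$p <- 0
  t0 <- detect_turns(sim$left, sim$right, cfg)
  cfg$fine_tune$p <- 0.6
  t6 <- detect_turns(sim$left, sim$right, cfg)
  expect_equal(nrow(t0), nrow(t6))
  # p = 0.6 shifts timestamps by at most the epsilon window
  expect_lt(max(abs(t0$t_end - t6$t_end)), 0.6 * 2.5)
})

test_that("fine tuning matches a brute-force window argmax and stays in window", {
  # asymmetric sawtooth-like ds/ft pair with known offset between extrema
  fs <- 64
  t <- seq(0, 20, by = 1 / fs)
  mean_sig <- uniform_series(-(sin(2 * pi * t / 4) + 0.35 * sin(4 * pi * t / 4)), 0, fs)
  ds <- decision_signal(mean_sig)
  ft <- fine_tune_signal(mean_sig)
  lab <- label_extrema(find_local_extrema(ds))
  sw <- lab[lab$label == "switch", ]
  turns <- build_turns(lab)
  tuned <- fine_tune_switches(turns, sw, ft, p = 0.6)
  times <- sort(unique(c(turns$t_start, turns$t_end)))
  tuned_times <- sort(unique(c(tuned$t_start, tuned$t_end)))
  tt <- series_time(ft)
  for (i in seq_along(times)) {
    gap_prev <- if (i > 1) times[i] - times[i - 1] else times[i + 1] - times[i]
    gap_next <- if (i < length(times)) times[i + 1] - times[i] else gap_prev
    lo <- times[i] - 0.6 * gap_prev
    hi <- times[i] + 0.6 * gap_next
    expect_gte(tuned_times[i], lo - 1e-9)
    expect_lte(tuned_times[i], hi + 1e-9)
    # brute-force argmax/argmin over the window
    k <- sw$kind[which.min(abs(sw$t - times[i]))]
    win <- which(tt >= lo & tt <= hi)
    target <- if (k == "max") win[which.max(ft$values[win])] else win[which.min(ft$values[win])]
    expect_lt(abs(tuned_times[i] - tt[target]), 1 / fs + 1e-9)
  }
  # tiling and alternation survive fine tuning
  for (s in unique(tuned$sequence_id)) {
    seq_rows <- tuned[tuned$sequence_id == s, ]
    if (nrow(seq_rows) > 1) {
      expect_equal(seq_rows$t_start[-1], seq_rows$t_end[-nrow(seq_rows)])
      expect_true(all(seq_rows$direction[-1] != seq_rows$direction[-nrow(seq_rows)]))
    }
  }
})

test_that("detect_turns recovers a clean simulated run exactly", {
  run <- simulate_run(clean_carved_sim(1, n_turns = 10, duration = 2))
  turns <- detect_turns(run$left, run$right)
  expect_equal(nrow(turns), 10L)
  expect_equal(length(unique(turns$sequence_id)), 1L)
  expect_lt(max(abs(sort(turns$t_end) - sort(run$truth$switch_time_s))), 0.1)
  # tiling within the sequence
  expect_equal(turns$t_start[-1], turns$t_end[-10])
  expect_true(all(turns$direction[-1] != turns$direction[-10]))
})

test_that("stationary noise yields no turn sequences", {
  set.seed(5)
  t <- seq(0, 20, by = 1 / 64)
  mk <- function(side) gyro_stream(t, rnorm(length(t), 0, 0.03),
                                   rnorm(length(t), 0, 0.03),
                                   rnorm(length(t), 0, 0.03), side)
  expect_equal(nrow(detect_turns(mk("left"), mk("right"))), 0L)
})

test_that("a long stop splits the recording into two sequences", {
  sc <- sim_config(seed = 3, segments = list(
    sim_segment("carved_long", n_turns = 8),
    sim_segment("stop", duration = 30),
    sim_segment("carved_long", n_turns = 8)))
  run <- simulate_run(sc)
  turns <- detect_turns(run$left, run$right)
  expect_equal(length(unique(turns$sequence_id)), 2L)
  expect_equal(sort(unique(turns$sequence_id)), c(1L, 2L))
})

test_that("zeroing a block of the recording never increases the turn count", {
  run <- simulate_run(clean_carved_sim(6, n_turns = 12))
  base <- nrow(detect_turns(run$left, run$right))
  for (win in list(c(5, 10), c(0, 8), c(12, 30))) {
    zero_block <- function(s) {
      idx <- s$t >= win[1] & s$t <= win[2]
      s$gyro_z[idx] <- 0
      s
    }
    n <- nrow(detect_turns(zero_block(run$left), zero_block(run$right)))
    expect_lte(n, base)
  }
})

test_that("non-overlapping streams are rejected", {
  t1 <- seq(0, 5, by = 1 / 64)
  a <- gyro_stream(t1, t1 * 0, t1 * 0, sin(t1), "left")
  b <- gyro_stream(t1 + 10, t1 * 0, t1 * 0, sin(t1), "right")
  expect_error(detect_turns(a, b), class = "skiturn_input_error")
})

test_that("transmission gaps split processing and sequence ids continue", {
  run <- simulate_run(sim_config(seed = 4, segments = list(
    sim_segment("carved_long", n_turns = 8))))
  keep <- !(run$left$t > 12 & run$left$t < 15)
  l2 <- gyro_stream(run$left$t[keep], run$left$gyro_x[keep],
                    run$left$gyro_y[keep], run$left$gyro_z[keep], "left")
  turns <- detect_turns(l2, run$right)
  expect_gt(length(unique(turns$sequence_id)), 1L)
  expect_equal(sort(unique(turns$sequence_id)),
               seq_along(unique(turns$sequence_id)))
})
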