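p0 <- labeling_params()

test_that("rule 1 labels opposite-sign high-rate pairs within the time window", {
  e <- rule1_switch_pairs(make_extrema(c(1, 2), c(1.0, -1.2)), p0)
  expect_equal(e$label, c("switch", "switch"))
  expect_equal(e$rule_id, c("1", "1"))
  # gap below 0.3 s disqualifies
  e <- rule1_switch_pairs(make_extrema(c(1, 1.2), c(1.0, -1.2)), p0)
  expect_true(all(is.na(e$label)))
  # gap above 5 s disqualifies
  e <- rule1_switch_pairs(make_extrema(c(1, 6.5), c(1.0, -1.2)), p0)
  expect_true(all(is.na(e$label)))
  # same sign disqualifies
  e <- rule1_switch_pairs(make_extrema(c(1, 2), c(1.0, 0.8)), p0)
  expect_true(all(is.na(e$label)))
  # low rate disqualifies
  e <- rule1_switch_pairs(make_extrema(c(1, 2), c(1.0, -0.1)), p0)
  expect_true(all(is.na(e$label)))
  expect_equal(nrow(rule1_switch_pairs(make_extrema(numeric(0), numeric(0)), p0)), 0L)
})

test_that("rule 2 labels the saddle pattern as noise, respecting prior switches", {
  e <- label_extrema(make_extrema(c(0, 1, 2, 3), c(1.0, -0.1, 0.1, -1.0)), p0)
  expect_equal(e$label, c("switch", "noise", "noise", "switch"))
  expect_equal(e$rule_id[2:3], c("2", "2"))
  # inner pair already switch-worthy: no noise
  e <- label_extrema(make_extrema(c(0, 1, 2, 3), c(1.0, -0.9, 0.9, -1.0)), p0)
  expect_equal(e$label, rep("switch", 4))
  # fewer than 4 extrema: rule 2 is a no-op
  e3 <- make_extrema(c(0, 1, 2), c(1.0, -0.1, 1.0))
  expect_equal(rule2_noise(e3, p0)$label, rep(NA_character_, 3))
})

test_that("rule 3 sub-rules fire in order a, b, c", {
  # 3a: low rate
  e <- rule3_eliminate(make_extrema(1, 0.01), labeling_params(low_rate_threshold = 0.05))
  expect_equal(e$label, "eliminated")
  expect_equal(e$rule_id, "3a")
  # 3b: same sign as predecessor (predecessor label irrelevant)
  e <- rule3_eliminate(make_extrema(c(1, 2), c(0.5, 0.4)), p0)
  expect_equal(e$label[2], "eliminated")
  expect_equal(e$rule_id[2], "3b")
  # same sign wins before 3c can be reached
  prm <- labeling_params(theta1 = 0.05, theta2 = 1.0)
  e <- rule3_eliminate(make_extrema(c(1, 1.4), c(0.16, 0.18)), prm)
  expect_equal(e$rule_id[2], "3b")
  # opposite sign, delta above theta1: survives rule 3 entirely
  e <- rule3_eliminate(make_extrema(c(1, 1.4), c(-0.15, 0.13)), prm)
  expect_true(is.na(e$label[2]))
  # 3c proper: opposite sign, small delta, short gap
  prm2 <- labeling_params(theta1 = 0.25, theta2 = 1.0)
  e <- rule3_eliminate(make_extrema(c(1, 1.4), c(-0.11, 0.12)), prm2)
  expect_equal(e$rule_id[2], "3c")
  # the same pair with a gap above theta2 survives
  e <- rule3_eliminate(make_extrema(c(1, 2.6), c(-0.11, 0.12)), prm2)
  expect_true(is.na(e$label[2]))
  # a value qualifying for both 3a and 3c gets 3a (order a, b, c)
  e <- rule3_eliminate(make_extrema(c(1, 1.4), c(-0.11, 0.05)), prm2)
  expect_equal(e$rule_id[2], "3a")
})

test_that("rule 4 eliminates stranded extrema iteratively, one-sided at the ends", {
  lab <- function(l) make_extrema(seq_along(l), ifelse(seq_along(l) %% 2 == 0, -0.5, 0.5),
                                  label = l, rule_id = ifelse(is.na(l), NA, "x"))
  e <- rule4_eliminate_isolated(lab(c("eliminated", NA, "eliminated")))
  expect_equal(e$label[2], "eliminated")
  expect_equal(e$rule_id[2], "4")
  e <- rule4_eliminate_isolated(lab(c("switch", NA, "eliminated")))
  expect_true(is.na(e$label[2]))
  # a pass exposes new candidates: both interior extrema fall
  e <- rule4_eliminate_isolated(lab(c("eliminated", NA, NA, "eliminated")))
  expect_equal(e$label, rep("eliminated", 4))
  # boundary: a single eliminated neighbor suffices
  e <- rule4_eliminate_isolated(lab(c(NA, "eliminated")))
  expect_equal(e$label[1], "eliminated")
  e <- rule4_eliminate_isolated(lab(c("eliminated", NA, NA, "switch")))
  expect_equal(e$label[2], "eliminated")
  expect_true(is.na(e$label[3]))
})

test_that("rule 5 switches the survivors and completes the labeling", {
  e <- make_extrema(c(1, 2), c(0.5, -0.5), label = c("switch", NA),
                    rule_id = c("1", NA))
  out <- rule5_remaining_switch(e)
  expect_equal(out$label, c("switch", "switch"))
  expect_equal(out$rule_id, c("1", "5"))
  expect_identical(rule5_remaining_switch(out), out)  # fully labeled: identity
  expect_equal(nrow(rule5_remaining_switch(make_extrema(numeric(0), numeric(0)))), 0L)
})

test_that("label_extrema labels everything exactly once and is idempotent", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    v <- round(runif(n, 0.02, 1.2), 2) * sample(c(-1, 1), n, replace = TRUE)
    t <- cumsum(c(0, runif(n - 1, 0.1, 3)))
    e <- label_extrema(make_extrema(t, v), p0)
    expect_false(anyNA(e$label))
    expect_true(all(e$label %in% c("switch", "noise", "eliminated")))
    expect_identical(label_extrema(e, p0), e)
  }
})

test_that("raising the low-rate threshold never turns eliminated into switch", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    v <- round(runif(n, 0.01, 0.8), 2) * sample(c(-1, 1), n, replace = TRUE)
    t <- cumsum(c(0, runif(n - 1, 0.2, 2)))
    lo <- label_extrema(make_extrema(t, v), labeling_params(low_rate_threshold = 0.05))
    hi <- label_extrema(make_extrema(t, v), labeling_params(low_rate_threshold = 0.15))
    was_elim <- lo$label == "eliminated"
    expect_false(any(hi$label[was_elim] == "switch"))
  }
})

test_that("labeling matches the brute-force oracle on random sequences", {
  set.seed(99)
  grid <- c(-1.1, -0.6, -0.15, -0.04, 0.04, 0.12, 0.5, 1.0)
  gaps <- c(0.1, 0.25, 0.45, 0.8, 1.5, 4.0, 6.0)
  for (rep in 1:300) {
    n <- sample(1:8, 1)
    v <- sample(grid, n, replace = TRUE)
    t <- cumsum(c(0, sample(gaps, max(0, n - 1), replace = TRUE)))
    got <- label_extrema(make_extrema(t, v), p0)$label
    expect_identical(got, oracle_label(t, v, p0))
  }
})

test_that("threshold training recovers a planted rule with perfect CV accuracy", {
  set.seed(2)
  f <- data.frame(
    delta_omega = runif(400, 0, 0.2) * sample(c(-1, 1), 400, replace = TRUE),
    dt = runif(400, 0, 2)
  )
  f$eliminated <- abs(f$delta_omega) < 0.05 & f$dt < 1
  fit <- train_elimination_thresholds(f, fold_count = 5, seed = 3)
  # recovered within one grid step of the planted thresholds
  step1 <- max(diff(sort(unique(abs(f$delta_omega)))))
  step2 <- max(diff(sort(unique(f$dt))))
  expect_lt(abs(fit$theta1 - 0.05), max(step1, 0.01) + 1e-9)
  expect_lt(abs(fit$theta2 - 1.0), max(step2, 0.05) + 1e-9)
  expect_equal(fit$cv_accuracy, 1.0)
})

test_that("training on label-independent features scores near the majority rate", {
  set.seed(8)
  f <- data.frame(delta_omega = runif(500, 0, 0.3), dt = runif(500, 0, 3),
                  eliminated = sample(c(TRUE, FALSE), 500, replace = TRUE,
                                      prob = c(0.3, 0.7)))
  fit <- train_elimination_thresholds(f, fold_count = 5, seed = 4)
  expect_lt(abs(fit$cv_accuracy - max(mean(f$eliminated), 1 - mean(f$eliminated))),
            0.08)
})

test_that("training validates folds and class balance", {
  f <- data.frame(delta_omega = runif(50), dt = runif(50),
                  eliminated = rep(c(TRUE, FALSE), 25))
  expect_error(train_elimination_thresholds(f, fold_count = 1),
               class = "skiturn_parameter_error")
  f$eliminated <- TRUE
  expect_error(train_elimination_thresholds(f), class = "skiturn_input_error")
})

test_that("the learned rule agrees with a depth-2 tree on separable data", {
  skip_if_not_installed("rpart")
  set.seed(5)
  f <- data.frame(
    delta_omega = runif(600, 0, 0.2) * sample(c(-1, 1), 600, replace = TRUE),
    dt = runif(600, 0, 2)
  )
  f$eliminated <- abs(f$delta_omega) < 0.06 & f$dt < 0.9
  fit <- train_elimination_thresholds(f, seed = 6)
  tree <- rpart::rpart(eliminated ~ abs_do + dt,
                       data = data.frame(abs_do = abs(f$delta_omega), dt = f$dt,
                                         eliminated = factor(f$eliminated)),
                       method = "class", control = rpart::rpart.control(maxdepth = 2, cp = 0))
  pred_rule <- abs(f$delta_omega) <= fit$theta1 & f$dt <= fit$theta2
  pred_tree <- predict(tree, type = "class") == "TRUE"
  expect_gt(mean(pred_rule == pred_tree), 0.98)
})
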