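#' Train the two-threshold elimination rule
#'
#' Learns the axis-aligned threshold pair `(theta1, theta2)` of the rule
#' `abs(delta value) <= theta1 AND dt <= theta2 -> eliminated` — the
#' depth-2 decision tree restricted to the two most expressive extremum
#' features: the value change to the predecessor extremum and the time gap
#' to it. A grid search over candidate split points (midpoints between
#' consecutive sorted feature values) maximizes classification accuracy;
#' k-fold cross-validation (per-fold selection on the training folds, scored
#' on the held-out fold) estimates generalization.
#'
#' @param features data.frame with columns `delta_omega` (rad/s, change in
#'   decision-signal value to the predecessor; sign ignored), `dt` (s, time
#'   gap to the predecessor) and `eliminated` (logical: `TRUE` = outside a
#'   turn sequence).
#' @param fold_count number of CV folds, >= 2 (default 5).
#' @param seed integer seed for the fold assignment (default 1), making the
#'   result deterministic.
#' @param max_grid cap on the number of candidate thresholds per feature
#'   (default 64; quantile-thinned above that).
#' @return List of class `elimination_thresholds` with `theta1`, `theta2`,
#'   `cv_accuracy`, `train_accuracy` and `n`.
#' @examples
#' f <- data.frame(delta_omega = runif(100, 0, 0.2), dt = runif(100, 0, 2))
#' f$eliminated <- abs(f$delta_omega) < 0.05 & f$dt < 1
#' train_elimination_thresholds(f)
#' @export
train_elimination_thresholds <- function(features, fold_count = 5, seed = 1,
                                         max_grid = 64) {
  need <- c("delta_omega", "dt", "eliminated")
  missing <- setdiff(need, names(features))
  if (length(missing)) {
    stop_input("features must have columns ", paste(need, collapse = ", "))
  }
  if (fold_count < 2) stop_param("fold_count must be >= 2")
  x1 <- abs(features$delta_omega)
  x2 <- features$dt
  y <- as.logical(features$eliminated)
  n <- length(y)
  if (n < fold_count) stop_input("fewer rows than folds")
  if (length(unique(y)) < 2L) {
    stop_input("training data contains a single class; cannot train")
  }

  candidates <- function(x) {
    u <- sort(unique(x))
    if (length(u) > max_grid) {
      u <- unique(quantile(x, probs = seq(0, 1, length.out = max_grid),
                           names = FALSE, type = 1))
    }
    if (length(u) == 1L) return(u)
    c(u[1] - diff(range(u)) / length(u), (u[-length(u)] + u[-1]) / 2, u[length(u)])
  }
  g1 <- candidates(x1)
  g2 <- candidates(x2)

  best_pair <- function(idx) {
    best <- c(acc = -1, t1 = g1[1], t2 = g2[1])
    for (t1 in g1) {
      hit1 <- x1[idx] <= t1
      for (t2 in g2) {
        pred <- hit1 & x2[idx] <= t2
        acc <- mean(pred == y[idx])
        if (acc > best["acc"] + 1e-12) best <- c(acc = acc, t1 = t1, t2 = t2)
      }
    }
    best
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(fold_count), n))

  cv <- numeric(fold_count)
  for (k in seq_len(fold_count)) {
    train <- which(fold != k)
    test <- which(fold == k)
    b <- best_pair(train)
    pred <- x1[test] <= b["t1"] & x2[test] <= b["t2"]
    cv[k] <- mean(pred == y[test])
  }

  b <- best_pair(seq_len(n))
  structure(list(theta1 = unname(b["t1"]), theta2 = unname(b["t2"]),
                 cv_accuracy = mean(cv), train_accuracy = unname(b["acc"]),
                 n = n),
            class = "elimination_thresholds")
}

#' @export
print.elimination_thresholds <- function(x, ...) {
  cat(sprintf(paste0("Elimination rule: abs(delta omega_ds) <= %.4g rad/s ",
                     "AND dt <= %.4g s -> eliminated\n"),
              x$theta1, x$theta2))
  cat(sprintf("CV accuracy %.3f, training accuracy %.3f (n = %d)\n",
              x$cv_accuracy, x$train_accuracy, x$n))
  invisible(x)
}

#' Extract elimination-rule training features from labeled extrema
#'
#' Projects labeled extrema into the feature table consumed by
#' [train_elimination_thresholds()]: per extremum, the value change and time
#' gap to its predecessor, and whether it lies outside a turn sequence
#' (label `eliminated`). The first extremum has no predecessor and is
#' dropped.
#'
#' @param labeled data.frame from [label_extrema()].
#' @return data.frame with columns `delta_omega`, `dt`, `eliminated`.
#' @export
elimination_features <- function(labeled) {
  n <- nrow(labeled)
  if (n < 2L) {
    return(data.frame(delta_omega = numeric(0), dt = numeric(0),
                      eliminated = logical(0)))
  }
  data.frame(
    delta_omega = diff(labeled$value),
    dt = diff(labeled$t),
    eliminated = labeled$label[-1] == "eliminated"
  )
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
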