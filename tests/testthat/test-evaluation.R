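## independent brute-force metric oracle: explicit loops over classes
oracle_metrics <- function(y_true, y_pred, levels = 0:3) {
  per <- lapply(levels, function(lv) {
    tp <- sum(y_true == lv & y_pred == lv)
    fp <- sum(y_true != lv & y_pred == lv)
    fn <- sum(y_true == lv & y_pred != lv)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(support = sum(y_true == lv), p = p, r = r, f = f)
  })
  m <- do.call(rbind, per)
  present <- vapply(levels, function(lv) any(y_true == lv) || any(y_pred == lv),
                    logical(1))
  w <- m[, "support"] / sum(m[, "support"])
  list(macro_f1 = mean(m[present, "f"]),
       macro_p = mean(m[present, "p"]),
       macro_r = mean(m[present, "r"]),
       weighted_f1 = sum(w * m[, "f"]),
       weighted_p = sum(w * m[, "p"]),
       weighted_r = sum(w * m[, "r"]))
}

test_that("the worked confusion-matrix example evaluates to macro F1 = 11/15", {
  ev <- global_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(ev$per_class$f1[1], 2 / 3)
  expect_equal(ev$per_class$f1[2], 4 / 5)
  expect_equal(ev$macro$f1, 11 / 15)
  expect_identical(ev$excluded_classes, c(2L, 3L))
})

test_that("perfect predictions score 1 and constant predictions hit chance recall", {
  y <- rep(0:3, each = 25)
  perf <- global_metrics(y, y)
  expect_equal(perf$macro$f1, 1)
  expect_equal(perf$weighted$precision, 1)
  const <- global_metrics(y, rep(2L, 100))
  expect_equal(const$macro$recall, 0.25)
})

test_that("global metrics agree with a brute-force oracle on random label vectors", {
  set.seed(50)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- sample(0:3, n, replace = TRUE)
    p <- sample(0:3, n, replace = TRUE)
    ev <- global_metrics(y, p)
    o <- oracle_metrics(y, p)
    expect_equal(ev$macro$f1, o$macro_f1, tolerance = 1e-12)
    expect_equal(ev$macro$precision, o$macro_p, tolerance = 1e-12)
    expect_equal(ev$weighted$f1, o$weighted_f1, tolerance = 1e-12)
    expect_equal(ev$weighted$recall, o$weighted_r, tolerance = 1e-12)
    expect_equal(sum(ev$confusion), n)
    expect_equal(as.integer(rowSums(ev$confusion)),
                 vapply(0:3, function(l) sum(y == l), integer(1)))
  }
})

test_that("balanced training sets hold exactly the per-class budget", {
  set.seed(51)
  ds <- dplyr::bind_rows(
    label_table(400, prevalence = c(0.4, 0.3, 0.2, 0.1), pid = "a", seed = 52),
    label_table(400, prevalence = c(0.1, 0.2, 0.3, 0.4), pid = "b", seed = 53)
  )
  budget <- 20 / 720 # 20 segments per class
  tr <- make_balanced_trainset(ds, budget, test_participant = NULL, seed = 54)
  counts <- table(tr$chaos_level)
  expect_true(all(counts == 20))
  for (lv in 1:3) {
    keys <- segment_key(tr$participant_id[tr$chaos_level == lv],
                        tr$segment_index[tr$chaos_level == lv])
    expect_false(any(duplicated(keys)))
  }
})

test_that("level 0 is oversampled with repetition after full inclusion", {
  ds <- dplyr::bind_rows(
    tibble::tibble(participant_id = "a", segment_index = 0:29, chaos_level = 0L),
    label_table(600, prevalence = c(0, 1/3, 1/3, 1/3), pid = "b", seed = 55)
  )
  tr <- make_balanced_trainset(ds, 50 / 720, seed = 56)
  l0 <- tr[tr$chaos_level == 0L, ]
  expect_equal(nrow(l0), 50L)
  ## every one of the 30 pool segments appears at least once
  expect_setequal(unique(l0$segment_index), 0:29)
})

test_that("a shortfall in a non-repetition class is an explicit error", {
  ds <- dplyr::bind_rows(
    label_table(200, prevalence = c(0.25, 0.25, 0.5, 0), pid = "a", seed = 57),
    tibble::tibble(participant_id = "b", segment_index = 0:9, chaos_level = 3L)
  )
  expect_error(make_balanced_trainset(ds, 30 / 720, seed = 58),
               "Shortfall for chaos level 3")
})

test_that("the feasible budget helper honours the scarcest class and fold", {
  ds <- dplyr::bind_rows(
    tibble::tibble(participant_id = "a", segment_index = 0:99,
                   chaos_level = rep(0:3, 25)),
    tibble::tibble(participant_id = "b", segment_index = 0:39,
                   chaos_level = rep(0:3, 10))
  )
  ## worst fold removes "a", leaving 10 segments per class from "b"
  expect_equal(max_balanced_budget(ds), 10 / 720)
})

test_that("LOPO folds never leak the test participant into training", {
  ds <- dplyr::bind_rows(lapply(letters[1:4], function(p) {
    label_table(200, pid = p, seed = match(p, letters) + 60)
  }))
  log_env <- new.env()
  log_env$train_participants <- list()
  res <- lopo_cv(ds, majority_factory(log_env), budget_hours_per_class = 20 / 720,
                 seed = 61)
  expect_equal(res$n_folds, 4L)
  expect_length(log_env$train_participants, 4L)
  for (i in seq_along(log_env$train_participants)) {
    expect_false(sort(unique(ds$participant_id))[i] %in%
                   log_env$train_participants[[i]])
  }
  expect_equal(nrow(res$predictions), nrow(ds))
  expect_error(lopo_cv(ds[ds$participant_id == "a", ], majority_factory(),
                       20 / 720), "2 participants")
})

test_that("participant-specific weighted scores match direct recomputation", {
  set.seed(62)
  preds <- dplyr::bind_rows(lapply(letters[1:5], function(p) {
    tibble::tibble(participant_id = p, chaos_level = sample(0:3, 40, TRUE),
                   predicted_level = sample(0:3, 40, TRUE))
  }))
  sc <- participant_weighted_scores(preds)
  expect_equal(nrow(sc), 5L)
  for (p in letters[1:5]) {
    sub <- preds[preds$participant_id == p, ]
    o <- oracle_metrics(sub$chaos_level, sub$predicted_level)
    expect_equal(sc$weighted_f1[sc$participant_id == p], o$weighted_f1,
                 tolerance = 1e-12)
  }
  one <- participant_weighted_scores(preds[preds$participant_id == "a", ])
  ev <- global_metrics(preds$chaos_level[preds$participant_id == "a"],
                       preds$predicted_level[preds$participant_id == "a"])
  expect_equal(one$weighted_f1, ev$weighted$f1) # single participant: global = per-participant
})

test_that("paired model comparison matches the closed-form t statistic", {
  sc <- function(v) tibble::tibble(participant_id = letters[seq_along(v)],
                                   weighted_f1 = v)
  same <- paired_model_test(sc(c(0.5, 0.6, 0.7)), sc(c(0.5, 0.6, 0.7)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_warning(
    deg <- paired_model_test(sc(c(0.5, 0.6, 0.7)), sc(c(0.4, 0.5, 0.6))),
    "Zero-variance")
  expect_true(deg$degenerate)

  set.seed(63)
  a <- runif(8)
  b <- runif(8)
  out <- paired_model_test(sc(a), sc(b))
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(out$t, t_manual, tolerance = 1e-8)
  expect_equal(out$p_value, 2 * pt(-abs(t_manual), 7), tolerance = 1e-8)

  expect_error(paired_model_test(sc(0.5), sc(0.4)), "2 participants")
})

test_that("cry/non-cry splitting partitions the data and drops predicted level 0", {
  ds <- label_table(50, seed = 64)
  events <- tibble::tibble(
    participant_id = "p1",
    segment_index = c(0L, 1L, 2L, 3L),
    class_name = c("Baby cry, infant cry", "Crying, sobbing", "Speech", "Vehicle"),
    confidence = 0.5
  )
  mp <- tibble::tibble(participant_id = "p1", segment_index = 0:49,
                       predicted_level = c(0L, rep(2L, 49)))
  sp <- split_cry_noncry(ds, events, mp)
  ## segments 0 and 1 carry cry-like classes; 0 is dropped (predicted level 0)
  expect_identical(sort(sp$cry$segment_index), 1L)
  expect_equal(sp$n_cry_dropped, 1L)
  expect_equal(nrow(sp$non_cry), 48L)
  expect_equal(nrow(sp$cry) + sp$n_cry_dropped + nrow(sp$non_cry), 50L)

  none <- split_cry_noncry(ds, events[0, ], mp)
  expect_equal(nrow(none$cry), 0L)
  expect_equal(nrow(none$non_cry), 50L)
})

test_that("the ablation harness records every run and is seed-reproducible", {
  ds <- dplyr::bind_rows(lapply(letters[1:3], function(p) {
    label_table(300, pid = p, seed = match(p, letters) + 70)
  }))
  sizes <- c(0.2, 0.1) # total hours across the 4 classes
  a1 <- suppressWarnings(run_ablation(ds, majority_factory(), sizes_hours = sizes,
                                      runs_per_size = 2, seed = 71))
  expect_equal(nrow(a1), 4L)
  expect_setequal(a1$size_hours, sizes)
  a2 <- suppressWarnings(run_ablation(ds, majority_factory(), sizes_hours = sizes,
                                      runs_per_size = 2, seed = 71))
  expect_identical(a1, a2)
  s <- summarise_ablation(a1)
  expect_equal(nrow(s), 2L)

  ## an infeasible size is skipped with a warning, not an error
  expect_warning(
    big <- run_ablation(ds, majority_factory(), sizes_hours = c(40, 0.1),
                        runs_per_size = 1, seed = 72),
    "skipped")
  expect_setequal(big$size_hours, 0.1)
})
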