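# naive loop-based reimplementations of the metric suite, kept deliberately
# independent of the package's vectorized versions
mae_bf <- function(y, yh) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(yh[i] - y[i])
  s / length(y)
}
e_bf <- function(y, yh) mae_bf(y, yh) / abs(sum(y) / length(y))
pcc_bf <- function(y, yh) {
  n <- length(y)
  my <- sum(y) / n; mh <- sum(yh) / n
  cv <- 0; vy <- 0; vh <- 0
  for (i in seq_len(n)) {
    cv <- cv + (y[i] - my) * (yh[i] - mh)
    vy <- vy + (y[i] - my)^2
    vh <- vh + (yh[i] - mh)^2
  }
  (cv / n) / (sqrt(vy / n) * sqrt(vh / n))
}
loa_bf <- function(y, yh) {
  d <- numeric(length(y))
  for (i in seq_along(y)) d[i] <- yh[i] - y[i]
  md <- sum(d) / length(d)
  sdd <- sqrt(sum((d - md)^2) / length(d))
  c(md - 1.96 * sdd, md + 1.96 * sdd)
}

test_that("metric definitions match hand-computed examples", {
  expect_equal(mae(c(10, 12, 14), c(11, 11, 15)), 1.0)
  expect_equal(mae(20, 18), 2.0)
  expect_equal(mae(c(3, 4), c(3, 4)), 0)
  y <- 15 + c(-1.5, 1.5, -1.5, 1.5)
  expect_equal(percentage_error(y, y + 1.5), 0.1)
  expect_equal(percentage_error(y, y + 1.5, as_percent = TRUE), 10)
  expect_equal(percentage_error(2 * y, 2 * (y + 1.5)), 0.1)   # scale invariance
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 4)), sqrt(27 / 28), tolerance = 1e-12)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pcc(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(loa(c(1, 2), c(1.5, 2.5)), c(low = 0.5, high = 0.5))
  expect_equal(loa(c(0, 0), c(-1, 1)), c(low = -1.96, high = 1.96))
  expect_equal(loa(c(5, 9), c(5, 9)), c(low = 0, high = 0))
})

test_that("metrics agree with brute-force implementations on random vectors", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(2:200, 1)
    y <- runif(n, 5, 30)
    yh <- y + rnorm(n)
    expect_equal(mae(y, yh), mae_bf(y, yh), tolerance = 1e-12)
    expect_equal(percentage_error(y, yh), e_bf(y, yh), tolerance = 1e-12)
    expect_equal(pcc(y, yh), pcc_bf(y, yh), tolerance = 1e-12)
    expect_equal(unname(loa(y, yh)), loa_bf(y, yh), tolerance = 1e-12)
  }
})

test_that("metric edge cases surface as typed errors", {
  expect_error(mae(1:3, 1:2), class = "transrr_contract_error")
  expect_error(percentage_error(c(-1, 1), c(0, 0)), class = "transrr_metric_error")
  expect_error(pcc(c(2, 2, 2), c(1, 2, 3)), class = "transrr_metric_error")
})

test_that("evaluate reports the four metrics and rejects degenerate predictors", {
  set.seed(5)
  segs <- toy_segment_set(n = 12)
  m <- build_model(tiny_model_config())
  rep <- evaluate(m, segs)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n, 12)
  expect_gte(rep$mae, 0)
  expect_lte(rep$loa_low, rep$loa_high)
  expect_lte(abs(rep$pcc), 1)
  # an oracle predictor: report against itself via a zero-error mock
  perfect <- segs
  expect_equal(mae(perfect$rr_label, perfect$rr_label), 0)
})

test_that("subject-level folds are disjoint, exhaustive, and balanced", {
  ids <- sprintf("s%02d", 1:95)
  folds <- subject_kfold(ids, 10, seed = 3)
  expect_length(folds, 10)
  expect_equal(sort(vapply(folds, length, 0L)), rep(c(9L, 10L), each = 5))
  expect_identical(sort(unlist(folds)), sort(ids))
  expect_equal(sum(duplicated(unlist(folds))), 0)
  expect_identical(subject_kfold(ids, 10, seed = 3), folds)
  expect_false(identical(subject_kfold(ids, 10, seed = 4), folds))
  expect_identical(unname(unlist(subject_kfold(ids, 1, seed = 1))) |> sort(),
                   sort(ids))
  expect_error(subject_kfold(ids[1:5], 10), class = "transrr_parameter_error")
})

test_that("subject leakage between training and validation is a hard error", {
  segs <- toy_segment_set(n = 18, subjects = c("a", "b", "c"))
  tr <- subset_segments(segs, segs$subject_id %in% c("a", "b"))
  va_leak <- subset_segments(segs, segs$subject_id %in% c("b", "c"))
  expect_error(train_model(tr, va_leak, tiny_model_config(),
                           train_config(epochs = 1, batch_size = 8, seed = 1)),
               class = "transrr_leakage_error")
})

test_that("training is seed-reproducible with a compliant learning-rate schedule", {
  segs <- toy_segment_set(n = 30, subjects = c("a", "b", "c"))
  tr <- subset_segments(segs, segs$subject_id %in% c("a", "b"))
  va <- subset_segments(segs, segs$subject_id == "c")
  tcfg <- train_config(epochs = 12, batch_size = 8, lr_patience = 2,
                       early_stop_patience = 12, seed = 5)
  f1 <- train_model(tr, va, tiny_model_config(), tcfg)
  f2 <- train_model(tr, va, tiny_model_config(), tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(all(diff(f1$history$lr) <= 0))
  expect_true(all(f1$history$lr >= tcfg$lr_floor))
  expect_true(all(is.finite(f1$history$train_loss)))
  expect_identical(f1$model$data_fingerprint, "toy")
  # best-epoch restoration: the returned model scores the best seen val loss
  best <- attr(f1$history, "best_epoch")
  expect_equal(f1$history$val_loss[best], min(f1$history$val_loss))
  expect_equal(mae(va$rr_label, forward(f1$model, va)),
               min(f1$history$val_loss), tolerance = 1e-9)
})

test_that("early stopping halts after the patience window without improvement", {
  segs <- toy_segment_set(n = 30, subjects = c("a", "b", "c"), seed = 7)
  tr <- subset_segments(segs, segs$subject_id %in% c("a", "b"))
  va <- subset_segments(segs, segs$subject_id == "c")
  tcfg <- train_config(epochs = 60, batch_size = 8, lr_init = 0,
                       lr_floor = 0, early_stop_patience = 4, seed = 2)
  # a zero learning rate freezes the parameters, so the validation loss can
  # never strictly improve after the first epoch: training must stop after
  # exactly the patience window
  fit <- train_model(tr, va, tiny_model_config(), tcfg)
  expect_equal(nrow(fit$history), 1 + 4)
})

test_that("the cross-dataset protocol is expressible as tagged-subset train/test", {
  segs <- bind_segment_sets(
    toy_segment_set(n = 16, subjects = c("bidmc_a", "bidmc_b"), seed = 1),
    toy_segment_set(n = 16, subjects = c("capno_a", "capno_b"), seed = 2))
  is_bidmc <- startsWith(segs$subject_id, "bidmc")
  tr <- subset_segments(segs, is_bidmc & segs$subject_id != "bidmc_b")
  va <- subset_segments(segs, segs$subject_id == "bidmc_b")
  te <- subset_segments(segs, !is_bidmc)
  fit <- train_model(tr, va, tiny_model_config(),
                     train_config(epochs = 2, batch_size = 8, seed = 1))
  rep <- evaluate(fit$model, te)
  expect_equal(rep$n, 16)
  expect_true(is.finite(rep$mae))
})

test_that("cross-validation keeps subjects on one side of every fold", {
  segs <- toy_segment_set(n = 60, subjects = sprintf("s%d", 1:6), seed = 4)
  cv <- crossvalidate(segs, tiny_model_config(),
                      train_config(epochs = 2, batch_size = 16, k_folds = 3,
                                   seed = 9))
  expect_length(cv$folds, 3)
  expect_identical(sort(unlist(cv$fold_subjects)), sort(sprintf("s%d", 1:6)))
  for (f in cv$folds) expect_true(is.finite(f$mae))
  # the mean report averages the per-fold metrics
  expect_equal(cv$mean$mae, mean(vapply(cv$folds, `[[`, 0, "mae")))
  expect_equal(cv$mean$pcc, mean(vapply(cv$folds, `[[`, 0, "pcc")))
  expect_equal(cv$mean$n, sum(vapply(cv$folds, `[[`, 0, "n")))
})
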