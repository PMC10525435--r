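#' Training protocol configuration
#'
#' Defaults follow the reference protocol: up to 100 epochs at batch size
#' 128, MAE loss minimized by Adam with the learning rate starting at 1e-3
#' and multiplied by 0.9 whenever the validation loss fails to improve for 5
#' consecutive epochs (floored at 1e-4), early stopping after 20 epochs
#' without validation improvement, and parameters restored from the best
#' validation epoch. Splits are subject-level: 20% of training subjects form
#' the validation set and k = 10 folds are used for cross-validation.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr_init,lr_floor Initial and minimum learning rates.
#' @param lr_factor Multiplicative decrease on plateau.
#' @param lr_patience Epochs without validation improvement before a decrease.
#' @param early_stop_patience Epochs without validation improvement before
#'   training stops.
#' @param val_fraction_subjects Fraction of training subjects held out for
#'   validation (subject-level).
#' @param k_folds Cross-validation fold count.
#' @param seed Master seed deriving the split, initialization and batch-order
#'   streams.
#' @return An object of class `train_config`. The loss (mean absolute error)
#'   and optimizer (Adam) are fixed by the protocol.
#' @export
train_config <- function(epochs = 100, batch_size = 128, lr_init = 1e-3,
                         lr_floor = 1e-4, lr_factor = 0.9, lr_patience = 5,
                         early_stop_patience = 20,
                         val_fraction_subjects = 0.20, k_folds = 10,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "train_config")
  if (cfg$lr_floor > cfg$lr_init)
    transrr_error("transrr_parameter_error", "lr_floor must be <= lr_init")
  if (cfg$val_fraction_subjects <= 0 || cfg$val_fraction_subjects >= 1)
    transrr_error("transrr_parameter_error", "val_fraction_subjects must be in (0, 1)")
  cfg$loss <- "mae"
  cfg$optimizer <- "adam"
  cfg
}

check_lengths <- function(y, yhat) {
  if (length(y) != length(yhat))
    transrr_error("transrr_contract_error",
                  "reference and prediction lengths differ (%d vs %d)",
                  length(y), length(yhat))
  if (length(y) < 1)
    transrr_error("transrr_contract_error", "empty metric input")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Mean absolute error
#' @param y Reference RR vector (breaths/min).
#' @param yhat Predicted RR vector.
#' @return MAE in breaths/min.
#' @export
mae <- function(y, yhat) {
  check_lengths(y, yhat)
  mean(abs(yhat - y))
}

#' Percentage error E
#'
#' MAE relative to the magnitude of the mean reference RR. Reported as a
#' fraction by default (an MAE of 1.2 at a mean RR of ~17 gives E = 0.07);
#' set `as_percent = TRUE` for the x100 display scale.
#'
#' @inheritParams mae
#' @param as_percent Multiply by 100.
#' @return Dimensionless fraction (or percent).
#' @export
percentage_error <- function(y, yhat, as_percent = FALSE) {
  check_lengths(y, yhat)
  if (mean(y) == 0)
    transrr_error("transrr_metric_error", "E undefined: reference mean is zero")
  e <- mae(y, yhat) / abs(mean(y))
  if (as_percent) 100 * e else e
}

#' Pearson correlation coefficient
#'
#' Covariance over the product of standard deviations, with the population
#' convention used consistently in numerator and denominator (the
#' normalization cancels, so this equals the sample-convention value).
#'
#' @inheritParams mae
#' @return PCC in [-1, 1].
#' @export
pcc <- function(y, yhat) {
  check_lengths(y, yhat)
  if (length(y) < 2)
    transrr_error("transrr_metric_error", "PCC needs at least 2 pairs")
  if (pop_sd(y) == 0 || pop_sd(yhat) == 0)
    transrr_error("transrr_metric_error", "PCC undefined for a constant vector")
  mean((y - mean(y)) * (yhat - mean(yhat))) / (pop_sd(y) * pop_sd(yhat))
}

#' 95% Bland-Altman limits of agreement
#'
#' On the differences d = yhat - y, returns
#' (mean(d) - 1.96 sd(d), mean(d) + 1.96 sd(d)) with the population standard
#' deviation.
#'
#' @inheritParams mae
#' @return Named numeric vector `c(low, high)` in breaths/min.
#' @export
loa <- function(y, yhat) {
  check_lengths(y, yhat)
  if (length(y) < 2)
    transrr_error("transrr_metric_error", "LOA needs at least 2 pairs")
  d <- yhat - y
  c(low = mean(d) - 1.96 * pop_sd(d), high = mean(d) + 1.96 * pop_sd(d))
}

#' Evaluate a model on a segment set
#'
#' Runs the forward pass in evaluation mode and computes the four-metric
#' suite on (labels, predictions).
#'
#' @param model A [transrr_model][build_model()].
#' @param segments A [segment_set()] with at least 2 segments.
#' @return An `eval_report`: list with `mae`, `e`, `pcc`, `loa_low`,
#'   `loa_high`, and `n`.
#' @export
evaluate <- function(model, segments) {
  if (n_segments(segments) < 2)
    transrr_error("transrr_contract_error", "evaluation needs at least 2 segments")
  yhat <- forward(model, segments)
  y <- segments$rr_label
  lims <- loa(y, yhat)
  structure(list(mae = mae(y, yhat), e = percentage_error(y, yhat),
                 pcc = pcc(y, yhat), loa_low = unname(lims["low"]),
                 loa_high = unname(lims["high"]), n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n  MAE %.3f b/m | E %.3f | PCC %.3f | LOA [%.2f, %.2f]\n",
              x$n, x$mae, x$e, x$pcc, x$loa_low, x$loa_high))
  invisible(x)
}

#' Subject-level k-fold partition
#'
#' Deterministically shuffles the distinct subject ids by `seed` and deals
#' them into k folds whose sizes differ by at most 1. Folds are pairwise
#' disjoint and cover all subjects.
#'
#' @param subject_ids Character vector (duplicates collapse to distinct ids).
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of k character vectors of subject ids.
#' @export
subject_kfold <- function(subject_ids, k, seed = 1L) {
  ids <- unique(as.character(subject_ids))
  if (k > length(ids))
    transrr_error("transrr_parameter_error",
                  "k = %d exceeds the %d distinct subjects", k, length(ids))
  shuffled <- with_local_seed(seed, sample(ids))
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  unname(split(shuffled, rep(seq_len(k), times = sizes)))
}

subsample_by_subject <- function(set, stride) {
  keep <- unlist(lapply(split(seq_along(set$subject_id), set$subject_id),
                        function(ix) ix[seq(1, length(ix), by = stride)]))
  subset_segments(set, sort(unname(keep)))
}

assert_no_leakage <- function(train_ids, other_ids, what) {
  shared <- intersect(unique(train_ids), unique(other_ids))
  if (length(shared))
    transrr_error("transrr_leakage_error",
                  "subject(s) %s appear in both training and %s sets",
                  paste(shared, collapse = ", "), what)
}

#' Train a TransRR model
#'
#' Minimizes MAE by Adam under the plateau learning-rate schedule and
#' validation-based early stopping of [train_config()]; the returned model
#' carries the parameters of the best validation epoch. Training and
#' validation sets must not share subjects (a violation is a hard error,
#' never a warning).
#'
#' @param train_set,val_set [segment_set()]s with disjoint subjects.
#' @param model_cfg A [model_config()]; its `seed` is derived from
#'   `train_cfg$seed` so one master seed reproduces the whole run.
#' @param train_cfg A [train_config()].
#' @return List with `model` (trained [transrr_model][build_model()]) and
#'   `history` (data frame of per-epoch train/validation loss and learning
#'   rate, plus the best epoch as an attribute).
#' @export
train_model <- function(train_set, val_set, model_cfg = model_config(),
                        train_cfg = train_config()) {
  assert_no_leakage(train_set$subject_id, val_set$subject_id, "validation")
  if (n_segments(train_set) < 1 || n_segments(val_set) < 1)
    transrr_error("transrr_contract_error", "empty training or validation set")
  model_cfg$seed <- as.integer((train_cfg$seed * 48271 + 11) %% 2147483647)
  model <- build_model(model_cfg)
  Xtr <- model_input_matrix(train_set, model_cfg)
  Xval <- model_input_matrix(val_set, model_cfg)
  fit <- cpp_train(model_cfg, model$params, Xtr, train_set$rr_label, Xval,
                   val_set$rr_label,
                   list(epochs = as.integer(train_cfg$epochs),
                        batch_size = as.integer(train_cfg$batch_size),
                        lr_init = train_cfg$lr_init,
                        lr_floor = train_cfg$lr_floor,
                        lr_factor = train_cfg$lr_factor,
                        lr_patience = as.integer(train_cfg$lr_patience),
                        early_stop_patience = as.integer(train_cfg$early_stop_patience),
                        seed = as.integer(train_cfg$seed)))
  model$params <- as.numeric(fit$params)
  model$trained <- TRUE
  model$data_fingerprint <- train_set$params_fingerprint
  history <- data.frame(epoch = seq_along(fit$train_loss),
                        train_loss = as.numeric(fit$train_loss),
                        val_loss = as.numeric(fit$val_loss),
                        lr = as.numeric(fit$lr))
  attr(history, "best_epoch") <- fit$best_epoch
  list(model = model, history = history)
}

#' Subject-level k-fold cross-validation
#'
#' For each fold: that fold's subjects form the test set; of the remaining
#' subjects, `val_fraction_subjects` (subject-level, seeded) form the
#' validation set and the rest the training set. A model is trained per fold
#' and evaluated on its test segments. The mean report averages each metric
#' across folds (unweighted). Each fold's report also carries
#' `baseline_mae`, the MAE of the constant predict-the-training-mean
#' predictor on that fold's test set.
#'
#' @param segments A pooled [segment_set()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()]; supplies `k_folds` and all seeds.
#' @param train_subsample Keep every `train_subsample`-th training window
#'   per subject (default 1 = all). With 87.5% window overlap adjacent
#'   windows are near-duplicates, so a stride of 2 halves the training cost
#'   at little information loss; validation and test sets always use every
#'   window.
#' @return List with `folds` (list of per-fold `eval_report`s, each with a
#'   `baseline_mae` field), `mean` (metric-wise mean report), and
#'   `fold_subjects`.
#' @export
crossvalidate <- function(segments, model_cfg = model_config(),
                          train_cfg = train_config(), train_subsample = 1L) {
  k <- train_cfg$k_folds
  folds <- subject_kfold(segments$subject_id, k, seed = train_cfg$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    rest <- setdiff(unique(segments$subject_id), test_ids)
    n_val <- max(1L, round(train_cfg$val_fraction_subjects * length(rest)))
    val_ids <- with_local_seed(train_cfg$seed + f,
                               sample(rest, n_val))
    train_ids <- setdiff(rest, val_ids)
    assert_no_leakage(train_ids, test_ids, "test")
    tr <- subset_segments(segments, segments$subject_id %in% train_ids)
    if (train_subsample > 1) tr <- subsample_by_subject(tr, train_subsample)
    va <- subset_segments(segments, segments$subject_id %in% val_ids)
    te <- subset_segments(segments, segments$subject_id %in% test_ids)
    fold_cfg <- train_cfg
    fold_cfg$seed <- as.integer(train_cfg$seed + 1000 * f)
    fit <- train_model(tr, va, model_cfg, fold_cfg)
    rep <- evaluate(fit$model, te)
    rep$baseline_mae <- mae(te$rr_label, rep(mean(tr$rr_label), n_segments(te)))
    rep$subjects <- test_ids
    reports[[f]] <- rep
  }
  metrics <- c("mae", "e", "pcc", "loa_low", "loa_high", "baseline_mae")
  mean_rep <- lapply(stats::setNames(metrics, metrics), function(m)
    mean(vapply(reports, function(r) r[[m]], numeric(1))))
  mean_rep$n <- sum(vapply(reports, function(r) r$n, numeric(1)))
  class(mean_rep) <- "eval_report"
  list(folds = reports, mean = mean_rep, fold_subjects = folds)
}
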