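# Shared fixtures. Heavy artifacts (preprocessed cohorts, cross-validation
# runs) are computed once per session and memoized here so several test
# files can assert against the same experiment.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# small model configuration used wherever the architecture itself is not
# under test (fast to build and train)
tiny_model_config <- function(input_len = 16, n_blocks = 1, ...) {
  model_config(input_len = input_len, n_blocks = n_blocks, n_heads = 2, head_size = 4,
               kernel_sizes = c(3, 5), dilation_rates = c(1, 2),
               dilation_kernel = 3, branch_channels = 2, fc_sizes = c(8, 1),
               seed = 1, ...)
}

# a synthetic segment set with labels linearly decodable from the windows,
# for exercising training plumbing quickly
toy_segment_set <- function(n = 24, len = 16, subjects = c("a", "b", "c"),
                            seed = 1) {
  withr::with_seed(seed, {
    y <- runif(n, 8, 28)
    phase <- runif(n, 0, 2 * pi)
    tt <- seq_len(len) / len
    ecg <- t(vapply(seq_len(n), function(i)
      sin(2 * pi * y[i] / 10 * tt + phase[i]), numeric(len)))
    segment_set(ecg, ecg + 0.01, y, rep_len(subjects, n), "toy")
  })
}

# desk-scale stand-in cohort for the recovery experiment: the generator
# defaults (modulation depths, noise, drift, HR/RR ranges) are the study
# conditions; only cohort size and duration are reduced to desk scale, and
# training uses every second (stride-2) window per subject since the 87.5%
# overlap makes neighbours near-duplicates (see the methods vignette).
recovery_cohort_config <- function() {
  synthetic_config(n_subjects = 16, duration_s = 120, seed = 7)
}

recovery_segments <- function() {
  memo("recovery_segments", {
    preprocess_dataset(generate_cohort(recovery_cohort_config()),
                       preprocess_params())
  })
}

recovery_model_config <- function(...) {
  model_config(n_blocks = 2, seed = 1, ...)
}

recovery_train_config <- function() {
  train_config(epochs = 30, batch_size = 32, k_folds = 5, seed = 7)
}

# full-model subject-level 5-fold cross-validation on the recovery cohort
recovery_cv <- function() {
  memo("recovery_cv", {
    crossvalidate(recovery_segments(), recovery_model_config(),
                  recovery_train_config(), train_subsample = 2L)
  })
}

# one-fold (first fold of the same partition) run of an arbitrary variant,
# for the ablation direction checks
recovery_single_fold <- function(model_cfg = recovery_model_config(),
                                 segments = recovery_segments()) {
  tcfg <- recovery_train_config()
  folds <- subject_kfold(segments$subject_id, tcfg$k_folds, seed = tcfg$seed)
  test_ids <- folds[[1]]
  rest <- setdiff(unique(segments$subject_id), test_ids)
  n_val <- max(1L, round(tcfg$val_fraction_subjects * length(rest)))
  val_ids <- transrr:::with_local_seed(tcfg$seed + 1, sample(rest, n_val))
  train_ids <- setdiff(rest, val_ids)
  tr <- transrr:::subsample_by_subject(
    subset_segments(segments, segments$subject_id %in% train_ids), 2L)
  va <- subset_segments(segments, segments$subject_id %in% val_ids)
  te <- subset_segments(segments, segments$subject_id %in% test_ids)
  fold_cfg <- tcfg
  fold_cfg$seed <- as.integer(tcfg$seed + 1000)
  fit <- train_model(tr, va, model_cfg, fold_cfg)
  evaluate(fit$model, te)
}
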