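#' Preprocessing parameters
#'
#' All tunable parameters of the signal-conditioning pipeline, with the
#' defaults used throughout: signals resampled to 125 Hz and reference RR to
#' 1 Hz; a 4th-order zero-phase Butterworth band-pass over 0.1-0.6 Hz (the
#' physiologically viable RR band of 6-36 breaths/min); VMD denoising with
#' K = 5 modes of which the highest-frequency mode (carrying most motion
#' artifact) is discarded; per-subject z-scoring; 16 s windows with 87.5%
#' overlap (2 s stride); segments with labels outside the open interval
#' (5, 30) breaths/min removed; windows decimated by one-eighth to length
#' 250 model inputs.
#'
#' @param fs_target Signal sampling rate after resampling (Hz).
#' @param fs_rr_target Reference-RR sampling rate after resampling (Hz).
#' @param band Respiratory band-pass edges in Hz.
#' @param filter_order Butterworth prototype order.
#' @param vmd_modes Number of VMD modes K.
#' @param vmd_alpha VMD bandwidth penalty.
#' @param vmd_tau VMD dual ascent step.
#' @param vmd_tol VMD convergence tolerance.
#' @param vmd_max_iter VMD iteration cap.
#' @param window_s Window length in seconds.
#' @param overlap Fractional window overlap in [0, 1).
#' @param rr_lo,rr_hi Open label-validity interval in breaths/min.
#' @param downsample_factor Plain-stride decimation factor applied to the
#'   already band-limited windows.
#' @param max_age_excluded Subjects aged `<=` this (years) are excluded.
#' @param max_missing_rr_fraction Subjects whose missing-RR fraction exceeds
#'   this are excluded.
#' @param zscore Logical; set `FALSE` to ablate per-subject normalization.
#' @param label_agg Window-label aggregator over the covered RR samples:
#'   `"mean"` (default) or `"median"`.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(fs_target = 125, fs_rr_target = 1,
                              band = c(0.1, 0.6), filter_order = 4,
                              vmd_modes = 5, vmd_alpha = 2000, vmd_tau = 0,
                              vmd_tol = 1e-7, vmd_max_iter = 500,
                              window_s = 16, overlap = 0.875,
                              rr_lo = 5, rr_hi = 30, downsample_factor = 8,
                              max_age_excluded = 5,
                              max_missing_rr_fraction = 0.75,
                              zscore = TRUE, label_agg = c("mean", "median")) {
  label_agg <- match.arg(label_agg)
  p <- structure(as.list(environment()), class = "preprocess_params")
  if (!(p$band[1] > 0 && p$band[1] < p$band[2] && p$band[2] < p$fs_target / 2))
    transrr_error("transrr_parameter_error",
                  "band must satisfy 0 < lo < hi < fs_target/2")
  if (p$overlap < 0 || p$overlap >= 1)
    transrr_error("transrr_parameter_error", "overlap must be in [0, 1)")
  if ((p$window_s * p$fs_target) %% p$downsample_factor != 0)
    transrr_error("transrr_parameter_error",
                  "downsample_factor must divide window_s * fs_target")
  p
}

params_fingerprint <- function(p) {
  flat <- vapply(p, function(v) paste(format(v, digits = 15), collapse = "/"), "")
  paste(names(flat), flat, sep = "=", collapse = ";")
}

#' Exclude subjects by age and missing reference RR
#'
#' Removes subjects aged `max_age_excluded` or younger and subjects whose
#' fraction of missing reference-RR samples exceeds
#' `max_missing_rr_fraction` (both boundary-inclusive kept semantics: a
#' missing fraction exactly at the threshold is kept). Order is preserved.
#'
#' @param records List of [subject_record()]s.
#' @param params A [preprocess_params()].
#' @return Filtered list of records.
#' @export
exclude_subjects <- function(records, params = preprocess_params()) {
  keep <- vapply(records, function(r) {
    if (!is.na(r$age) && r$age <= params$max_age_excluded) return(FALSE)
    miss <- if (is.null(r$rr_missing_mask)) 0 else mean(r$rr_missing_mask)
    miss <= params$max_missing_rr_fraction
  }, logical(1))
  records[keep]
}

#' Resample a signal to a new rate
#'
#' Anti-aliased polyphase rational resampling: the rate ratio is reduced to a
#' rational p/q and the signal interpolated/decimated through
#' `signal::resample`. Output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric signal.
#' @param fs_in,fs_out Input/output sampling rates (Hz).
#' @return Resampled numeric vector.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0)
    transrr_error("transrr_parameter_error", "sampling rates must be positive")
  if (any(!is.finite(x)))
    transrr_error("transrr_data_error", "signal contains non-finite samples")
  if (fs_in == fs_out) return(x)
  frac <- rational_approx(fs_out / fs_in)
  y <- signal::resample(x, frac[1], frac[2])
  n_out <- round(length(x) * fs_out / fs_in)
  length(y) <- n_out          # pads with NA if short
  if (anyNA(y)) y[is.na(y)] <- y[max(which(!is.na(y)))]
  y
}

rational_approx <- function(r, max_den = 10000) {
  # continued-fraction expansion
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    fr <- x - a
    if (fr < 1e-12) break
    x <- 1 / fr
  }
  c(p1, q1)
}

#' Extract the respiratory band from a cardiac signal
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order
#' `filter_order` over `band`, realised as cascaded second-order sections
#' for numerical stability at the very low normalized cutoffs involved.
#' Output has the input's length; constant (DC) input maps to zero.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()].
#' @return Filtered numeric vector.
#' @export
bandpass_respiratory <- function(x, fs, params = preprocess_params()) {
  if (length(x) < 10 * fs / params$band[1])
    warning(sprintf("signal of %d samples is short for stable %g Hz high-pass edge",
                    length(x), params$band[1]), call. = FALSE)
  sos <- butter_bandpass_sos(params$filter_order, params$band[1],
                             params$band[2], fs)
  sosfiltfilt(sos, x, params$band[1], fs)
}

#' Denoise a respiratory surrogate by variational mode decomposition
#'
#' Decomposes the signal into `vmd_modes` modes and returns the sum of all
#' but the highest-center-frequency mode, which carries most of the
#' residual motion artifact.
#'
#' @param x Numeric signal.
#' @param params A [preprocess_params()].
#' @return Denoised numeric vector of the same length.
#' @export
vmd_denoise <- function(x, params = preprocess_params()) {
  dec <- vmd_decompose(x, K = params$vmd_modes, alpha = params$vmd_alpha,
                       tau = params$vmd_tau, tol = params$vmd_tol,
                       max_iter = params$vmd_max_iter)
  rowSums(dec$modes[, -ncol(dec$modes), drop = FALSE])
}

#' Z-score a signal (population convention)
#'
#' Centers to mean 0 and scales to unit population standard deviation.
#' Applied per subject and per channel to remove inter-subject amplitude
#' variance.
#'
#' @param x Numeric vector (length >= 2, non-constant).
#' @param subject_id Optional id used in the degenerate-signal error message.
#' @return Standardized numeric vector.
#' @export
zscore <- function(x, subject_id = NULL) {
  if (length(x) < 2)
    transrr_error("transrr_data_error", "cannot z-score fewer than 2 samples")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0)
    transrr_error("transrr_degenerate_signal_error",
                  "constant signal cannot be z-scored%s",
                  if (is.null(subject_id)) "" else paste0(" (subject ", subject_id, ")"))
  (x - m) / s
}

#' Cut a preprocessed recording into model-ready segments
#'
#' Windows of `window_s` seconds advance by `window_s * (1 - overlap)`
#' seconds (2 s at defaults). Each window's label is the `label_agg` of the
#' reference-RR samples whose timestamps fall in `[start, start + window_s)`;
#' windows covering any missing RR sample are dropped. ECG/PPG windows are
#' decimated by plain stride `downsample_factor` (the signal is already
#' band-limited far below the post-decimation Nyquist), yielding length
#' `window_s * fs_target / downsample_factor` (250 at defaults).
#'
#' @param record A preprocessed [subject_record()] at `fs_target`/`fs_rr_target`.
#' @param params A [preprocess_params()].
#' @return A [segment_set()] (empty if the recording is shorter than one window).
#' @export
segment_subject <- function(record, params = preprocess_params()) {
  fs <- record$fs_signal
  wlen <- round(params$window_s * fs)
  out_len <- wlen %/% params$downsample_factor
  n <- length(record$ecg)
  duration <- n / fs
  stride_s <- params$window_s * (1 - params$overlap)
  empty <- segment_set(matrix(numeric(), 0, out_len), matrix(numeric(), 0, out_len),
                       numeric(), character(), params_fingerprint(params))
  if (duration < params$window_s) return(empty)
  n_win <- floor((duration - params$window_s) / stride_s) + 1
  starts_s <- (seq_len(n_win) - 1) * stride_s
  agg <- if (params$label_agg == "mean") mean else stats::median
  t_rr <- (seq_along(record$rr_ref) - 1) / record$fs_rr
  keep <- logical(n_win)
  labels <- numeric(n_win)
  pick <- seq(1, wlen, by = params$downsample_factor)
  ecg_w <- matrix(0, n_win, out_len)
  ppg_w <- matrix(0, n_win, out_len)
  for (i in seq_len(n_win)) {
    s0 <- starts_s[i]
    in_win <- t_rr >= s0 & t_rr < s0 + params$window_s
    if (!any(in_win)) next
    if (!is.null(record$rr_missing_mask) && any(record$rr_missing_mask[in_win]))
      next
    rr_vals <- record$rr_ref[in_win]
    if (anyNA(rr_vals)) next
    i0 <- round(s0 * fs)
    ecg_w[i, ] <- record$ecg[i0 + pick]
    ppg_w[i, ] <- record$ppg[i0 + pick]
    labels[i] <- agg(rr_vals)
    keep[i] <- TRUE
  }
  segment_set(ecg_w[keep, , drop = FALSE], ppg_w[keep, , drop = FALSE],
              labels[keep], rep(record$subject_id, sum(keep)),
              params_fingerprint(params))
}

#' Drop segments with out-of-range RR labels
#'
#' Keeps exactly the segments whose label lies strictly inside
#' `(rr_lo, rr_hi)`; labels at or beyond either bound are removed.
#'
#' @param set A [segment_set()].
#' @param params A [preprocess_params()].
#' @return Filtered [segment_set()].
#' @export
filter_rr_range <- function(set, params = preprocess_params()) {
  if (any(!is.finite(set$rr_label)))
    transrr_error("transrr_data_error", "non-finite RR labels")
  subset_segments(set, set$rr_label > params$rr_lo & set$rr_label < params$rr_hi)
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Applies, in order: subject exclusion, resampling (signals to `fs_target`,
#' RR to `fs_rr_target`), respiratory band-pass, VMD denoising, per-subject
#' z-scoring (each channel independently; skipped when `zscore = FALSE`),
#' windowing, and RR-range filtering, then pools all subjects' segments.
#' The pipeline is fully deterministic.
#'
#' @param records List of raw [subject_record()]s.
#' @param params A [preprocess_params()].
#' @return A pooled [segment_set()] carrying the parameter fingerprint.
#' @export
preprocess_dataset <- function(records, params = preprocess_params()) {
  records <- exclude_subjects(records, params)
  sets <- lapply(records, function(rec) {
    res <- tryCatch(preprocess_subject(rec, params), error = function(e) {
      transrr_error("transrr_pipeline_error", "subject %s: %s", rec$subject_id,
                    conditionMessage(e))
    })
    res
  })
  if (!length(sets))
    return(segment_set(matrix(numeric(), 0, 0), matrix(numeric(), 0, 0),
                       numeric(), character(), params_fingerprint(params)))
  bind_segment_sets(sets, params_fingerprint = params_fingerprint(params))
}

preprocess_subject <- function(rec, params) {
  fs <- rec$fs_signal
  ecg <- rec$ecg; ppg <- rec$ppg
  if (fs != params$fs_target) {
    ecg <- resample_signal(ecg, fs, params$fs_target)
    ppg <- resample_signal(ppg, fs, params$fs_target)
  }
  rr <- rec$rr_ref; mask <- rec$rr_missing_mask
  if (rec$fs_rr != params$fs_rr_target) {
    t_in <- (seq_along(rr) - 1) / rec$fs_rr
    n_out <- round(length(rr) / rec$fs_rr * params$fs_rr_target)
    t_out <- (seq_len(n_out) - 1) / params$fs_rr_target
    ok <- if (is.null(mask)) !is.na(rr) else !(mask | is.na(rr))
    rr_out <- rep(NA_real_, n_out)
    if (sum(ok) >= 2)
      rr_out <- stats::approx(t_in[ok], rr[ok], xout = t_out, rule = 2)$y
    # a grid point is missing if its nearest input sample was missing
    near <- pmin(pmax(round(t_out * rec$fs_rr) + 1, 1), length(rr))
    mask_out <- if (is.null(mask)) is.na(rr)[near] else (mask | is.na(rr))[near]
    rr <- rr_out; mask <- if (any(mask_out)) mask_out else NULL
  }
  clean <- function(x) {
    x <- bandpass_respiratory(x, params$fs_target, params)
    x <- vmd_denoise(x, params)
    if (params$zscore) x <- zscore(x, rec$subject_id)
    x
  }
  rec2 <- subject_record(rec$subject_id, rec$dataset, rec$age,
                         clean(ecg), clean(ppg), params$fs_target,
                         rr, params$fs_rr_target,
                         rr_missing_mask = mask)
  filter_rr_range(segment_subject(rec2, params), params)
}
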