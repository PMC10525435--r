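#' Construct a subject recording
#'
#' Bundles one subject's simultaneous ECG and PPG traces with the reference
#' respiratory-rate (RR) trace and metadata. This is the unit every pipeline
#' stage operates on: raw recordings from BIDMC/CapnoBase-style sources (after
#' conversion to the package CSV dialect) or synthetic subjects from
#' [generate_subject()].
#'
#' @param subject_id Character scalar identifier.
#' @param dataset Dataset tag, e.g. `"bidmc"`, `"capnobase"` or `"synthetic"`.
#' @param age Age in years (>= 0).
#' @param ecg,ppg Numeric vectors of equal length (arbitrary units).
#' @param fs_signal Sampling rate of `ecg`/`ppg` in Hz.
#' @param rr_ref Reference RR trace in breaths/min.
#' @param fs_rr Sampling rate of `rr_ref` in Hz (typically 1).
#' @param breath_onsets Optional strictly increasing vector of sample indices
#'   (on the `fs_signal` grid) marking breath onsets.
#' @param rr_missing_mask Optional logical vector aligned to `rr_ref`; `TRUE`
#'   marks a missing reference sample.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, dataset, age, ecg, ppg, fs_signal,
                           rr_ref, fs_rr, breath_onsets = NULL,
                           rr_missing_mask = NULL) {
  rec <- structure(
    list(subject_id = as.character(subject_id), dataset = as.character(dataset),
         age = as.numeric(age), ecg = as.numeric(ecg), ppg = as.numeric(ppg),
         fs_signal = as.numeric(fs_signal), rr_ref = as.numeric(rr_ref),
         fs_rr = as.numeric(fs_rr),
         breath_onsets = if (length(breath_onsets)) as.numeric(breath_onsets),
         rr_missing_mask = if (length(rr_missing_mask)) as.logical(rr_missing_mask)),
    class = "subject_record")
  validate_subject_record(rec)
  rec
}

validate_subject_record <- function(rec) {
  if (length(rec$ecg) != length(rec$ppg))
    transrr_error("transrr_format_error", "ecg and ppg lengths differ (%d vs %d)",
                  length(rec$ecg), length(rec$ppg))
  if (rec$fs_signal <= 0 || rec$fs_rr <= 0)
    transrr_error("transrr_format_error", "sampling rates must be positive")
  if (!is.na(rec$age) && rec$age < 0)
    transrr_error("transrr_format_error", "age must be >= 0")
  dur <- length(rec$ecg) / rec$fs_signal
  if (abs(length(rec$rr_ref) - dur * rec$fs_rr) > 1 + 1e-8)
    transrr_error("transrr_format_error",
                  "rr_ref length %d inconsistent with duration %.1f s at %g Hz",
                  length(rec$rr_ref), dur, rec$fs_rr)
  if (!is.null(rec$breath_onsets) && any(diff(rec$breath_onsets) <= 0))
    transrr_error("transrr_format_error", "breath_onsets must be strictly increasing")
  if (!is.null(rec$rr_missing_mask) &&
      length(rec$rr_missing_mask) != length(rec$rr_ref))
    transrr_error("transrr_format_error", "rr_missing_mask not aligned to rr_ref")
  invisible(rec)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s), age %.1f\n", x$subject_id, x$dataset, x$age))
  cat(sprintf("  ECG/PPG: %d samples at %g Hz (%.1f s)\n", length(x$ecg),
              x$fs_signal, length(x$ecg) / x$fs_signal))
  cat(sprintf("  RR ref:  %d samples at %g Hz%s\n", length(x$rr_ref), x$fs_rr,
              if (!is.null(x$rr_missing_mask))
                sprintf(" (%.0f%% missing)", 100 * mean(x$rr_missing_mask)) else ""))
  invisible(x)
}

fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path))
    transrr_error("transrr_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    transrr_error("transrr_format_error", "%s: missing column(s): %s", path,
                  paste(missing, collapse = ", "))
  df
}

#' Read a subject recording from the package CSV dialect
#'
#' The dialect is a trio of UTF-8, `.`-decimal CSV files sharing a stem:
#' `<stem>.csv` with columns `t,ecg,ppg` (`t` in seconds, strictly
#' increasing), `<stem>_rr.csv` with columns `t,rr` (empty `rr` cells mark
#' missing reference samples), and `<stem>_meta.csv` with columns
#' `subject_id,age,dataset,fs_signal`. An optional `<stem>_onsets.csv` with a
#' single `onset` column carries breath-onset sample indices.
#'
#' @param path Path to the `<stem>.csv` signal file.
#' @return A [subject_record()].
#' @seealso [write_subject_csv()]
#' @export
read_subject_csv <- function(path) {
  stem <- sub("\\.csv$", "", path)
  sig <- read_csv_strict(path, c("t", "ecg", "ppg"))
  if (nrow(sig) > 1 && any(diff(sig$t) <= 0))
    transrr_error("transrr_format_error", "%s: time column not strictly increasing", path)
  meta <- read_csv_strict(paste0(stem, "_meta.csv"),
                          c("subject_id", "age", "dataset", "fs_signal"))
  rr <- read_csv_strict(paste0(stem, "_rr.csv"), c("t", "rr"))
  rr_vals <- suppressWarnings(as.numeric(rr$rr))
  mask <- is.na(rr_vals)
  rr_vals[mask] <- NA_real_
  onset_path <- paste0(stem, "_onsets.csv")
  onsets <- NULL
  if (file.exists(onset_path)) onsets <- read_csv_strict(onset_path, "onset")$onset
  fs_rr <- if (nrow(rr) > 1) 1 / stats::median(diff(rr$t)) else 1
  subject_record(subject_id = meta$subject_id[1], dataset = meta$dataset[1],
                 age = meta$age[1], ecg = sig$ecg, ppg = sig$ppg,
                 fs_signal = meta$fs_signal[1], rr_ref = rr_vals, fs_rr = fs_rr,
                 breath_onsets = onsets,
                 rr_missing_mask = if (any(mask)) mask else NULL)
}

#' Write a subject recording in the package CSV dialect
#'
#' Values are written with 17 significant digits so that a
#' write-then-read round trip is bit-exact. Missing RR samples (per
#' `rr_missing_mask`) become empty cells. The onset file is only written when
#' breath onsets are present.
#'
#' @param record A [subject_record()].
#' @param path Path of the signal file to create (`<stem>.csv`); the sibling
#'   `_rr.csv`, `_meta.csv` and (optionally) `_onsets.csv` files are derived
#'   from its stem.
#' @return Invisibly, `path`.
#' @export
write_subject_csv <- function(record, path) {
  validate_subject_record(record)
  stem <- sub("\\.csv$", "", path)
  dir <- dirname(path)
  if (!dir.exists(dir))
    transrr_error("transrr_io_error", "directory does not exist: %s", dir)
  n <- length(record$ecg)
  t <- (seq_len(n) - 1) / record$fs_signal
  writeLines(c("t,ecg,ppg",
               paste(fmt_full(t), fmt_full(record$ecg), fmt_full(record$ppg),
                     sep = ",")), path)
  rr <- record$rr_ref
  if (!is.null(record$rr_missing_mask)) rr[record$rr_missing_mask] <- NA_real_
  t_rr <- (seq_along(rr) - 1) / record$fs_rr
  writeLines(c("t,rr", paste(fmt_full(t_rr), fmt_full(rr), sep = ",")),
             paste0(stem, "_rr.csv"))
  writeLines(c("subject_id,age,dataset,fs_signal",
               paste(record$subject_id, fmt_full(record$age), record$dataset,
                     fmt_full(record$fs_signal), sep = ",")),
             paste0(stem, "_meta.csv"))
  if (!is.null(record$breath_onsets))
    writeLines(c("onset", fmt_full(record$breath_onsets)),
               paste0(stem, "_onsets.csv"))
  invisible(path)
}

#' Derive a reference RR trace from breath-onset annotations
#'
#' The instantaneous rate between consecutive onsets i and i+1 is
#' 60 / (interval in seconds), held piecewise-constant over that inter-breath
#' interval; before the first and after the last interval the nearest
#' interval's value is extended. The resulting trace is sampled on the
#' `fs_out` grid (t = 0, 1/fs_out, ...).
#'
#' @param onsets Strictly increasing breath-onset sample indices on the
#'   `fs_signal` grid (at least 2).
#' @param fs_signal Sampling rate of the annotated signal in Hz.
#' @param duration_s Duration of the output trace in seconds.
#' @param fs_out Output sampling rate in Hz (typically 1).
#' @return Numeric vector of length `round(duration_s * fs_out)` in breaths/min.
#' @export
rr_from_breath_onsets <- function(onsets, fs_signal, duration_s, fs_out) {
  if (length(onsets) < 2)
    transrr_error("transrr_annotation_error",
                  "need at least 2 breath onsets, got %d", length(onsets))
  if (fs_out <= 0 || fs_signal <= 0)
    transrr_error("transrr_parameter_error", "sampling rates must be positive")
  if (any(diff(onsets) <= 0))
    transrr_error("transrr_annotation_error", "onsets must be strictly increasing")
  t_on <- onsets / fs_signal
  rr_int <- 60 / diff(t_on)                      # one value per interval
  n_out <- round(duration_s * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  idx <- findInterval(t_out, t_on)               # 0 before first onset
  idx <- pmin(pmax(idx, 1L), length(rr_int))     # edge hold
  rr_int[idx]
}

#' Construct a segment set
#'
#' A matrix-backed collection of model-ready 16 s segments: each row of `ecg`
#' and `ppg` is one decimated window, with an aligned RR label and subject id.
#'
#' @param ecg,ppg Numeric matrices (`n_segments` x window length).
#' @param rr_label Numeric vector of RR labels in breaths/min.
#' @param subject_id Character vector of per-segment subject ids.
#' @param params_fingerprint Character scalar summarising the preprocessing
#'   parameters that produced the set.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(ecg, ppg, rr_label, subject_id,
                        params_fingerprint = "") {
  ecg <- as.matrix(ecg); ppg <- as.matrix(ppg)
  n <- nrow(ecg)
  if (nrow(ppg) != n || length(rr_label) != n || length(subject_id) != n)
    transrr_error("transrr_format_error", "segment_set components are not aligned")
  if (n > 0 && ncol(ecg) != ncol(ppg))
    transrr_error("transrr_format_error", "ECG and PPG window lengths differ")
  structure(list(ecg = ecg, ppg = ppg, rr_label = as.numeric(rr_label),
                 subject_id = as.character(subject_id),
                 params_fingerprint = as.character(params_fingerprint)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples, %d subject(s)\n",
              n_segments(x), if (n_segments(x)) ncol(x$ecg) else 0,
              length(unique(x$subject_id))))
  if (n_segments(x))
    cat(sprintf("  RR labels: %.1f-%.1f breaths/min\n", min(x$rr_label),
                max(x$rr_label)))
  invisible(x)
}

#' Number of segments in a segment set
#' @param set A [segment_set()].
#' @return Integer count.
#' @export
n_segments <- function(set) nrow(set$ecg)

#' Row-bind segment sets
#' @param ... [segment_set()] objects (sharing one window length).
#' @param params_fingerprint Fingerprint for the pooled set; defaults to the
#'   first non-empty input fingerprint.
#' @return A pooled [segment_set()].
#' @export
bind_segment_sets <- function(..., params_fingerprint = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "segment_set"))
    sets <- sets[[1]]
  fps <- vapply(sets, function(s) s$params_fingerprint, "")
  segment_set(do.call(rbind, lapply(sets, `[[`, "ecg")),
              do.call(rbind, lapply(sets, `[[`, "ppg")),
              unlist(lapply(sets, `[[`, "rr_label")) %||% numeric(),
              unlist(lapply(sets, `[[`, "subject_id")) %||% character(),
              params_fingerprint %||% (fps[nzchar(fps)][1] %||% ""))
}

#' Subset a segment set
#' @param set A [segment_set()].
#' @param i Row index (logical or integer).
#' @return A [segment_set()] with the selected segments.
#' @export
subset_segments <- function(set, i) {
  segment_set(set$ecg[i, , drop = FALSE], set$ppg[i, , drop = FALSE],
              set$rr_label[i], set$subject_id[i], set$params_fingerprint)
}

#' Write a segment archive
#'
#' The archive is a directory holding `ecg.csv` and `ppg.csv` (headerless
#' dense numeric blocks, one row per segment, 17 significant digits),
#' `manifest.csv` (`segment_index,subject_id,rr_label`) and `meta.json`
#' (fingerprint and shapes).
#'
#' @param set A [segment_set()].
#' @param path Directory to create (must not be an existing file).
#' @return Invisibly, `path`.
#' @export
write_segment_archive <- function(set, path) {
  if (file.exists(path) && !dir.exists(path))
    transrr_error("transrr_io_error", "path exists and is not a directory: %s", path)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_block <- function(m, f) {
    con <- file(file.path(path, f), "w")
    on.exit(close(con))
    if (nrow(m))
      writeLines(apply(matrix(sprintf("%.17g", m), nrow(m)), 1, paste,
                       collapse = ","), con)
  }
  write_block(set$ecg, "ecg.csv")
  write_block(set$ppg, "ppg.csv")
  writeLines(c("segment_index,subject_id,rr_label",
               if (n_segments(set))
                 paste(seq_len(n_segments(set)), set$subject_id,
                       fmt_full(set$rr_label), sep = ",")),
             file.path(path, "manifest.csv"))
  jsonlite::write_json(list(params_fingerprint = set$params_fingerprint,
                            n_segments = n_segments(set),
                            window_len = if (n_segments(set)) ncol(set$ecg) else 0L),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a segment archive
#'
#' @param path Archive directory written by [write_segment_archive()].
#' @param expected_fingerprint Optional fingerprint; a mismatch with the
#'   stored one raises a stale-archive warning.
#' @return A [segment_set()].
#' @export
read_segment_archive <- function(path, expected_fingerprint = NULL) {
  if (!dir.exists(path))
    transrr_error("transrr_io_error", "archive not found: %s", path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  man <- utils::read.csv(file.path(path, "manifest.csv"),
                         colClasses = c("integer", "character", "numeric"))
  read_block <- function(f, n) {
    if (n == 0) return(matrix(numeric(), 0, 0))
    as.matrix(utils::read.csv(file.path(path, f), header = FALSE,
                              colClasses = "numeric"))
  }
  n <- nrow(man)
  ecg <- read_block("ecg.csv", n)
  ppg <- read_block("ppg.csv", n)
  dimnames(ecg) <- NULL; dimnames(ppg) <- NULL
  if (!is.null(expected_fingerprint) &&
      !identical(expected_fingerprint, meta$params_fingerprint))
    warning(sprintf("stale archive: fingerprint '%s' differs from expected '%s'",
                    meta$params_fingerprint, expected_fingerprint),
            call. = FALSE)
  segment_set(ecg, ppg, man$rr_label, man$subject_id,
              meta$params_fingerprint %||% "")
}
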