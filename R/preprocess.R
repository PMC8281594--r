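# Fixed-length episode segmentation, Pan-Tompkins-style R-peak detection,
# and episode-level quality control.
#
# Records are segmented on their native sampling grid: no resampling,
# ever — robustness to heterogeneous sampling frequencies is the design
# premise, and a silent resample would defeat it.

#' Fixed-length episode of an ECG record
#'
#' @param values numeric vector of exactly `length` amplitudes (mV).
#' @param label rhythm label or `NA`.
#' @param parent_record identifier of the originating record.
#' @param window_index 0-based window ordinal within the record.
#' @param pad_length number of zeros appended at the tail.
#' @param fs sampling frequency of the parent record, Hz.
#' @param subject_id subject of the parent record.
#' @param length episode length in samples; default 2700.
#' @return an object of class `ecg_episode`.
#' @export
ecg_episode <- function(values, label = NA_character_,
                        parent_record = NA_character_, window_index = 0L,
                        pad_length = 0L, fs = NA_real_,
                        subject_id = NA_character_, length = 2700L) {
  values <- as.numeric(values)
  if (base::length(values) != length)
    abort("episode must have exactly %d values, got %d",
          length, base::length(values))
  if (pad_length < 0L || pad_length >= length)
    abort("pad_length must be in [0, %d)", length)
  if (pad_length > 0L &&
      any(values[seq.int(length - pad_length + 1L, length)] != 0))
    abort("padded tail must be all zeros")
  structure(list(values = values, label = as.character(label),
                 parent_record = as.character(parent_record),
                 window_index = as.integer(window_index),
                 pad_length = as.integer(pad_length),
                 fs = as.numeric(fs), subject_id = as.character(subject_id)),
            class = "ecg_episode")
}

#' Segment a record into fixed-length episodes
#'
#' Consecutive non-overlapping windows of `L` samples (stride
#' configurable). A final partial window of at least `L/2` samples is
#' zero-padded at the tail to `L`; a shorter remainder is dropped. A
#' record shorter than `L` yields exactly one zero-padded episode.
#'
#' @param record an [ecg_record()].
#' @param L episode length in samples; default 2700.
#' @param stride window stride in samples; default `L` (non-overlapping).
#' @return list of [ecg_episode()]s, `window_index` numbered from 0.
#' @export
segment_record <- function(record, L = 2700L, stride = L) {
  stopifnot(inherits(record, "ecg_record"), is_count(L), is_count(stride))
  x <- record$samples
  n <- length(x)
  id <- if (is.na(record$subject_id)) record$source else
    sprintf("%s:%s", record$source, record$subject_id)
  starts <- if (n >= L) seq.int(1L, n - L + 1L, by = stride) else integer(0)
  episodes <- list()
  w <- 0L
  for (s in starts) {
    episodes[[w + 1L]] <- ecg_episode(x[seq.int(s, s + L - 1L)],
                                      label = record$label,
                                      parent_record = id, window_index = w,
                                      pad_length = 0L, fs = record$fs,
                                      subject_id = record$subject_id,
                                      length = L)
    w <- w + 1L
  }
  consumed <- if (n >= L) starts[length(starts)] + L - 1L else 0L
  rem <- n - consumed
  if ((n < L) || (stride == L && rem >= ceiling(L / 2))) {
    tail_vals <- x[seq.int(consumed + 1L, n)]
    pad <- L - length(tail_vals)
    episodes[[w + 1L]] <- ecg_episode(c(tail_vals, numeric(pad)),
                                      label = record$label,
                                      parent_record = id, window_index = w,
                                      pad_length = pad, fs = record$fs,
                                      subject_id = record$subject_id,
                                      length = L)
  }
  episodes
}

#' Detect R-peaks
#'
#' Pan-Tompkins-style detector: 5-15 Hz Butterworth band-pass
#' (zero-phase), squaring, 150 ms moving-window integration, adaptive
#' threshold at a fixed fraction of the upper envelope quantile, 0.2 s
#' refractory period, with each peak refined to the local maximum of the
#' band-passed signal. Deterministic.
#'
#' @param record an [ecg_record()] (fs must be known).
#' @return an object of class `r_peak_set`: `indices` (1-based sample
#'   positions, strictly increasing) and `rr_intervals` (seconds,
#'   `length(indices) - 1` of them).
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  empty <- structure(list(indices = integer(0), rr_intervals = numeric(0)),
                     class = "r_peak_set")
  if (n < fs) return(empty)                      # < 1 s of signal
  if (all(x == x[1L])) return(empty)             # flat line
  ny <- fs / 2
  hi <- min(15 / ny, 0.95)
  lo <- 5 / ny
  bf <- signal::butter(3, c(lo, hi), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  sq <- bp^2
  wlen <- max(3L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * stats::quantile(integ, 0.99, names = FALSE)
  if (thr <= 0) return(empty)
  above <- integ > thr
  # candidate = local max of the integrated signal inside an above-threshold run
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cand <- integer(0)
  half <- round(0.10 * fs)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    c0 <- seg[which.max(integ[seg])]
    lo_i <- max(1L, c0 - half)
    hi_i <- min(n, c0 + half)
    cand <- c(cand, (lo_i:hi_i)[which.max(abs(bp[lo_i:hi_i]))])
  }
  cand <- sort(unique(cand))
  refract <- round(0.2 * fs)
  keep <- integer(0)
  for (p in cand) {
    if (length(keep) && (p - keep[length(keep)]) < refract) {
      if (abs(bp[p]) > abs(bp[keep[length(keep)]]))
        keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  structure(list(indices = keep,
                 rr_intervals = diff(keep) / fs),
            class = "r_peak_set")
}

#' @export
print.r_peak_set <- function(x, ...) {
  cat(sprintf("<r_peak_set> %d peaks", length(x$indices)))
  if (length(x$rr_intervals))
    cat(sprintf(", mean RR %.3f s, CV %.3f", mean(x$rr_intervals),
                stats::sd(x$rr_intervals) / mean(x$rr_intervals)))
  cat("\n")
  invisible(x)
}

#' Episode quality control
#'
#' `TRUE` iff at least 3 R-peaks (two R-R intervals) are detected within
#' the unpadded portion of the episode. Used for reporting only — the
#' pipeline never drops episodes on QC, since segmentation is
#' unconditional.
#'
#' @param episode an [ecg_episode()].
#' @param fs sampling frequency of the parent record; defaults to the
#'   episode's own.
#' @return logical.
#' @export
episode_qc <- function(episode, fs = episode$fs) {
  stopifnot(inherits(episode, "ecg_episode"))
  if (!is_scalar_num(fs)) abort("episode_qc needs a known fs")
  n_unpadded <- length(episode$values) - episode$pad_length
  if (n_unpadded < fs) return(FALSE)
  rec <- ecg_record(episode$values[seq_len(n_unpadded)], fs)
  length(detect_r_peaks(rec)$indices) >= 3L
}

# ---- episode store ---------------------------------------------------------

#' Convert episodes to a flat table and back
#'
#' The episode store is one row per episode: metadata columns
#' (`parent_record`, `window_index`, `pad_length`, `fs`, `label`,
#' `subject_id`) followed by the amplitude columns `v1..vL`, in that
#' order.
#'
#' @param episodes list of [ecg_episode()]s.
#' @return `episodes_to_table` returns the data.frame.
#' @export
episodes_to_table <- function(episodes) {
  stopifnot(length(episodes) >= 1L)
  meta <- do.call(rbind, lapply(episodes, function(e)
    data.frame(parent_record = e$parent_record,
               window_index = e$window_index, pad_length = e$pad_length,
               fs = e$fs, label = e$label, subject_id = e$subject_id,
               stringsAsFactors = FALSE)))
  vals <- do.call(rbind, lapply(episodes, function(e) e$values))
  colnames(vals) <- paste0("v", seq_len(ncol(vals)))
  cbind(meta, as.data.frame(vals))
}

#' @rdname episodes_to_table
#' @param table a data.frame in episode-store layout.
#' @export
table_to_episodes <- function(table) {
  vcols <- grep("^v[0-9]+$", names(table), value = TRUE)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  lapply(seq_len(nrow(table)), function(i)
    ecg_episode(as.numeric(table[i, vcols]), label = table$label[i],
                parent_record = table$parent_record[i],
                window_index = table$window_index[i],
                pad_length = table$pad_length[i], fs = table$fs[i],
                subject_id = table$subject_id[i], length = length(vcols)))
}

# amplitude matrix (episodes x L) from an episode store table
episode_matrix <- function(table) {
  vcols <- grep("^v[0-9]+$", names(table), value = TRUE)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  as.matrix(table[, vcols])
}

#' Preprocess a manifest of records into an episode store
#'
#' Reads every record in the manifest (CSV paths resolved relative to the
#' manifest's directory), optionally denoises, segments into fixed-length
#' episodes, and returns the episode store table together with a QC
#' summary.
#'
#' @param manifest manifest data.frame (or path to one).
#' @param dir directory record paths are relative to; defaults to the
#'   manifest's directory when `manifest` is a path.
#' @param plan a [wavelet_plan()] or `NULL` to skip denoising.
#' @param L episode length; default 2700.
#' @param run_qc compute per-episode QC flags? Adds a `qc_pass` column.
#' @return the episode store data.frame; QC counts in attribute
#'   `"qc_summary"`.
#' @export
preprocess_manifest <- function(manifest, dir = ".", plan = wavelet_plan(),
                                L = 2700L, run_qc = FALSE) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- load_manifest(manifest)
  }
  manifest <- validate_manifest(manifest)
  if (nrow(manifest) == 0L) abort("empty manifest: nothing to preprocess")
  episodes <- list()
  failed <- character(0)
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$path[i])
    rec <- tryCatch(
      read_record_csv(path, fs = manifest$fs_hz[i],
                      label = manifest$label[i],
                      subject_id = manifest$subject_id[i]),
      error = function(e) e)
    if (inherits(rec, "error")) {
      warnf("skipping unreadable record %s: %s", path, conditionMessage(rec))
      failed <- c(failed, path)
      next
    }
    if (!is.null(plan)) rec <- suppressWarnings(denoise_record(rec, plan))
    episodes <- c(episodes, segment_record(rec, L = L))
  }
  if (!length(episodes))
    abort("all %d records failed to preprocess", nrow(manifest))
  tab <- episodes_to_table(episodes)
  qc <- NULL
  if (run_qc) {
    eps <- table_to_episodes(tab)
    tab$qc_pass <- vapply(eps, episode_qc, logical(1L))
    qc <- c(episodes = nrow(tab), padded = sum(tab$pad_length > 0),
            qc_fail = sum(!tab$qc_pass), failed_records = length(failed))
  } else {
    qc <- c(episodes = nrow(tab), padded = sum(tab$pad_length > 0),
            qc_fail = NA, failed_records = length(failed))
  }
  log_stage("preprocess", "%d records -> %d episodes (%d padded, %d skipped)",
            nrow(manifest), nrow(tab), sum(tab$pad_length > 0), length(failed))
  attr(tab, "qc_summary") <- qc
  tab
}
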