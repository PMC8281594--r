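# Record and manifest containers and their on-disk formats: two-column CSV
# records, WFDB (.hea/.dat, format 16) record pairs with a subset MIT
# annotation reader/writer, and dataset manifest CSVs.
#
# Everything internal is millivolts; WFDB gain is applied on read and write
# so the single-unit invariant holds package-wide.

#' Single-lead ECG record
#'
#' @param samples numeric vector of amplitudes in mV.
#' @param fs sampling frequency in Hz.
#' @param label rhythm label, one of [rhythm_classes()] or `NA` for
#'   unlabeled.
#' @param subject_id opaque subject identifier.
#' @param source free-text dataset tag.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, label = NA_character_,
                       subject_id = NA_character_, source = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) abort("an ecg_record needs at least one sample")
  if (!is_scalar_num(fs) || fs <= 0) abort("fs must be a positive number")
  label <- as.character(label)
  if (!is.na(label) && !label %in% rhythm_classes())
    abort("label must be one of %s or NA, got '%s'",
          paste(rhythm_classes(), collapse = "/"), label)
  structure(list(samples = samples, fs = as.numeric(fs), label = label,
                 subject_id = as.character(subject_id),
                 source = as.character(source)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.2f s), label=%s, subject=%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$label, x$subject_id))
  invisible(x)
}

#' Read an ECG record from a two-column CSV file
#'
#' Expects columns (time_s, amplitude_mV), comma-separated, '.' decimal,
#' with an optional single header line. The sampling frequency is the
#' reciprocal of the median time step unless `fs` is supplied, which
#' always wins (a warning is emitted when the time column disagrees with
#' it by more than 1%).
#'
#' @param path CSV file path.
#' @param fs optional explicit sampling frequency in Hz, overriding the
#'   time column.
#' @param label,subject_id,source metadata attached to the record.
#' @return an [ecg_record()].
#' @export
read_record_csv <- function(path, fs = NULL, label = NA_character_,
                            subject_id = NA_character_, source = "csv") {
  if (!file.exists(path)) abort("no such record file: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort("empty record file: %s", path)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("time_s", "amplitude_mV"),
                        colClasses = "numeric")
  if (nrow(df) < 2L) abort("record file %s has fewer than 2 samples", path)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) abort("non-monotone time column in %s", path)
  fs_inferred <- 1 / stats::median(dt)
  if (is.null(fs)) {
    fs_use <- fs_inferred
  } else {
    if (abs(fs_inferred - fs) / fs > 0.01)
      warnf("explicit fs = %g Hz overrides time column (implied %g Hz) in %s",
            fs, fs_inferred, path)
    fs_use <- fs
  }
  ecg_record(df$amplitude_mV, fs_use, label = label,
             subject_id = subject_id, source = source)
}

#' Write an ECG record as a two-column CSV file
#'
#' @param record an [ecg_record()].
#' @param path output path.
#' @param header write a `time_s,amplitude_mV` header line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path, header = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / record$fs,
                   amplitude_mV = record$samples)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

# ---- WFDB (format 16) ------------------------------------------------------

# Annotation type codes used for .atr round trips (subset of the MIT table).
.wfdb_ann_codes <- c("N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L,
                     "F" = 6L, "J" = 7L, "A" = 8L, "S" = 9L, "E" = 10L,
                     "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
                     "+" = 28L, "x" = 37L, "|" = 40L)

#' Write an ECG record as a WFDB record (.hea/.dat pair, format 16)
#'
#' Amplitudes are quantized at `gain` adu/mV into 16-bit little-endian
#' integers. Optionally writes a WFDB annotation file from a vector of
#' (sample index, symbol) annotations.
#'
#' @param record an [ecg_record()], or a list of them for a multi-channel
#'   record (all channels must share fs and length).
#' @param dir output directory.
#' @param name record name (file stem).
#' @param gain adu per mV; default 200.
#' @param annotations optional data.frame with columns `sample` (0-based
#'   index) and `symbol`; written to `<name>.atr`.
#' @param channel_names optional character vector of signal descriptions.
#' @return the record path stem, invisibly.
#' @export
write_record_wfdb <- function(record, dir, name, gain = 200,
                              annotations = NULL, channel_names = NULL) {
  chans <- if (inherits(record, "ecg_record")) list(record) else record
  stopifnot(length(chans) >= 1L,
            all(vapply(chans, inherits, TRUE, "ecg_record")))
  fs <- chans[[1L]]$fs
  n <- length(chans[[1L]]$samples)
  for (ch in chans)
    if (ch$fs != fs || length(ch$samples) != n)
      abort("all channels of a WFDB record must share fs and length")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%d", seq_along(chans) - 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adus <- lapply(chans, function(ch) {
    v <- as.integer(round(ch$samples * gain))
    pmin(pmax(v, -32768L), 32767L)
  })
  hea <- c(sprintf("%s %d %g %d", name, length(chans), fs, n),
           vapply(seq_along(chans), function(i) {
             sumv <- sum(adus[[i]]) %% 65536
             if (sumv >= 32768) sumv <- sumv - 65536
             sprintf("%s.dat 16 %g/mV 16 0 %d %d 0 %s",
                     name, gain, adus[[i]][1L], sumv, channel_names[i])
           }, character(1L)))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  mat <- do.call(rbind, adus)          # channels x samples, interleave by column
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  writeBin(as.integer(mat), con, size = 2L, endian = "little")
  close(con)
  if (!is.null(annotations))
    write_wfdb_annotations(annotations, file.path(dir, paste0(name, ".atr")))
  invisible(file.path(dir, name))
}

write_wfdb_annotations <- function(annotations, path) {
  stopifnot(is.data.frame(annotations),
            all(c("sample", "symbol") %in% names(annotations)))
  ord <- order(annotations$sample)
  samp <- as.integer(annotations$sample)[ord]
  sym <- as.character(annotations$symbol)[ord]
  con <- file(path, "wb")
  on.exit(close(con))
  put_word <- function(w) writeBin(as.integer(w), con, size = 2L,
                                   endian = "little")
  prev <- 0L
  for (i in seq_along(samp)) {
    code <- .wfdb_ann_codes[[sym[i]]]
    if (is.null(code)) abort("no WFDB code for annotation symbol '%s'", sym[i])
    delta <- samp[i] - prev
    if (delta > 1023L) {
      put_word(bitwShiftL(59L, 10L))            # SKIP, then 4-byte interval
      put_word(bitwAnd(bitwShiftR(delta, 16L), 65535L))
      put_word(bitwAnd(delta, 65535L))
      delta <- 0L
    }
    put_word(bitwOr(bitwShiftL(code, 10L), delta))
    prev <- samp[i]
  }
  put_word(0L)                                   # end of annotations
  invisible(path)
}

#' Read WFDB annotations
#'
#' Supports the plain annotation words plus the SKIP (long interval)
#' pseudo-annotation; AUX and other pseudo-annotations are skipped.
#'
#' @param path `.atr`/`.qrs` file path.
#' @return data.frame with columns `sample` (0-based) and `symbol`
#'   (annotation mnemonic, `"?"` for codes outside the shipped table).
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) abort("no such annotation file: %s", path)
  raw <- readBin(path, "integer", n = file.size(path) %/% 2L,
                 size = 2L, signed = FALSE, endian = "little")
  sym_of <- names(.wfdb_ann_codes)
  samples <- integer(0)
  symbols <- character(0)
  t <- 0L
  i <- 1L
  pending_skip <- 0L
  while (i <= length(raw)) {
    w <- raw[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == 59L && delta == 0L) {            # SKIP: 4-byte interval follows
      pending_skip <- bitwShiftL(raw[i + 1L], 16L) + raw[i + 2L]
      i <- i + 3L
      next
    }
    if (code == 63L) {                           # AUX: skip payload
      i <- i + 1L + (delta + delta %% 2L) %/% 2L
      next
    }
    if (code >= 60L) { i <- i + 1L; next }       # other pseudo-annotations
    t <- t + pending_skip + delta
    pending_skip <- 0L
    m <- match(code, .wfdb_ann_codes)
    samples <- c(samples, t)
    symbols <- c(symbols, if (is.na(m)) "?" else sym_of[m])
    i <- i + 1L
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

#' Read an ECG record from a WFDB record pair
#'
#' Parses the `.hea` header and format-16 `.dat` file written under the
#' PhysioNet conventions. When channel names are present and `channel` is
#' not given, a channel described as Lead II (`"II"` / `"MLII"`) is
#' preferred, else channel 0. Gain is applied so samples come back in mV.
#'
#' @param record_name path stem of the record (no extension).
#' @param channel 0-based channel index; default picks Lead II when named,
#'   else the first channel.
#' @param annotation optional annotation extension (e.g. `"atr"`); when
#'   given together with `label_map` the record label is taken from the
#'   first annotation whose symbol the map covers.
#' @param label_map named character vector mapping annotation symbols to
#'   [rhythm_classes()] labels; symbols outside the map leave the record
#'   unlabeled.
#' @param subject_id,source metadata attached to the record.
#' @return an [ecg_record()].
#' @export
read_record_wfdb <- function(record_name, channel = NULL, annotation = NULL,
                             label_map = NULL, subject_id = NA_character_,
                             source = "wfdb") {
  hea_path <- paste0(record_name, ".hea")
  if (!file.exists(hea_path)) abort("missing WFDB header: %s", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_f[2L])
  fs <- if (length(head_f) >= 3L) as.numeric(head_f[3L]) else 250
  nsamp <- if (length(head_f) >= 4L) as.integer(head_f[4L]) else NA_integer_
  if (nsig < 1L) abort("header %s declares no signals", hea_path)
  sig_lines <- lines[seq.int(2L, 1L + nsig)]
  sig <- lapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- f[2L]
    if (!identical(sub("x.*", "", fmt), "16"))
      abort("unsupported WFDB signal format '%s' (only 16)", fmt)
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- {
      b <- regmatches(gain_field, regexec("\\(([-0-9]+)\\)", gain_field))[[1L]]
      if (length(b) == 2L) as.numeric(b[2L]) else 0
    }
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1L], gain = gain, baseline = baseline, desc = desc)
  })
  if (is.null(channel)) {
    descs <- toupper(vapply(sig, `[[`, character(1L), "desc"))
    lead2 <- which(descs %in% c("II", "MLII", "LEAD II"))
    channel <- if (length(lead2)) lead2[1L] - 1L else 0L
  }
  if (channel < 0L || channel >= nsig)
    abort("channel %d out of range for %d-signal record", channel, nsig)
  dat_path <- file.path(dirname(record_name), sig[[1L]]$file)
  if (!file.exists(dat_path)) abort("missing WFDB data file: %s", dat_path)
  raw <- readBin(dat_path, "integer", n = file.size(dat_path) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
  total <- (length(raw) %/% nsig) * nsig
  mat <- matrix(raw[seq_len(total)], nrow = nsig)
  x <- mat[channel + 1L, ]
  if (!is.na(nsamp) && nsamp <= ncol(mat)) x <- x[seq_len(nsamp)]
  ch <- sig[[channel + 1L]]
  samples <- (x - ch$baseline) / ch$gain
  label <- NA_character_
  if (!is.null(annotation)) {
    ann_path <- paste0(record_name, ".", annotation)
    if (file.exists(ann_path) && !is.null(label_map)) {
      ann <- read_wfdb_annotations(ann_path)
      mapped <- label_map[ann$symbol]
      mapped <- mapped[!is.na(mapped)]
      if (length(mapped)) label <- unname(mapped[1L])
    }
  }
  ecg_record(samples, fs, label = label, subject_id = subject_id,
             source = source)
}

# ---- label taxonomy --------------------------------------------------------

#' Mapping from common arrhythmia names to the three-class taxonomy
#'
#' Collapses the named non-AF arrhythmias (including atrial flutter) to
#' `NON_AF`; normal sinus rhythm maps to `N` and atrial fibrillation to
#' `AF`.
#'
#' @return named character vector: arrhythmia name -> class label.
#' @export
arrhythmia_label_map <- function() {
  c("normal sinus rhythm" = "N",
    "atrial fibrillation" = "AF",
    "atrial flutter" = "NON_AF",
    "supraventricular tachycardia" = "NON_AF",
    "sinus bradycardia" = "NON_AF",
    "sinus tachycardia" = "NON_AF",
    "premature ventricular contraction" = "NON_AF",
    "premature atrial contraction" = "NON_AF",
    "left bundle branch block" = "NON_AF",
    "right bundle branch block" = "NON_AF",
    "first-degree atrioventricular block" = "NON_AF",
    "ventricular escape" = "NON_AF",
    "junctional rhythm" = "NON_AF")
}

# ---- manifests -------------------------------------------------------------

.manifest_cols <- c("path", "fs_hz", "label", "subject_id", "split")
.split_levels <- c("train", "val", "test", "unassigned")

validate_manifest <- function(manifest) {
  need <- setdiff(c("path", "fs_hz", "label", "subject_id"), names(manifest))
  if (length(need)) abort("manifest is missing column '%s'", need[1L])
  if (!"split" %in% names(manifest))
    manifest$split <- rep("unassigned", nrow(manifest))
  if (anyDuplicated(manifest$path))
    abort("manifest has duplicate path '%s'",
          manifest$path[duplicated(manifest$path)][1L])
  bad <- setdiff(unique(manifest$split), .split_levels)
  if (length(bad)) abort("unknown split value '%s'", bad[1L])
  bad_lab <- setdiff(unique(manifest$label[!is.na(manifest$label)]),
                     rhythm_classes())
  if (length(bad_lab)) abort("unknown label '%s' in manifest", bad_lab[1L])
  manifest
}

#' Load or save a dataset manifest
#'
#' A manifest is one CSV row per record: `path`, `fs_hz`, `label`,
#' `subject_id`, `split` (one of train/val/test/unassigned; absent column
#' means all unassigned). Extra columns round-trip untouched.
#'
#' @param path manifest CSV path.
#' @return `load_manifest` returns the manifest data.frame.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) abort("no such manifest: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

#' @rdname load_manifest
#' @param manifest manifest data.frame.
#' @export
save_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.table(manifest, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
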