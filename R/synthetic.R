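# Seeded synthetic single-lead ECG generator.
#
# Beat morphology is a sum-of-Gaussians P/QRS/T template placed at R-times
# drawn from a log-normal R-R interval model; atrial fibrillation replaces
# the P-wave with a band-limited (6-8 Hz) fibrillatory oscillation and
# draws i.i.d. irregular R-R intervals. Additive artifacts: baseline
# wander (< 0.5 Hz), 50 Hz powerline, white noise. Every draw site uses a
# child seed derived from the root seed, so outputs are reproducible and
# stable under insertion of new draw sites.

#' Rhythm parameters for the synthetic generator
#'
#' @param rhythm_class one of [rhythm_classes()].
#' @param mean_hr mean heart rate, beats/min.
#' @param rr_cv coefficient of variation of R-R intervals (dimensionless).
#'   AF requires `rr_cv >= 0.15` ("irregularly irregular"); N requires
#'   `rr_cv <= 0.05`.
#' @param p_wave_amplitude P-wave amplitude in mV; must be 0 for AF
#'   (P-waves disappear) and > 0 for N.
#' @param f_wave_amplitude fibrillatory-wave amplitude in mV; > 0 only
#'   for AF.
#' @param variant Non-AF subtype tag (`"bradycardia"`, `"tachycardia"`,
#'   `"ectopic"`); ignored for N/AF.
#' @return an object of class `rhythm_params`.
#' @export
rhythm_params <- function(rhythm_class = c("N", "AF", "NON_AF"),
                          mean_hr = NULL, rr_cv = NULL,
                          p_wave_amplitude = NULL, f_wave_amplitude = NULL,
                          variant = "bradycardia") {
  rhythm_class <- match.arg(rhythm_class)
  defaults <- switch(rhythm_class,
    N      = list(mean_hr = 70, rr_cv = 0.03, p = 0.15, f = 0),
    AF     = list(mean_hr = 95, rr_cv = 0.25, p = 0, f = 0.08),
    NON_AF = switch(variant,
      bradycardia = list(mean_hr = 45, rr_cv = 0.04, p = 0.15, f = 0),
      tachycardia = list(mean_hr = 130, rr_cv = 0.04, p = 0.12, f = 0),
      ectopic     = list(mean_hr = 75, rr_cv = 0.10, p = 0.15, f = 0),
      abort("unknown NON_AF variant '%s'", variant)))
  p <- list(rhythm_class = rhythm_class,
            mean_hr = mean_hr %||% defaults$mean_hr,
            rr_cv = rr_cv %||% defaults$rr_cv,
            p_wave_amplitude = p_wave_amplitude %||% defaults$p,
            f_wave_amplitude = f_wave_amplitude %||% defaults$f,
            variant = if (rhythm_class == "NON_AF") variant else NA_character_)
  if (p$mean_hr <= 0) abort("mean_hr must be positive")
  if (p$rr_cv < 0) abort("rr_cv must be >= 0")
  if (rhythm_class == "AF") {
    if (p$p_wave_amplitude != 0)
      abort("AF rhythm must have p_wave_amplitude = 0")
    if (p$rr_cv < 0.15)
      abort("AF rhythm requires rr_cv >= 0.15, got %g", p$rr_cv)
  }
  if (rhythm_class == "N") {
    if (p$rr_cv > 0.05)
      abort("N rhythm requires rr_cv <= 0.05, got %g", p$rr_cv)
    if (p$p_wave_amplitude <= 0)
      abort("N rhythm requires p_wave_amplitude > 0")
  }
  if (rhythm_class != "AF" && p$f_wave_amplitude != 0)
    abort("f_wave_amplitude > 0 is only meaningful for AF")
  structure(p, class = "rhythm_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Artifact (noise) parameters for the synthetic generator
#'
#' @param baseline_wander_amplitude mV; slow sinusoidal drift.
#' @param baseline_wander_freq Hz, must be < 0.5.
#' @param powerline_amplitude mV at 50 Hz.
#' @param white_noise_sd mV.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(baseline_wander_amplitude = 0.05,
                         baseline_wander_freq = 0.3,
                         powerline_amplitude = 0.02,
                         white_noise_sd = 0.02) {
  vals <- c(baseline_wander_amplitude, powerline_amplitude, white_noise_sd)
  if (any(vals < 0)) abort("noise amplitudes must be >= 0")
  if (baseline_wander_freq <= 0 || baseline_wander_freq >= 0.5)
    abort("baseline_wander_freq must be in (0, 0.5) Hz")
  structure(list(baseline_wander_amplitude = baseline_wander_amplitude,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amplitude = powerline_amplitude,
                 white_noise_sd = white_noise_sd),
            class = "noise_params")
}

#' Full configuration for one synthetic record
#'
#' @param fs sampling frequency, Hz, in `[100, 500]` unless
#'   `allow_any_fs`.
#' @param duration record length in seconds; must cover at least 3 beats
#'   at `mean_hr`.
#' @param rhythm a [rhythm_params()].
#' @param noise a [noise_params()].
#' @param seed integer; fully determines the record.
#' @param allow_any_fs lift the 100-500 Hz guard.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(fs = 250, duration = 10,
                         rhythm = rhythm_params("N"),
                         noise = noise_params(), seed = 1L,
                         allow_any_fs = FALSE) {
  stopifnot(inherits(rhythm, "rhythm_params"), inherits(noise, "noise_params"))
  if (!is_scalar_num(fs) || fs <= 0) abort("fs must be positive")
  if (!allow_any_fs && (fs < 100 || fs > 500))
    abort("fs = %g Hz outside the supported 100-500 Hz range", fs)
  min_dur <- 3 * 60 / rhythm$mean_hr
  if (!is_scalar_num(duration) || duration < min_dur)
    abort("duration %.3g s too short: at %g bpm at least %.3g s (3 beats) needed",
          duration, rhythm$mean_hr, min_dur)
  structure(list(fs = fs, duration = duration, rhythm = rhythm,
                 noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

# R-R intervals are i.i.d. log-normal with the configured mean and CV;
# drawn in continuous time so R-times do not depend on fs.
draw_beat_times <- function(rhythm, duration, seed) {
  mean_rr <- 60 / rhythm$mean_hr
  sdlog <- sqrt(log(1 + rhythm$rr_cv^2))
  meanlog <- log(mean_rr) - sdlog^2 / 2
  n_max <- ceiling(duration / mean_rr * 3) + 10L
  with_seed(seed, {
    t0 <- stats::runif(1, 0.2, 0.8) * mean_rr
    rr <- stats::rlnorm(n_max, meanlog, sdlog)
    if (identical(rhythm$variant, "ectopic")) {
      # premature beats: ~15% of intervals shortened, next compensatory
      early <- stats::runif(n_max) < 0.15
      rr[early] <- rr[early] * 0.65
      rr[c(FALSE, early[-n_max])] <- rr[c(FALSE, early[-n_max])] * 1.3
    }
    times <- t0 + cumsum(c(0, rr))
    times[times < duration]
  })
}

# Gaussian bump helper, vectorised over a whole sample grid
add_gauss <- function(x, tgrid, center, amp, sd) {
  lo <- findInterval(center - 4 * sd, tgrid)
  hi <- findInterval(center + 4 * sd, tgrid)
  if (hi < 1L || lo >= length(tgrid)) return(x)
  idx <- max(lo, 1L):min(hi + 1L, length(tgrid))
  x[idx] <- x[idx] + amp * exp(-((tgrid[idx] - center)^2) / (2 * sd^2))
  x
}

#' Generate one synthetic ECG record
#'
#' @param config a [synth_config()].
#' @return an [ecg_record()] of exactly `round(fs * duration)` samples,
#'   with the R-times used stored in attribute `"r_times"` (seconds).
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(fs * config$duration)
  tgrid <- (seq_len(n) - 1L) / fs
  rhythm <- config$rhythm
  beat_seed <- derive_seed(config$seed, "rr")
  r_times <- draw_beat_times(rhythm, config$duration, beat_seed)
  x <- numeric(n)
  rr_local <- diff(c(r_times, r_times[length(r_times)] + 60 / rhythm$mean_hr))
  for (i in seq_along(r_times)) {
    tr <- r_times[i]
    k <- min(max(rr_local[i], 0.5), 1.2)      # compress P/T offsets at high HR
    x <- add_gauss(x, tgrid, tr - 0.035, -0.10, 0.010)   # Q
    x <- add_gauss(x, tgrid, tr, 1.00, 0.012)            # R
    x <- add_gauss(x, tgrid, tr + 0.035, -0.15, 0.010)   # S
    x <- add_gauss(x, tgrid, tr + 0.30 * k, 0.30, 0.05 * k)  # T
    if (rhythm$p_wave_amplitude > 0)
      x <- add_gauss(x, tgrid, tr - 0.17 * k, rhythm$p_wave_amplitude,
                     0.022)                              # P
  }
  if (rhythm$f_wave_amplitude > 0) {
    f_seed <- derive_seed(config$seed, "fwave")
    fw <- with_seed(f_seed, {
      f0 <- stats::runif(1, 6, 8)                         # fibrillatory band
      dphi <- 2 * pi * f0 / fs + stats::rnorm(n, 0, 0.05)
      sin(cumsum(dphi) + stats::runif(1, 0, 2 * pi))
    })
    x <- x + rhythm$f_wave_amplitude * fw
  }
  noise <- config$noise
  if (noise$baseline_wander_amplitude > 0) {
    phi <- with_seed(derive_seed(config$seed, "bw"),
                     stats::runif(1, 0, 2 * pi))
    x <- x + noise$baseline_wander_amplitude *
      sin(2 * pi * noise$baseline_wander_freq * tgrid + phi)
  }
  if (noise$powerline_amplitude > 0) {
    phi <- with_seed(derive_seed(config$seed, "pl"),
                     stats::runif(1, 0, 2 * pi))
    x <- x + noise$powerline_amplitude * sin(2 * pi * 50 * tgrid + phi)
  }
  if (noise$white_noise_sd > 0)
    x <- x + with_seed(derive_seed(config$seed, "white"),
                       stats::rnorm(n, 0, noise$white_noise_sd))
  rec <- ecg_record(x, fs, label = rhythm$rhythm_class,
                    source = "synthetic")
  attr(rec, "r_times") <- r_times
  rec
}

#' Generate a labeled synthetic dataset with a manifest
#'
#' Writes `n_per_class` records per requested class as two-column CSVs
#' under `dir`, assigning subjects round-robin within each class so that
#' inter-patient splits are meaningful, and returns (and writes) the
#' manifest. Per-record heart rate is jittered log-normally (5% CV) around
#' the class default; each record gets its own derived seed.
#'
#' @param dir output directory.
#' @param n_per_class records per class.
#' @param classes subset of [rhythm_classes()].
#' @param subjects number of distinct subjects.
#' @param fs sampling frequency, Hz.
#' @param duration record duration, seconds.
#' @param seed root seed.
#' @param rhythm_overrides optional named list (by class) of argument
#'   lists forwarded to [rhythm_params()] (e.g.
#'   `list(AF = list(rr_cv = 0.3))`).
#' @param noise a [noise_params()] shared by all records.
#' @param write_records write the per-record CSVs? Default `TRUE`.
#' @param allow_any_fs lift the 100-500 Hz sampling-frequency guard.
#' @return the manifest data.frame (also saved as `dir/manifest.csv`),
#'   with the generated records attached as attribute `"records"`.
#' @export
generate_dataset <- function(dir, n_per_class = 10L,
                             classes = c("N", "AF"), subjects = 5L,
                             fs = 250, duration = 10, seed = 1L,
                             rhythm_overrides = list(),
                             noise = noise_params(),
                             write_records = TRUE, allow_any_fs = FALSE) {
  if (!is_count(n_per_class)) abort("n_per_class must be a positive count")
  if (!is_count(subjects)) abort("subjects must be a positive count")
  classes <- match.arg(classes, rhythm_classes(), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  variants <- c("bradycardia", "tachycardia", "ectopic")
  rows <- list()
  records <- list()
  i_global <- 0L
  for (cls in classes) {
    for (j in seq_len(n_per_class)) {
      i_global <- i_global + 1L
      rec_seed <- derive_seed(seed, sprintf("record/%s/%d", cls, j))
      args <- c(list(rhythm_class = cls),
                if (cls == "NON_AF")
                  list(variant = variants[(j - 1L) %% 3L + 1L]),
                rhythm_overrides[[cls]])
      rp <- do.call(rhythm_params, args)
      hr_jitter <- with_seed(derive_seed(rec_seed, "hr"),
                             stats::rlnorm(1, 0, 0.05))
      rp$mean_hr <- rp$mean_hr * hr_jitter
      cfg <- synth_config(fs = fs, duration = duration, rhythm = rp,
                          noise = noise, seed = rec_seed,
                          allow_any_fs = allow_any_fs)
      rec <- generate_record(cfg)
      subject <- sprintf("S%03d", (j - 1L) %% subjects + 1L)
      rec$subject_id <- subject
      fname <- sprintf("%s_%03d.csv", tolower(cls), j)
      path <- file.path(dir, fname)
      if (write_records) write_record_csv(rec, path)
      rows[[i_global]] <- data.frame(path = fname, fs_hz = fs, label = cls,
                                     subject_id = subject,
                                     split = "unassigned",
                                     stringsAsFactors = FALSE)
      records[[i_global]] <- rec
    }
  }
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, file.path(dir, "manifest.csv"))
  log_stage("generate", "%d records (%s) x %d subjects -> %s",
            nrow(manifest), paste(classes, collapse = ","), subjects, dir)
  attr(manifest, "records") <- records
  manifest
}
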