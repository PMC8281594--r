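# Segmentation, R-peak detection, QC, and the manifest-to-episodes path.

make_rec <- function(n, fs = 250) ecg_record(sin((1:n) / 7), fs, label = "N",
                                             subject_id = "S1")

test_that("segmentation follows the fixed-length + tail-padding rule", {
  eps <- segment_record(make_rec(2700))
  expect_length(eps, 1)
  expect_equal(eps[[1]]$pad_length, 0)

  eps <- segment_record(make_rec(1000))
  expect_length(eps, 1)
  expect_equal(eps[[1]]$pad_length, 1700)
  expect_true(all(eps[[1]]$values[1001:2700] == 0))

  eps <- segment_record(make_rec(5000, fs = 500))
  expect_length(eps, 2)
  expect_equal(vapply(eps, `[[`, 0L, "pad_length"), c(0L, 400L))
  expect_equal(vapply(eps, `[[`, 0L, "window_index"), 0:1)

  # remainder below L/2 is dropped
  eps <- segment_record(make_rec(2700 + 1349))
  expect_length(eps, 1)
})

test_that("episode counts and sample conservation hold over random lengths", {
  set.seed(88)
  L <- 2700L
  for (n in sample.int(20000L, 40)) {
    eps <- segment_record(make_rec(n))
    expected <- if (n < L) 1L else n %/% L + as.integer(n %% L >= L / 2)
    expect_equal(length(eps), expected)
    unpadded <- sum(vapply(eps, function(e) L - e$pad_length, 0L))
    dropped <- n - unpadded
    expect_true(dropped >= 0 && (dropped == 0 || dropped < L / 2))
    expect_equal(vapply(eps, `[[`, 0L, "window_index"),
                 seq_along(eps) - 1L)
    expect_true(all(vapply(eps, `[[`, "", "label") == "N"))
  }
})

test_that("episodes validate their shape and padding invariants", {
  expect_error(ecg_episode(numeric(10)), "exactly 2700")
  expect_error(ecg_episode(c(numeric(2699), 1), pad_length = 5),
               "all zeros")
  expect_error(ecg_episode(numeric(2700), pad_length = 2700), "pad_length")
})

test_that("R-peak detection recovers beat counts and rate irregularity", {
  rec <- quiet_record("N", fs = 250, duration = 10, mean_hr = 60, seed = 1)
  n_peaks <- length(detect_r_peaks(rec)$indices)
  expect_true(abs(n_peaks - 10) <= 1)

  expect_length(detect_r_peaks(ecg_record(numeric(1000), 250))$indices, 0)
  expect_length(detect_r_peaks(ecg_record(rnorm(100), 250))$indices, 0)

  af <- quiet_record("AF", fs = 250, duration = 20, mean_hr = 90,
                     rr_cv = 0.25, seed = 12)
  rr <- detect_r_peaks(af)$rr_intervals
  expect_gte(length(rr), 19)
  cv <- sd(rr) / mean(rr)
  expect_gt(cv, 0.15)
  expect_lt(abs(cv - 0.25) / 0.25, 0.30)
})

test_that("peak indices increase strictly and RR lengths are consistent", {
  for (seed in 1:4) {
    rec <- quiet_record("AF", fs = 200, duration = 15, seed = seed,
                        noise = noise_params())
    pk <- detect_r_peaks(rec)
    expect_true(all(diff(pk$indices) > 0))
    expect_length(pk$rr_intervals, max(length(pk$indices) - 1L, 0L))
    expect_true(all(pk$rr_intervals >= 0.2))   # refractory period
  }
})

test_that("episode QC needs three beats inside the unpadded portion", {
  rec60 <- quiet_record("N", fs = 250, duration = 10.8, mean_hr = 60,
                        seed = 2)
  ep <- segment_record(rec60)[[1]]
  expect_true(episode_qc(ep))

  rec40 <- quiet_record("N", fs = 500, duration = 10.8, mean_hr = 40,
                        seed = 3)
  ep40 <- segment_record(rec40)[[1]]      # 2700 samples = 5.4 s, ~3.6 beats
  expect_true(episode_qc(ep40))

  blank <- ecg_episode(c(sin(1:100 / 9) * 0.01, numeric(2600)),
                       pad_length = 2600, fs = 250)
  expect_false(episode_qc(blank))
})

test_that("episode tables round-trip and manifests preprocess end to end", {
  dir <- withr::local_tempdir()
  generate_dataset(dir, n_per_class = 2, classes = c("N", "AF"),
                   subjects = 2, fs = 250, duration = 12, seed = 9)
  tab <- preprocess_manifest(file.path(dir, "manifest.csv"), L = 1350,
                             run_qc = TRUE)
  # 12 s at 250 Hz = 3000 samples -> 2 episodes of 1350 + dropped 300
  expect_equal(nrow(tab), 8)
  expect_true(all(c("qc_pass", "v1", "v1350") %in% names(tab)))
  qc <- attr(tab, "qc_summary")
  expect_equal(unname(qc["episodes"]), 8)

  eps <- table_to_episodes(tab[, setdiff(names(tab), "qc_pass")])
  expect_equal(eps[[1]]$values, as.numeric(tab[1, paste0("v", 1:1350)]),
               ignore_attr = TRUE)

  expect_error(preprocess_manifest(data.frame(path = character(),
                                              fs_hz = numeric(),
                                              label = character(),
                                              subject_id = character()),
                                   dir = dir), "empty manifest")
})

test_that("unreadable records are skipped with a warning, not fatal", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(dir, n_per_class = 2, classes = "N", subjects = 1,
                        fs = 250, duration = 12, seed = 10)
  file.remove(file.path(dir, m$path[2]))
  expect_warning(tab <- preprocess_manifest(file.path(dir, "manifest.csv"),
                                            L = 1350),
                 "skipping")
  expect_equal(unname(attr(tab, "qc_summary")["failed_records"]), 1)
})
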