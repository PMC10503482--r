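fs <- 500

test_that("band-pass removes DC and passes the band at unit gain", {
  t <- seq(0, 4, by = 1 / fs)
  # DC is deep in the stopband
  y_dc <- bandpass_iir(rep(2, length(t)), fs, 5, 45)
  expect_lt(max(abs(y_dc)), 1e-6 * 2)

  # oracle: the designed filter's squared magnitude response (filtfilt) at
  # the probe frequency, from the transfer function itself
  bf <- signal::butter(4, c(5, 45) / (fs / 2), type = "pass")
  w <- 2 * pi * 20 / fs
  H <- function(coef) sum(coef * exp(-1i * w * (seq_along(coef) - 1)))
  H20 <- abs(H(bf$b) / H(bf$a))^2
  y20 <- bandpass_iir(sin(2 * pi * 20 * t), fs, 5, 45)
  mid <- round(length(t) / 2) + (-200:200)
  amp <- max(abs(y20[mid]))
  expect_equal(amp, H20, tolerance = 0.02)
  expect_gt(amp, 0.9)
  expect_lt(amp, 1.1)

  # 0.1 Hz is below the PPG band: strongly attenuated
  t2 <- seq(0, 30, by = 1 / fs)
  y01 <- bandpass_iir(sin(2 * pi * 0.1 * t2), fs, 0.8, 8)
  expect_lt(max(abs(y01[round(length(t2) / 2) + (-500:500)])), 0.1)

  expect_error(bandpass_iir(rnorm(100), fs, 10, 300),
               class = "pttbp_config_error")
})

test_that("band-pass filtering is idempotent within the passband tolerance", {
  # a signal wholly inside the 5-45 Hz passband
  t <- (0:9999) / fs
  x <- sin(2 * pi * 15 * t) + 0.6 * sin(2 * pi * 20 * t + 1) +
    0.3 * sin(2 * pi * 30 * t + 2)
  once <- bandpass_iir(x, fs, 5, 45)
  twice <- bandpass_iir(once, fs, 5, 45)
  rel_rms <- sqrt(mean((twice - once)^2)) / sqrt(mean(once^2))
  expect_lt(rel_rms, 0.01)
})

test_that("PPG onsets are found once per beat at the pulse feet", {
  rec <- synth_beat_train(beat_train_spec(heart_rate_bpm = 60,
                                          true_ptt_ms = 200, seed = 1))
  ppg_f <- bandpass_iir(rec$ppg, fs, 0.8, 8)
  onsets <- detect_ppg_onsets(ppg_f, fs)
  expect_true(length(onsets) %in% 19:20)
  expect_true(all(diff(onsets) > 0.3 & diff(onsets) < 2))
  truth_feet <- attr(rec, "truth")$foot_times_s
  err_ms <- vapply(onsets, function(o) min(abs(o - truth_feet)) * 1000,
                   numeric(1))
  expect_true(all(err_ms <= 2))  # one sample on the noiseless construction

  expect_identical(detect_ppg_onsets(rep(0, 5 * fs), fs), numeric(0))
  expect_error(detect_ppg_onsets(rnorm(100), fs), class = "pttbp_input_error")
})

test_that("noisy onsets stay within 10 ms of the generator feet", {
  rec <- synth_beat_train(beat_train_spec(seed = 9, scg_snr_db = 10,
                                          ppg_snr_db = 10))
  ppg_f <- bandpass_iir(rec$ppg, fs, 0.8, 8)
  onsets <- detect_ppg_onsets(ppg_f, fs)
  truth_feet <- attr(rec, "truth")$foot_times_s
  err_ms <- vapply(onsets, function(o) min(abs(o - truth_feet)) * 1000,
                   numeric(1))
  expect_gt(length(onsets), 10)
  expect_true(all(err_ms <= 10))
})

test_that("segmentation windows are fixed-length with truncated windows dropped", {
  x <- rnorm(20 * fs)
  # 20 onsets, the last 300 ms before the end: its forward window is dropped
  onsets <- seq(0.5, by = 1.01, length.out = 20)
  onsets[20] <- 20 - 0.3
  segs <- segment_scg(x, onsets, fs, window_ms = 450)
  expect_length(segs, 19)
  expect_true(all(lengths(segs) == 225))

  # backward windows drop onsets within the first 450 ms instead
  onsets_b <- c(0.2, seq(0.5, by = 1.01, length.out = 19))
  segs_b <- segment_scg(x, onsets_b, fs, window_ms = 450,
                        direction = "backward")
  expect_length(segs_b, 19)

  expect_error(segment_scg(x, numeric(0), fs), class = "pttbp_beats_error")
})

test_that("ensemble averaging is the pointwise mean", {
  seg <- sin(seq(0, 3, length.out = 225))
  same <- ensemble_average(list(seg, seg, seg), fs)
  expect_equal(same$waveform, seg)
  expect_equal(same$n_beats, 3)
  cancel <- ensemble_average(list(seg, -seg), fs)
  expect_equal(cancel$waveform, rep(0, 225))
  expect_error(ensemble_average(list(seg, seg[-1]), fs),
               class = "pttbp_contract_error")
})

test_that("ensemble RMS error shrinks like 1/sqrt(n)", {
  template <- sin(seq(0, 3, length.out = 225))
  rms_at <- function(n, seed) {
    withr::with_seed(seed, {
      segs <- lapply(seq_len(n), function(i) template + rnorm(225, sd = 1))
    })
    ens <- ensemble_average(segs, fs)
    sqrt(mean((ens$waveform - template)^2))
  }
  ratios <- vapply(1:20, function(s) rms_at(4, s) / rms_at(64, s * 100),
                   numeric(1))
  # expected ratio sqrt(64/4) = 4
  expect_equal(mean(ratios), 4, tolerance = 0.35)
})

test_that("AO detection finds the burst peak and rejects empty windows", {
  tt <- seq(0, 0.45 - 1 / fs, by = 1 / fs)
  burst <- exp(-(tt - 0.26)^2 / (2 * 0.01^2)) * cos(2 * pi * 20 * (tt - 0.26))
  ens <- ensemble_average(list(burst), fs)
  off <- detect_ao(ens)
  expect_equal(off, 260, tolerance = 2)

  zero <- ensemble_average(list(rep(0, length(tt))), fs)
  expect_true(is.na(detect_ao(zero)))
  expect_true(attr(detect_ao(zero), "rejected"))
})

test_that("PTT is recovered end-to-end on noiseless recordings", {
  for (case in list(c(60, 200), c(75, 250))) {
    rec <- synth_beat_train(beat_train_spec(heart_rate_bpm = case[1],
                                            true_ptt_ms = case[2], seed = 4))
    est <- compute_ptt(rec)
    expect_equal(est$quality, "ok")
    expect_equal(est$ptt_ms, case[2], tolerance = 4)
    expect_equal(est$ptt_beat_median_ms, case[2], tolerance = 4)
    expect_gte(est$n_beats_used, 5)
  }
  short <- synth_beat_train(beat_train_spec(duration_s = 5, seed = 1))
  expect_error(compute_ptt(short), class = "pttbp_input_error")
})

test_that("PTT survives baseline wander through the high-pass edge", {
  rec <- synth_beat_train(beat_train_spec(true_ptt_ms = 220, seed = 6,
                                          ppg_wander_amp = 0.5))
  est <- compute_ptt(rec)
  expect_equal(est$ptt_ms, 220, tolerance = 4)
})

test_that("recordings at another rate are resampled to the analysis rate", {
  rec <- synth_beat_train(beat_train_spec(fs_hz = 250, true_ptt_ms = 240,
                                          seed = 8))
  est <- compute_ptt(rec)  # default config resamples 250 -> 500 Hz
  expect_equal(est$ptt_ms, 240, tolerance = 8)
})

test_that("flat recordings are rejected rather than producing a PTT", {
  flat <- as_ptt_recording(
    tibble::tibble(t = (0:(12 * fs - 1)) / fs,
                   scg = 0, ppg = 0), fs_hz = fs)
  est <- compute_ptt(flat)
  expect_equal(est$quality, "rejected")
  expect_true(is.na(est$ptt_ms))
})

test_that("ensemble averaging tightens the AO estimate across realizations", {
  res <- lapply(1:15, function(s) {
    rec <- synth_beat_train(beat_train_spec(true_ptt_ms = 210, seed = s,
                                            scg_snr_db = 5, ppg_snr_db = 10))
    compute_ptt(rec)
  })
  ens_sd <- stats::sd(vapply(res, function(e) e$ptt_ms, numeric(1)))
  beat_sd <- mean(vapply(res, function(e) stats::sd(e$per_beat_ptt_ms),
                         numeric(1)), na.rm = TRUE)
  expect_gte(beat_sd, ens_sd)
})
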