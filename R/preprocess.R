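#' Zero-phase IIR band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' giving zero phase shift — fiducial timing is not displaced by filtering.
#' DC is removed and the passband gain is ~1.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate in Hz.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs_hz/2`.
#' @param order Butterworth prototype order (default 4). The band-pass
#'   realization doubles it, and forward-backward application squares the
#'   magnitude response.
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 500
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 20 * t)
#' y <- bandpass_iir(x, fs, 5, 45)  # 20 Hz is in the SCG passband
#' @export
bandpass_iir <- function(x, fs_hz, low_hz, high_hz, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2)) {
    abort("band edges must satisfy 0 < low_hz < high_hz < fs_hz/2",
          class = "pttbp_config_error")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  x <- as.numeric(x)
  n <- length(x)
  mu <- mean(x)
  # odd-reflection padding keeps filtfilt's edge transients out of the
  # signal proper; pad length covers ~3 periods of the low band edge
  pad <- min(n - 1, max(50, round(3 * fs_hz / low_hz)))
  xc <- x - mu
  xp <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[(pad + 1):(pad + n)]
}

#' Detect PPG pulse onsets (feet)
#'
#' Finds systolic peaks on the band-pass-filtered PPG (local maxima above a
#' fraction of the global maximum, separated by at least the minimum RR
#' interval), then locates each pulse foot as the maximum of the second
#' derivative on the rising edge between the preceding trough and the peak
#' (earliest sample on ties).
#'
#' @param ppg_filtered Band-pass-filtered PPG signal.
#' @param fs_hz Sampling rate in Hz.
#' @param min_rr_s Minimum inter-onset interval, seconds.
#' @param peak_frac Fraction of the maximum amplitude a systolic peak must
#'   exceed.
#' @return Strictly increasing onset times in seconds (empty if none found).
#' @export
detect_ppg_onsets <- function(ppg_filtered, fs_hz, min_rr_s = 0.3,
                              peak_frac = 0.3) {
  x <- as.numeric(ppg_filtered)
  n <- length(x)
  if (n < 2 * fs_hz) abort("need at least 2 s of signal",
                           class = "pttbp_input_error")
  top <- max(x)
  if (!is.finite(top) || top <= 0 || stats::sd(x) == 0) return(numeric(0))
  pk <- pracma::findpeaks(x, minpeakheight = peak_frac * top,
                          minpeakdistance = max(1L, round(min_rr_s * fs_hz)))
  if (is.null(pk)) return(numeric(0))
  peaks <- sort(pk[, 2])

  d2 <- c(NA_real_, diff(x, differences = 2), NA_real_)
  onsets <- vapply(peaks, function(p) {
    lo <- max(2L, p - round(0.45 * fs_hz))
    seg <- lo:p
    trough <- seg[which.min(x[seg])]
    rise <- trough:p
    rise[which.max(d2[rise])]   # which.max returns the earliest tie
  }, integer(1))
  onsets <- sort(unique(onsets))
  (onsets - 1) / fs_hz
}

#' Segment an SCG around PPG onsets
#'
#' Cuts one fixed-length window per onset from the filtered SCG. With
#' `direction = "forward"` the window is `[onset, onset + window_ms)`; with
#' `"backward"` it is `[onset - window_ms, onset)`, ending at the anchoring
#' onset. Windows that do not fit inside the recording are dropped.
#'
#' @param scg_filtered Band-pass-filtered SCG signal.
#' @param onsets Onset times in seconds (from [detect_ppg_onsets()]).
#' @param fs_hz Sampling rate in Hz.
#' @param window_ms Window length in milliseconds (default 450).
#' @param direction `"forward"` or `"backward"` (see Details).
#' @return A list of numeric segments, each of length
#'   `round(window_ms/1000 * fs_hz)`, with attribute `onset_times_s` giving
#'   the anchoring onset of each retained segment.
#' @export
segment_scg <- function(scg_filtered, onsets, fs_hz, window_ms = 450,
                        direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  x <- as.numeric(scg_filtered)
  n <- length(x)
  wlen <- round(window_ms / 1000 * fs_hz)
  on_idx <- round(onsets * fs_hz) + 1L
  if (direction == "forward") {
    keep <- on_idx >= 1L & (on_idx + wlen - 1L) <= n
    starts <- on_idx[keep]
  } else {
    keep <- (on_idx - wlen) >= 1L & on_idx <= n
    starts <- on_idx[keep] - wlen
  }
  if (length(starts) == 0) {
    abort("insufficient beats: no complete segment fits the recording",
          class = "pttbp_beats_error")
  }
  segs <- lapply(starts, function(s) x[s:(s + wlen - 1L)])
  attr(segs, "onset_times_s") <- onsets[keep]
  segs
}

#' Ensemble-average SCG segments
#'
#' Pointwise mean of equal-length segments aligned on their anchoring PPG
#' onset; raises the SNR of the aortic-opening complex by ~sqrt(n) before
#' fiducial detection.
#'
#' @param segments List of equal-length numeric segments ([segment_scg()]).
#' @param fs_hz Sampling rate in Hz.
#' @param window_ms Window length in milliseconds (for bookkeeping).
#' @return A list of class `"ensemble_scg"` with `waveform`, `n_beats`,
#'   `fs_hz`, `window_ms`.
#' @export
ensemble_average <- function(segments, fs_hz, window_ms = 450) {
  if (length(segments) < 1) abort("need at least one segment",
                                  class = "pttbp_beats_error")
  lens <- lengths(segments)
  if (length(unique(lens)) != 1) {
    abort("segments must all have the same length",
          class = "pttbp_contract_error")
  }
  waveform <- rowMeans(do.call(cbind, segments))
  structure(list(waveform = waveform, n_beats = length(segments),
                 fs_hz = fs_hz, window_ms = window_ms),
            class = "ensemble_scg")
}

#' Detect the aortic-opening fiducial in an ensemble-averaged SCG
#'
#' Deterministic AO detector: the largest positive peak of the ensemble
#' waveform within a search region (largest offset on ties, i.e. the burst
#' closest to the anchoring onset). The detection is rejected when the peak
#' does not rise above the noise floor, defined as `snr_factor` times the
#' median absolute ensemble amplitude.
#'
#' @param ensemble An `"ensemble_scg"` from [ensemble_average()].
#' @param search_ms Length-2 numeric, search region `[lo, hi)` in ms relative
#'   to the window start; defaults to the whole window except the 40 ms
#'   adjacent to the anchoring onset.
#' @param snr_factor Rejection threshold multiple (default 3).
#' @return Offset of the AO peak in milliseconds relative to the window
#'   start, or `NA_real_` (with attribute `rejected = TRUE`) when rejected.
#' @export
detect_ao <- function(ensemble, search_ms = NULL, snr_factor = 3) {
  stopifnot(inherits(ensemble, "ensemble_scg"))
  w <- ensemble$waveform
  fs <- ensemble$fs_hz
  if (is.null(search_ms)) search_ms <- c(0, ensemble$window_ms - 40)
  off_ms <- (seq_along(w) - 1) / fs * 1000
  cand <- which(off_ms >= search_ms[1] & off_ms < search_ms[2])
  rejected <- structure(NA_real_, rejected = TRUE)
  if (length(cand) == 0) return(rejected)
  floor_amp <- median(abs(w))
  peak_val <- max(w[cand])
  if (!is.finite(peak_val) || peak_val <= 0 ||
      peak_val < snr_factor * floor_amp) {
    return(rejected)
  }
  at_max <- cand[w[cand] >= peak_val - 1e-12 * max(1, abs(peak_val))]
  off_ms[max(at_max)]
}

#' Extract pulse transit time from a two-channel recording
#'
#' Runs the full device signal chain: zero-phase band-pass filtering of both
#' channels, PPG onset detection, PPG-onset-anchored SCG segmentation,
#' ensemble averaging, and aortic-opening detection. With the default
#' backward-anchored window `[onset - window_ms, onset)`, the AO that
#' precedes each onset by PTT sits at offset `window_ms - PTT`, so
#' `PTT = window_ms - AO offset`. Per-beat PTTs from per-segment AO
#' detection are reported for quality assessment.
#'
#' @param recording A `"ptt_recording"` (or data frame with `t`, `scg`,
#'   `ppg`); at least 10 s long. Recordings at a rate other than
#'   `config$analysis_fs_hz` are polyphase-resampled to it first.
#' @param config A [pipeline_config()].
#' @return A list of class `"ptt_estimate"`: `ptt_ms` (ensemble estimate),
#'   `per_beat_ptt_ms`, `ptt_beat_median_ms`, `n_beats_used`, `rr_median_s`,
#'   and `quality` (`"ok"`, `"low_beats"` or `"rejected"`).
#' @examples
#' rec <- synth_beat_train(beat_train_spec(heart_rate_bpm = 60,
#'                                         true_ptt_ms = 200, seed = 1))
#' est <- compute_ptt(rec)
#' est$ptt_ms
#' @export
compute_ptt <- function(recording, config = pipeline_config()) {
  rec <- as_ptt_recording(recording)
  fs <- attr(rec, "fs_hz")
  if (nrow(rec) / fs < 10) {
    abort("recording must be at least 10 s long", class = "pttbp_input_error")
  }
  if (abs(fs - config$analysis_fs_hz) > 1e-9) {
    rec <- resample_recording(rec, config$analysis_fs_hz)
    fs <- config$analysis_fs_hz
  }

  scg_f <- bandpass_iir(rec$scg, fs, config$scg_band_hz[1],
                        config$scg_band_hz[2], config$filter_order)
  ppg_f <- bandpass_iir(rec$ppg, fs, config$ppg_band_hz[1],
                        config$ppg_band_hz[2], config$filter_order)

  onsets <- detect_ppg_onsets(ppg_f, fs, min_rr_s = config$min_rr_s,
                              peak_frac = config$onset_peak_frac)
  rejected <- function() {
    structure(list(ptt_ms = NA_real_, per_beat_ptt_ms = numeric(0),
                   ptt_beat_median_ms = NA_real_, n_beats_used = 0L,
                   rr_median_s = NA_real_, quality = "rejected"),
              class = "ptt_estimate")
  }
  if (length(onsets) < 2) return(rejected())
  rr <- diff(onsets)
  rr <- rr[rr >= config$min_rr_s & rr <= config$max_rr_s]
  if (length(rr) == 0) return(rejected())

  segs <- tryCatch(
    segment_scg(scg_f, onsets, fs, config$window_ms,
                direction = config$window_direction),
    pttbp_beats_error = function(e) NULL
  )
  if (is.null(segs)) return(rejected())
  ens <- ensemble_average(segs, fs, config$window_ms)

  offset_to_ptt <- function(off_ms) {
    if (config$window_direction == "backward") config$window_ms - off_ms
    else median(rr) * 1000 - off_ms
  }
  # search region expressed as AO offsets implied by the physiologic PTT range
  search_ms <-
    if (config$window_direction == "backward") {
      c(max(0, config$window_ms - config$ptt_range_ms[2]),
        config$window_ms - config$ptt_range_ms[1])
    } else {
      c(0, config$window_ms - 40)
    }
  ao_off <- detect_ao(ens, search_ms = search_ms,
                      snr_factor = config$ao_snr_factor)
  if (is.na(ao_off)) return(rejected())
  ptt_ms <- offset_to_ptt(ao_off)

  per_beat <- vapply(segs, function(s) {
    one <- structure(list(waveform = s, n_beats = 1L, fs_hz = fs,
                          window_ms = config$window_ms),
                     class = "ensemble_scg")
    off <- detect_ao(one, search_ms = search_ms,
                     snr_factor = config$ao_snr_factor)
    if (is.na(off)) NA_real_ else offset_to_ptt(off)
  }, numeric(1))
  per_beat <- per_beat[!is.na(per_beat)]

  structure(list(
    ptt_ms = ptt_ms,
    per_beat_ptt_ms = per_beat,
    ptt_beat_median_ms = if (length(per_beat)) median(per_beat) else NA_real_,
    n_beats_used = length(segs),
    rr_median_s = median(rr),
    quality = if (length(segs) < config$min_beats) "low_beats" else "ok"
  ), class = "ptt_estimate")
}

# polyphase-style resampling of both channels onto a new uniform grid
resample_recording <- function(rec, new_fs) {
  fs <- attr(rec, "fs_hz")
  p_q <- ratio_approx(new_fs / fs)
  scg <- signal::resample(rec$scg, p = p_q[1], q = p_q[2])
  ppg <- signal::resample(rec$ppg, p = p_q[1], q = p_q[2])
  n <- min(length(scg), length(ppg))
  new_ptt_recording(
    tibble(t = (seq_len(n) - 1) / new_fs, scg = scg[seq_len(n)],
           ppg = ppg[seq_len(n)]),
    fs_hz = new_fs, truth = attr(rec, "truth")
  )
}

# small rational approximation for resampling ratios
ratio_approx <- function(x, max_den = 1000) {
  best <- c(1L, 1L)
  err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) {
      best <- c(p, q)
      err <- e
    }
    if (err < 1e-12) break
  }
  best
}

#' @export
print.ptt_estimate <- function(x, ...) {
  cat(sprintf("<ptt_estimate> ptt = %s ms (%d beats, quality = %s)\n",
              format(x$ptt_ms, digits = 4), x$n_beats_used, x$quality))
  invisible(x)
}

#' @rdname compute_ptt
#' @param x A `"ptt_estimate"`.
#' @param ... Unused.
#' @export
tidy.ptt_estimate <- function(x, ...) {
  tibble(ptt_ms = x$ptt_ms,
         ptt_beat_median_ms = x$ptt_beat_median_ms,
         n_beats_used = x$n_beats_used,
         rr_median_s = x$rr_median_s,
         quality = x$quality)
}
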