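#' Specification of a synthetic two-channel beat train
#'
#' Describes a 20-second (by default) SCG/PPG recording in which every cardiac
#' cycle produces a high-frequency SCG burst marking aortic valve opening (AO)
#' followed, exactly `true_ptt_ms` later, by the foot of a PPG upstroke. The
#' generator places both fiducials on the sample grid, so ground truth is
#' known to sample resolution and every downstream stage can be tested
#' without real data.
#'
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate in Hz (both channels share one grid).
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param true_ptt_ms Ground-truth pulse transit time (AO to PPG foot), ms.
#'   Must be shorter than one cardiac cycle.
#' @param scg_snr_db,ppg_snr_db Per-channel signal-to-noise ratio of the
#'   additive white Gaussian noise, in dB. `Inf` means noiseless.
#' @param rr_jitter_pct Multiplicative Gaussian jitter on each RR interval,
#'   as a percentage of the mean RR.
#' @param ppg_wander_amp Amplitude of an optional 0.2-Hz baseline-wander
#'   sinusoid added to the PPG channel (same units as the pulse, whose peak
#'   amplitude is ~0.54); 0 disables it.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#'
#' @return A list of class `"beat_train_spec"`.
#' @examples
#' beat_train_spec(heart_rate_bpm = 72, true_ptt_ms = 230, seed = 1)
#' @export
beat_train_spec <- function(duration_s = 20,
                            fs_hz = 500,
                            heart_rate_bpm = 60,
                            true_ptt_ms = 200,
                            scg_snr_db = Inf,
                            ppg_snr_db = Inf,
                            rr_jitter_pct = 2,
                            ppg_wander_amp = 0,
                            seed = 1L) {
  check_field <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("invalid `%s`: %s", field, msg),
                           class = "pttbp_spec_error")
  }
  check_field(is.numeric(duration_s) && duration_s > 0,
              "duration_s", "must be > 0")
  check_field(is.numeric(fs_hz) && fs_hz >= 100,
              "fs_hz", "must be >= 100 Hz")
  check_field(is.numeric(heart_rate_bpm) &&
                heart_rate_bpm >= 30 && heart_rate_bpm <= 200,
              "heart_rate_bpm", "must be in [30, 200] bpm")
  check_field(is.numeric(true_ptt_ms) && true_ptt_ms > 0 &&
                true_ptt_ms < 60000 / heart_rate_bpm,
              "true_ptt_ms", "must be positive and shorter than one beat")
  check_field(is.numeric(scg_snr_db), "scg_snr_db", "must be numeric")
  check_field(is.numeric(ppg_snr_db), "ppg_snr_db", "must be numeric")
  check_field(is.numeric(rr_jitter_pct) && rr_jitter_pct >= 0,
              "rr_jitter_pct", "must be >= 0")
  check_field(is.numeric(ppg_wander_amp) && ppg_wander_amp >= 0,
              "ppg_wander_amp", "must be >= 0")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 heart_rate_bpm = heart_rate_bpm, true_ptt_ms = true_ptt_ms,
                 scg_snr_db = scg_snr_db, ppg_snr_db = ppg_snr_db,
                 rr_jitter_pct = rr_jitter_pct,
                 ppg_wander_amp = ppg_wander_amp,
                 seed = as.integer(seed)),
            class = "beat_train_spec")
}

# SCG morphology: Gabor-like burst (Gaussian-windowed 20-Hz cosine, ~60 ms
# support). Its maximum positive excursion is exactly at the AO time, and its
# energy sits inside the 5-45 Hz analysis band so filtering preserves the peak.
scg_burst <- function(u, sigma = 0.010, f0 = 20) {
  exp(-u^2 / (2 * sigma^2)) * cos(2 * pi * f0 * u)
}

# PPG morphology: gamma-shaped pulse, zero before its foot, fast ~100 ms rise
# (peak at 2b = 100 ms) and slow decay; fundamental below 8 Hz for any
# physiological heart rate.
ppg_pulse <- function(u, b = 0.05) {
  y <- (u / b)^2 * exp(-u / b)
  y[u < 0] <- 0
  y
}

#' Generate a synthetic SCG/PPG recording
#'
#' Realizes a [beat_train_spec()]: beat times are laid down with the requested
#' rate and RR jitter, an SCG aortic-opening burst is placed at each beat, a
#' PPG pulse foot follows each burst after exactly the ground-truth PTT
#' (snapped to the sample grid), and white Gaussian noise is added per channel
#' at the requested SNR.
#'
#' @param spec A [beat_train_spec()].
#' @return A tibble of class `"ptt_recording"` with columns `t` (seconds),
#'   `scg` and `ppg`, and attributes `fs_hz` and `truth` (a list with the
#'   ground-truth AO times, PPG foot times, `true_ptt_ms` and the spec).
#' @examples
#' rec <- synth_beat_train(beat_train_spec(seed = 1))
#' nrow(rec)                       # duration_s * fs_hz samples
#' length(attr(rec, "truth")$ao_times_s)
#' @export
synth_beat_train <- function(spec) {
  if (!inherits(spec, "beat_train_spec")) {
    spec <- do.call(beat_train_spec, as.list(spec))
  }
  fs <- spec$fs_hz
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  rr0 <- 60 / spec$heart_rate_bpm

  withr::with_seed(spec$seed, {
    # beat times: first AO leaves room for one full analysis window before
    # the first PPG onset; subsequent RR intervals carry multiplicative jitter
    ao_t <- 0.5
    ao_times <- numeric(0)
    while (ao_t < spec$duration_s - 0.02) {
      ao_times <- c(ao_times, ao_t)
      ao_t <- ao_t + rr0 * max(0.5, 1 + spec$rr_jitter_pct / 100 * rnorm(1))
    }
    ao_idx <- round(ao_times * fs) + 1L
    ao_idx <- ao_idx[ao_idx >= 1 & ao_idx <= n]
    foot_idx <- ao_idx + round(spec$true_ptt_ms / 1000 * fs)

    scg <- numeric(n)
    ppg <- numeric(n)
    for (i in ao_idx) scg <- scg + scg_burst(t - t[i])
    for (i in foot_idx[foot_idx <= n]) ppg <- ppg + ppg_pulse(t - t[i])
    if (spec$ppg_wander_amp > 0) {
      ppg <- ppg + spec$ppg_wander_amp * sin(2 * pi * 0.2 * t)
    }

    add_noise <- function(x, snr_db) {
      if (is.infinite(snr_db)) return(x)
      x + rnorm(length(x), sd = sqrt(var(x) / 10^(snr_db / 10)))
    }
    scg <- add_noise(scg, spec$scg_snr_db)
    ppg <- add_noise(ppg, spec$ppg_snr_db)
  })

  new_ptt_recording(
    tibble(t = t, scg = scg, ppg = ppg), fs_hz = fs,
    truth = list(ao_times_s = t[ao_idx],
                 foot_times_s = t[foot_idx[foot_idx <= n]],
                 true_ptt_ms = spec$true_ptt_ms,
                 spec = spec)
  )
}

new_ptt_recording <- function(df, fs_hz, truth = NULL) {
  structure(df, fs_hz = fs_hz, truth = truth,
            class = c("ptt_recording", class(tibble())))
}

#' Coerce a data frame to a PTT recording
#'
#' @param x A data frame with columns `t`, `scg`, `ppg` on a uniform time grid.
#' @param fs_hz Sampling rate; if omitted it is inferred from the grid spacing.
#' @return A `"ptt_recording"` tibble.
#' @export
as_ptt_recording <- function(x, fs_hz = NULL) {
  stopifnot(all(c("t", "scg", "ppg") %in% names(x)))
  dt <- diff(x$t)
  if (is.null(fs_hz)) fs_hz <- 1 / median(dt)
  if (max(abs(dt - 1 / fs_hz)) > 1e-9 * max(1, 1 / fs_hz)) {
    abort("`t` is not a uniform grid at `fs_hz`", class = "pttbp_input_error")
  }
  new_ptt_recording(as_tibble(x[c("t", "scg", "ppg")]), fs_hz = fs_hz,
                    truth = attr(x, "truth"))
}

#' Ground-truth PTT implied by a blood pressure, under a subject's law
#'
#' Inverts the Bramwell-Hill pulse-pressure relation
#' `PP = PP0 * (PTT0/PTT)^2` to obtain the transit time a subject with
#' operating point `(ptt0_ms, sbp0, dbp0)` would exhibit at the requested
#' pressures: `PTT = PTT0 * sqrt(PP0 / (sbp - dbp))`. Used as the generator's
#' ground truth so that calibrate-then-estimate round trips can be tested.
#'
#' @param profile A [subject_profile()].
#' @param sbp,dbp Requested systolic/diastolic pressure, mm Hg (vectorized).
#' @return PTT in milliseconds.
#' @examples
#' pr <- subject_profile(sbp0 = 120, dbp0 = 80, ptt0_ms = 250)
#' bp_to_ptt(pr, 120, 80)          # at the operating point: 250 ms
#' bp_to_ptt(pr, 142.5, 80)        # PP = 62.5: 200 ms
#' @export
bp_to_ptt <- function(profile, sbp, dbp) {
  if (any(sbp <= dbp)) {
    abort("`sbp` must exceed `dbp`", class = "pttbp_domain_error")
  }
  pp0 <- profile$sbp0 - profile$dbp0
  profile$ptt0_ms * sqrt(pp0 / (sbp - dbp))
}

#' Synthetic subject profile
#'
#' Ground-truth description of one subject for end-to-end simulation: a
#' baseline blood pressure and transit time tied together by the
#' Bramwell-Hill/Moens-Korteweg law with subject constant `gamma_true`, plus
#' an optional between-session blood-pressure drift model.
#'
#' @param age_years Age in years (drives the age-banded default gamma).
#' @param sbp0,dbp0 Baseline systolic/diastolic pressure, mm Hg.
#' @param gamma_true Subject's true Moens-Korteweg constant (dimensionless).
#' @param ptt0_ms Transit time at the baseline pressure, ms.
#' @param heart_rate_bpm Subject heart rate used for generated recordings.
#' @param bp_drift Between-session drift of the true blood pressure:
#'   `"none"`, `"linear"` (cumulative `drift_mag` mm Hg per session on SBP,
#'   half that on DBP) or `"random_walk"` (Gaussian steps with SD
#'   `drift_mag`).
#' @param drift_mag Drift magnitude per session, mm Hg.
#' @return A list of class `"subject_profile"`.
#' @export
subject_profile <- function(age_years = 35,
                            sbp0 = 120, dbp0 = 80,
                            gamma_true = 0.05,
                            ptt0_ms = 250,
                            heart_rate_bpm = 70,
                            bp_drift = c("none", "linear", "random_walk"),
                            drift_mag = 0) {
  bp_drift <- match.arg(bp_drift)
  stopifnot(age_years > 0, sbp0 > dbp0, dbp0 > 0, ptt0_ms > 0,
            gamma_true >= 0, drift_mag >= 0)
  structure(list(age_years = age_years, sbp0 = sbp0, dbp0 = dbp0,
                 gamma_true = gamma_true, ptt0_ms = ptt0_ms,
                 heart_rate_bpm = heart_rate_bpm,
                 bp_drift = bp_drift, drift_mag = drift_mag),
            class = "subject_profile")
}

#' Simulate a whole subject: calibration plus measurement sessions
#'
#' Mirrors the validation-study protocol: each subject undergoes `n_cal`
#' calibration sessions followed by `n_meas` measurement sessions (3 + 3 by
#' default, matching the 3 calibrations and 3 measurements per participant of
#' an AAMI/ESH/ISO-style study). Each session has a true blood pressure
#' (drifting per the profile), the transit time it implies through
#' [bp_to_ptt()], and a synthetic recording embedding that PTT.
#'
#' @param profile A [subject_profile()].
#' @param n_cal Number of calibration sessions (at least 3).
#' @param n_meas Number of measurement sessions (at least 1).
#' @param seed Integer seed controlling drift, jitter and noise.
#' @param duration_s,fs_hz,scg_snr_db,ppg_snr_db,rr_jitter_pct Recording
#'   parameters passed to [beat_train_spec()] for every session.
#' @return A tibble with one row per session: `session`, `role`
#'   (`"calibration"`/`"measurement"`), `true_sbp`, `true_dbp`,
#'   `true_ptt_ms`, and a `recording` list-column of `"ptt_recording"`s.
#' @examples
#' ds <- synth_subject_dataset(subject_profile(), seed = 7)
#' ds[, c("session", "role", "true_sbp", "true_ptt_ms")]
#' @export
synth_subject_dataset <- function(profile, n_cal = 3, n_meas = 3, seed = 1L,
                                  duration_s = 20, fs_hz = 500,
                                  scg_snr_db = Inf, ppg_snr_db = Inf,
                                  rr_jitter_pct = 2) {
  stopifnot(inherits(profile, "subject_profile"))
  if (n_cal < 3) abort("`n_cal` must be >= 3 (three-session calibration)",
                       class = "pttbp_protocol_error")
  if (n_meas < 1) abort("`n_meas` must be >= 1", class = "pttbp_protocol_error")
  n_sess <- n_cal + n_meas
  seed <- as.integer(seed)

  bp <- withr::with_seed(seed, {
    sbp <- rep(profile$sbp0, n_sess)
    dbp <- rep(profile$dbp0, n_sess)
    if (profile$bp_drift == "linear") {
      step <- (seq_len(n_sess) - 1) * profile$drift_mag
      sbp <- sbp + step
      dbp <- dbp + step / 2
    } else if (profile$bp_drift == "random_walk") {
      sbp <- sbp + cumsum(c(0, rnorm(n_sess - 1, sd = profile$drift_mag)))
      dbp <- dbp + cumsum(c(0, rnorm(n_sess - 1, sd = profile$drift_mag / 2)))
    }
    list(sbp = sbp, dbp = pmin(dbp, sbp - 10))
  })

  ptt <- bp_to_ptt(profile, bp$sbp, bp$dbp)
  recs <- purrr::map(seq_len(n_sess), function(i) {
    synth_beat_train(beat_train_spec(
      duration_s = duration_s, fs_hz = fs_hz,
      heart_rate_bpm = profile$heart_rate_bpm,
      true_ptt_ms = ptt[i],
      scg_snr_db = scg_snr_db, ppg_snr_db = ppg_snr_db,
      rr_jitter_pct = rr_jitter_pct,
      seed = (seed * 1009L + i * 101L) %% 2147483647L
    ))
  })

  tibble(
    session = seq_len(n_sess),
    role = rep(c("calibration", "measurement"), c(n_cal, n_meas)),
    true_sbp = bp$sbp, true_dbp = bp$dbp, true_ptt_ms = ptt,
    recording = recs
  )
}
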