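#' Pipeline configuration
#'
#' Collects every tunable parameter of the PTT extraction and blood-pressure
#' estimation pipeline in one serializable object. Defaults reproduce the
#' published device description: 20-s acquisitions, a zero-phase IIR band-pass
#' of 5--45 Hz for the seismocardiogram (SCG) and 0.8--8 Hz for the
#' photoplethysmogram (PPG), 450-ms PPG-onset-anchored segmentation with
#' ensemble averaging, and age-banded defaults for the Moens-Korteweg
#' constant gamma (0.031 below 40 years, 0.09 at or above).
#'
#' @param analysis_fs_hz Common analysis sampling rate in Hz. Channels at a
#'   different rate are resampled to this grid before processing.
#' @param scg_band_hz Length-2 numeric, SCG band-pass edges in Hz.
#' @param ppg_band_hz Length-2 numeric, PPG band-pass edges in Hz.
#' @param filter_order Butterworth prototype order (applied forward-backward,
#'   so the effective magnitude response is squared).
#' @param window_ms Ensemble segmentation window length in milliseconds.
#' @param window_direction Direction of the segmentation window relative to
#'   each PPG onset: `"backward"` (window ends at the onset, so it contains
#'   the aortic opening that precedes that onset by PTT) or `"forward"`.
#'   See `vignette("pttbp-methods")` for why `"backward"` is the default.
#' @param ptt_range_ms Physiologic PTT search range in milliseconds; the
#'   aortic-opening search region within each window is derived from it. Its
#'   lower bound also acts as the exclusion zone next to the anchoring onset.
#' @param min_beats Minimum number of complete beats for an estimate of
#'   quality `"ok"`; fewer beats flag the estimate `"low_beats"`.
#' @param min_rr_s,max_rr_s Physiologic bounds on the inter-onset interval in
#'   seconds; detected onsets closer than `min_rr_s` are suppressed.
#' @param onset_peak_frac Fraction of the maximum filtered-PPG amplitude a
#'   systolic peak must exceed to seed onset detection.
#' @param ao_snr_factor Rejection rule for aortic-opening detection: the peak
#'   must exceed this multiple of the median absolute ensemble amplitude.
#' @param gamma_young,gamma_old Age-banded defaults for gamma.
#' @param gamma_age_cut Age (years) at which `gamma_old` applies; the
#'   boundary age itself uses `gamma_old`.
#' @param gamma_max Upper clamp for the calibrated gamma; values outside
#'   `[0, gamma_max]` indicate calibration failure, not physiology.
#' @param gamma_r_tol Singularity guard: if the third-calibration PTT ratio
#'   satisfies `|PTT0/PTT - 1| <` this tolerance, the gamma update is
#'   ill-posed and the age default is kept.
#' @param band_thresholds_mmhg Absolute-difference band thresholds in mm Hg.
#' @param bland_altman_k Multiple of the SD defining the limits of agreement.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `"pttbp_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$scg_band_hz
#' @export
pipeline_config <- function(analysis_fs_hz = 500,
                            scg_band_hz = c(5, 45),
                            ppg_band_hz = c(0.8, 8),
                            filter_order = 4,
                            window_ms = 450,
                            window_direction = c("backward", "forward"),
                            ptt_range_ms = c(60, 400),
                            min_beats = 5,
                            min_rr_s = 0.3,
                            max_rr_s = 2,
                            onset_peak_frac = 0.3,
                            ao_snr_factor = 3,
                            gamma_young = 0.031,
                            gamma_old = 0.09,
                            gamma_age_cut = 40,
                            gamma_max = 10,
                            gamma_r_tol = 1e-3,
                            band_thresholds_mmhg = c(5, 10, 15),
                            bland_altman_k = 2,
                            seed = NULL) {
  window_direction <- match.arg(window_direction)
  cfg <- list(
    analysis_fs_hz = analysis_fs_hz,
    scg_band_hz = scg_band_hz,
    ppg_band_hz = ppg_band_hz,
    filter_order = filter_order,
    window_ms = window_ms,
    window_direction = window_direction,
    ptt_range_ms = ptt_range_ms,
    min_beats = min_beats,
    min_rr_s = min_rr_s,
    max_rr_s = max_rr_s,
    onset_peak_frac = onset_peak_frac,
    ao_snr_factor = ao_snr_factor,
    gamma_young = gamma_young,
    gamma_old = gamma_old,
    gamma_age_cut = gamma_age_cut,
    gamma_max = gamma_max,
    gamma_r_tol = gamma_r_tol,
    band_thresholds_mmhg = band_thresholds_mmhg,
    bland_altman_k = bland_altman_k,
    seed = seed
  )
  stopifnot(
    analysis_fs_hz >= 100,
    length(scg_band_hz) == 2, scg_band_hz[1] > 0,
    scg_band_hz[1] < scg_band_hz[2], scg_band_hz[2] < analysis_fs_hz / 2,
    length(ppg_band_hz) == 2, ppg_band_hz[1] > 0,
    ppg_band_hz[1] < ppg_band_hz[2], ppg_band_hz[2] < analysis_fs_hz / 2,
    filter_order >= 1, window_ms > 0,
    ptt_range_ms[1] > 0, ptt_range_ms[1] < ptt_range_ms[2],
    band_thresholds_mmhg > 0, !is.unsorted(band_thresholds_mmhg),
    bland_altman_k > 0, gamma_max > 0
  )
  structure(cfg, class = "pttbp_config")
}

#' @export
print.pttbp_config <- function(x, ...) {
  cat("<pttbp_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}

#' Stable hash of a configuration
#'
#' Reports embed this hash so results can be traced to the exact parameter
#' set that produced them.
#'
#' @param config A [pipeline_config()] object.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # rolling polynomial hash over the canonical JSON; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(json)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
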