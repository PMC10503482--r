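#' Read and write recording CSV files
#'
#' Recordings are stored as plain CSV with header `t,scg,ppg`, one row per
#' sample, accompanied by a JSON sidecar (`<path>.json`) carrying the
#' sampling rate, the seed, and — for synthetic recordings — the ground
#' truth.
#'
#' @param rec A `"ptt_recording"`.
#' @param path CSV path.
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns a `"ptt_recording"`.
#' @export
write_recording_csv <- function(rec, path, sidecar = TRUE) {
  rec <- as_ptt_recording(rec)
  write.csv(as.data.frame(rec)[c("t", "scg", "ppg")], path, row.names = FALSE)
  if (sidecar) {
    truth <- attr(rec, "truth")
    meta <- list(fs_hz = attr(rec, "fs_hz"))
    if (!is.null(truth)) {
      meta$seed <- truth$spec$seed
      meta$truth <- list(ao_times_s = truth$ao_times_s,
                         foot_times_s = truth$foot_times_s,
                         true_ptt_ms = truth$true_ptt_ms)
    }
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  fs <- NULL
  truth <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- meta$fs_hz
    if (!is.null(meta$truth)) truth <- meta$truth
  }
  rec <- as_ptt_recording(df, fs_hz = fs)
  attr(rec, "truth") <- truth
  rec
}

#' Read and write calibration files and models
#'
#' Calibration sessions travel as CSV with columns `ptt_ms,sbp_ref,dbp_ref`
#' (3 rows, sessions in order); fitted models as JSON with fields `ptt0_ms`,
#' `pp0`, `mbp0`, `gamma` and flags.
#'
#' @param path File path.
#' @return `read_calibration_csv()` returns a tibble;
#'   `read_model_json()` returns a `"bp_calibration"`-like list usable by
#'   [estimate_bp()].
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  need <- c("ptt_ms", "sbp_ref", "dbp_ref")
  if (!all(need %in% names(df))) {
    abort("calibration CSV needs columns ptt_ms, sbp_ref, dbp_ref",
          class = "pttbp_input_error")
  }
  as_tibble(df[need])
}

#' @rdname read_calibration_csv
#' @param model A `"bp_calibration"` from [calibrate_bp()].
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(ptt0_ms = model$ptt0_ms, pp0 = model$pp0, mbp0 = model$mbp0,
         gamma = model$gamma, gamma_source = model$gamma_source,
         gamma_clamped = model$gamma_clamped, age_years = model$age_years),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_calibration_csv
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "bp_calibration")
}

#' Read a measurement-pairs CSV
#'
#' Expected columns: `participant_id`, `test_sbp`, `test_dbp`, `ref_sbp`,
#' `ref_dbp`, optionally `test_hr`, `ref_hr`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_pairs_csv <- function(path) {
  df <- read.csv(path)
  need <- c("test_sbp", "test_dbp", "ref_sbp", "ref_dbp")
  if (!all(need %in% names(df))) {
    abort("pairs CSV needs columns test_sbp, test_dbp, ref_sbp, ref_dbp",
          class = "pttbp_input_error")
  }
  as_tibble(df)
}

# flatten a bp_validation report into plain lists for JSON
report_to_list <- function(report) {
  list(
    n_pairs = report$n_pairs,
    config_hash = report$config_hash,
    seed = report$seed,
    results = lapply(report$results, function(r) {
      list(
        mean_diff = r$diff$mean_diff,
        sd_diff = r$diff$sd_diff,
        bands = lapply(seq_len(nrow(r$bands)), function(i) {
          list(threshold = r$bands$threshold[i], count = r$bands$count[i],
               pct = r$bands$pct[i])
        }),
        bland_altman = as.list(r$bland_altman$stats[
          c("mean_diff", "sd_diff", "k", "lower", "upper",
            "n_outside", "pct_outside")]),
        pearson = list(r = r$pearson$r, p = r$pearson$p),
        cv_mean_pct = if (!is.null(r$cv)) {
          list(test = attr(r$cv$test, "mean_cv_pct"),
               ref = attr(r$cv$ref, "mean_cv_pct"))
        },
        aami_pass = r$aami_pass
      )
    })
  )
}

#' Serialize a validation report to JSON
#'
#' @param report A `"bp_validation"` from [validate_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
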