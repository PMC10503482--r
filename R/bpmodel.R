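#' Mean blood pressure from systolic and diastolic pressure
#'
#' Standard one-third rule: `MBP = DBP + (SBP - DBP) / 3`.
#'
#' @param sbp,dbp Pressures in mm Hg (vectorized).
#' @return MBP in mm Hg.
#' @examples
#' mbp_from_sbp_dbp(120, 80)  # 93.33
#' @export
mbp_from_sbp_dbp <- function(sbp, dbp) {
  if (any(sbp <= dbp)) {
    abort("`sbp` must exceed `dbp`", class = "pttbp_domain_error")
  }
  dbp + (sbp - dbp) / 3
}

#' Age-banded default for the Moens-Korteweg constant gamma
#'
#' Before the third-calibration update, gamma is 0.031 for subjects younger
#' than 40 years and 0.09 otherwise (the boundary age 40 takes the older
#' band's value).
#'
#' @param age_years Age in years (vectorized).
#' @param young,old Band values.
#' @param age_cut Age at which the older band applies.
#' @return Gamma (dimensionless).
#' @export
default_gamma <- function(age_years, young = 0.031, old = 0.09, age_cut = 40) {
  stopifnot(all(age_years > 0))
  ifelse(age_years < age_cut, young, old)
}

#' Estimate blood pressure from pulse transit time
#'
#' Evaluates the Bramwell-Hill / Moens-Korteweg pair at `r = PTT0 / PTT`:
#' \deqn{DBP = MBP_0 + 2\gamma \ln r - \frac{PP_0}{3} r^2}
#' \deqn{SBP = DBP + PP_0 r^2}
#' At `PTT = PTT0` the model reproduces its calibration-mean pressures
#' exactly, and SBP is strictly decreasing in PTT for gamma >= 0.
#'
#' @param model A `"bp_calibration"` from [calibrate_bp()] (or any list with
#'   `ptt0_ms`, `pp0`, `mbp0`, `gamma`).
#' @param ptt_ms Pulse transit time(s) in milliseconds.
#' @return A tibble with columns `ptt_ms`, `sbp`, `dbp`, `pp`, `mbp`.
#' @examples
#' m <- list(ptt0_ms = 250, pp0 = 40, mbp0 = mbp_from_sbp_dbp(120, 80),
#'           gamma = 0.031)
#' estimate_bp(m, 250)   # reproduces 120/80
#' estimate_bp(m, 200)   # shorter transit time, higher pressure
#' @export
estimate_bp <- function(model, ptt_ms) {
  if (any(ptt_ms <= 0)) {
    abort("`ptt_ms` must be positive", class = "pttbp_domain_error")
  }
  r <- model$ptt0_ms / ptt_ms
  dbp <- model$mbp0 + 2 * model$gamma * log(r) - model$pp0 / 3 * r^2
  sbp <- dbp + model$pp0 * r^2
  tibble(ptt_ms = ptt_ms, sbp = sbp, dbp = dbp,
         pp = sbp - dbp, mbp = mbp_from_sbp_dbp(sbp, dbp))
}

#' Solve for gamma from the third calibration session
#'
#' Closed-form inversion of the diastolic equation at the third calibration
#' point: with `r = PTT0 / PTT3`,
#' `gamma = (DBP3 - MBP0 + (PP0/3) r^2) / (2 ln r)`. Near `r = 1` the
#' equation carries no information about gamma (`ln r = 0`); the fit is then
#' flagged singular and the caller should keep the age default. The result is
#' clamped to `[0, gamma_max]` — values outside indicate calibration failure
#' rather than physiology.
#'
#' @param dbp3 Reference DBP of the third calibration, mm Hg.
#' @param ptt3_ms Device PTT of the third calibration, ms.
#' @param ptt0_ms,pp0,mbp0 Operating-point parameters (from calibrations 1-2).
#' @param r_tol Singularity tolerance on `|r - 1|`.
#' @param gamma_max Upper clamp.
#' @return Gamma, with attributes `singular` and `clamped` (logicals).
#' @examples
#' # round trip: plant gamma, evaluate the forward model, invert
#' g <- 0.05; r <- 1.25
#' dbp3 <- 93.33 + 2 * g * log(r) - 40 / 3 * r^2
#' solve_gamma(dbp3, 250 / r, ptt0_ms = 250, pp0 = 40, mbp0 = 93.33)
#' @export
solve_gamma <- function(dbp3, ptt3_ms, ptt0_ms, pp0, mbp0,
                        r_tol = 1e-3, gamma_max = 10) {
  stopifnot(dbp3 > 0, ptt3_ms > 0, ptt0_ms > 0, pp0 > 0)
  r <- ptt0_ms / ptt3_ms
  if (abs(r - 1) < r_tol) {
    return(structure(NA_real_, singular = TRUE, clamped = FALSE))
  }
  g <- (dbp3 - mbp0 + pp0 / 3 * r^2) / (2 * log(r))
  clamped <- g < 0 || g > gamma_max
  structure(min(max(g, 0), gamma_max), singular = FALSE, clamped = clamped)
}

#' Three-session individual calibration
#'
#' Implements the device's calibration protocol. Each of the three sessions
#' pairs a device PTT with a simultaneous cuff reference SBP/DBP. Stages:
#' \enumerate{
#'   \item Provisional operating point: `PTT0'`, `PP0'`, `MBP0'` are the
#'     means over sessions 1-2.
#'   \item Gamma update: gamma is solved from session 3 against the
#'     provisional operating point ([solve_gamma()]), starting from the
#'     age-banded default; a singular solve keeps the default.
#'   \item Final model: `PTT0`, `PP0`, `MBP0` are the means over all three
#'     sessions, with the stage-2 gamma.
#' }
#'
#' @param records A data frame with exactly 3 rows and columns `ptt_ms`,
#'   `sbp_ref`, `dbp_ref` (sessions in order).
#' @param age_years Subject age, for the default gamma.
#' @param config A [pipeline_config()] supplying the gamma defaults, clamp
#'   and singularity tolerance.
#' @return A list of class `"bp_calibration"`: `ptt0_ms`, `pp0`, `mbp0`,
#'   `gamma`, `gamma_source` (`"calibration"` or `"age_default"`),
#'   `gamma_clamped`, `age_years`, plus the stage-1 provisional parameters.
#' @examples
#' recs <- data.frame(ptt_ms = c(252, 248, 230),
#'                    sbp_ref = c(121, 119, 124.9),
#'                    dbp_ref = c(81, 79, 77.6))
#' calibrate_bp(recs, age_years = 35)
#' @export
calibrate_bp <- function(records, age_years, config = pipeline_config()) {
  records <- as.data.frame(records)
  need <- c("ptt_ms", "sbp_ref", "dbp_ref")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns ptt_ms, sbp_ref, dbp_ref",
          class = "pttbp_protocol_error")
  }
  if (nrow(records) != 3) {
    abort("calibration requires exactly 3 records",
          class = "pttbp_protocol_error")
  }
  with(records, {
    if (any(ptt_ms <= 0) || any(dbp_ref <= 0) || any(sbp_ref <= dbp_ref)) {
      abort("calibration records must satisfy sbp_ref > dbp_ref > 0, ptt_ms > 0",
            class = "pttbp_protocol_error")
    }
  })
  pp <- records$sbp_ref - records$dbp_ref
  mbp <- mbp_from_sbp_dbp(records$sbp_ref, records$dbp_ref)

  # stage 1: provisional operating point from sessions 1-2
  ptt0_12 <- mean(records$ptt_ms[1:2])
  pp0_12 <- mean(pp[1:2])
  mbp0_12 <- mean(mbp[1:2])

  # stage 2: gamma from session 3
  g0 <- default_gamma(age_years, config$gamma_young, config$gamma_old,
                      config$gamma_age_cut)
  g <- solve_gamma(records$dbp_ref[3], records$ptt_ms[3],
                   ptt0_12, pp0_12, mbp0_12,
                   r_tol = config$gamma_r_tol, gamma_max = config$gamma_max)
  singular <- isTRUE(attr(g, "singular"))
  if (singular) {
    warn("gamma update is singular (PTT3 ~ PTT0'); keeping the age default")
  }
  gamma <- if (singular) g0 else as.numeric(g)

  # stage 3: final operating point from all three sessions
  structure(list(
    ptt0_ms = mean(records$ptt_ms),
    pp0 = mean(pp),
    mbp0 = mean(mbp),
    gamma = gamma,
    gamma_source = if (singular) "age_default" else "calibration",
    gamma_clamped = isTRUE(attr(g, "clamped")),
    age_years = age_years,
    stage1 = list(ptt0_ms = ptt0_12, pp0 = pp0_12, mbp0 = mbp0_12),
    records = as_tibble(records[need])
  ), class = "bp_calibration")
}

#' @export
print.bp_calibration <- function(x, ...) {
  cat("<bp_calibration>\n")
  cat(sprintf("  PTT0 = %.2f ms, PP0 = %.2f mm Hg, MBP0 = %.2f mm Hg\n",
              x$ptt0_ms, x$pp0, x$mbp0))
  cat(sprintf("  gamma = %.4g (%s%s)\n", x$gamma, x$gamma_source,
              if (x$gamma_clamped) ", clamped" else ""))
  invisible(x)
}

#' @rdname calibrate_bp
#' @param x A `"bp_calibration"`.
#' @param ... Unused.
#' @export
tidy.bp_calibration <- function(x, ...) {
  tibble(term = c("ptt0_ms", "pp0", "mbp0", "gamma"),
         estimate = c(x$ptt0_ms, x$pp0, x$mbp0, x$gamma))
}

#' @rdname calibrate_bp
#' @export
glance.bp_calibration <- function(x, ...) {
  tibble(ptt0_ms = x$ptt0_ms, pp0 = x$pp0, mbp0 = x$mbp0, gamma = x$gamma,
         gamma_source = x$gamma_source, gamma_clamped = x$gamma_clamped,
         age_years = x$age_years)
}
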