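quantity_cols <- function(pairs, quantity = c("sbp", "dbp", "hr")) {
  quantity <- match.arg(quantity)
  cols <- paste0(c("test_", "ref_"), quantity)
  if (!all(cols %in% names(pairs))) {
    abort(sprintf("`pairs` needs columns %s", paste(cols, collapse = ", ")),
          class = "pttbp_input_error")
  }
  list(test = pairs[[cols[1]]], ref = pairs[[cols[2]]], quantity = quantity)
}

# half-up rounding to `digits` decimals; base round() is half-even and does
# not reproduce published percentage tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Paired test-reference difference statistics
#'
#' Mean and sample SD (n-1 denominator) of test minus reference, the summary
#' in which device-validation studies express agreement.
#'
#' @param pairs Data frame of measurement pairs with columns
#'   `test_<quantity>` and `ref_<quantity>` (`sbp`, `dbp` or `hr`).
#' @param quantity `"sbp"`, `"dbp"` or `"hr"`.
#' @return A one-row tibble: `quantity`, `n`, `mean_diff`, `sd_diff`.
#' @examples
#' pairs <- tibble::tibble(test_sbp = c(121, 118), ref_sbp = c(120, 115))
#' diff_stats(pairs, "sbp")
#' @export
diff_stats <- function(pairs, quantity = c("sbp", "dbp", "hr")) {
  q <- quantity_cols(pairs, quantity)
  d <- q$test - q$ref
  if (length(d) < 2) abort("need at least 2 pairs", class = "pttbp_input_error")
  tibble(quantity = q$quantity, n = length(d),
         mean_diff = mean(d), sd_diff = sd(d))
}

#' Absolute-difference band percentages
#'
#' For each threshold, the count and percentage of pairs whose absolute
#' test-reference difference is strictly below it. Percentages are rounded
#' half-up to one decimal, matching how validation tables are printed.
#'
#' @inheritParams diff_stats
#' @param thresholds Positive ascending thresholds (mm Hg), default 5/10/15.
#' @return A tibble with one row per threshold: `threshold`, `count`, `pct`.
#' @examples
#' pairs <- tibble::tibble(test_sbp = c(120, 126, 131), ref_sbp = rep(120, 3))
#' band_percentages(pairs, "sbp")
#' @export
band_percentages <- function(pairs, quantity = c("sbp", "dbp", "hr"),
                             thresholds = c(5, 10, 15)) {
  q <- quantity_cols(pairs, quantity)
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  d <- abs(q$test - q$ref)
  n <- length(d)
  if (n == 0) abort("`pairs` is empty", class = "pttbp_input_error")
  counts <- vapply(thresholds, function(th) sum(d < th), integer(1))
  tibble(quantity = q$quantity, threshold = thresholds, n = n,
         count = counts, pct = round_half_up(100 * counts / n, 1))
}

#' Bland-Altman agreement analysis
#'
#' Limits of agreement `mean_diff +/- k * sd_diff` (k = 2 by default) with
#' the count and percentage of pairs strictly outside them, plus the
#' (average, difference) points for plotting.
#'
#' @inheritParams diff_stats
#' @param k Multiple of the SD defining the limits.
#' @return A list of class `"bland_altman"`: `stats` (one-row tibble with
#'   `mean_diff`, `sd_diff`, `lower`, `upper`, `n`, `n_outside`,
#'   `pct_outside`) and `points` (tibble `avg`, `diff`, `outside`).
#' @examples
#' pairs <- tibble::tibble(test_sbp = rnorm(50, 120, 5),
#'                         ref_sbp = rnorm(50, 120, 5))
#' bland_altman(pairs, "sbp")$stats
#' @export
bland_altman <- function(pairs, quantity = c("sbp", "dbp", "hr"), k = 2) {
  q <- quantity_cols(pairs, quantity)
  d <- q$test - q$ref
  if (length(d) < 2) abort("need at least 2 pairs", class = "pttbp_input_error")
  m <- mean(d)
  s <- sd(d)
  lower <- m - k * s
  upper <- m + k * s
  outside <- d < lower | d > upper
  structure(list(
    stats = tibble(quantity = q$quantity, n = length(d), mean_diff = m,
                   sd_diff = s, k = k, lower = lower, upper = upper,
                   n_outside = sum(outside),
                   pct_outside = round_half_up(100 * mean(outside), 1)),
    points = tibble(avg = (q$test + q$ref) / 2, diff = d, outside = outside)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<bland_altman> %s: mean %.2f, SD %.2f, LoA [%.2f, %.2f], %d/%d (%.1f%%) outside\n",
    s$quantity, s$mean_diff, s$sd_diff, s$lower, s$upper,
    s$n_outside, s$n, s$pct_outside))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `"bland_altman"` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$stats

#' @rdname bland_altman
#' @param object A `"bland_altman"` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outside),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = s$mean_diff, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(s$lower, s$upper),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(
      x = sprintf("Mean of test and reference %s", toupper(s$quantity)),
      y = "Test - reference",
      title = sprintf("Bland-Altman, %s (LoA = mean ± %g SD)",
                      toupper(s$quantity), s$k)) +
    ggplot2::theme_minimal()
}

#' Pearson correlation between test and reference measurements
#'
#' @inheritParams diff_stats
#' @return A one-row tibble: `quantity`, `n`, `r`, `p` (two-sided, from the
#'   t transform via [stats::cor.test()]).
#' @export
pearson_agreement <- function(pairs, quantity = c("sbp", "dbp", "hr")) {
  q <- quantity_cols(pairs, quantity)
  if (length(q$test) < 3) abort("need at least 3 pairs",
                                class = "pttbp_input_error")
  if (sd(q$test) == 0 || sd(q$ref) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(quantity = q$quantity, n = length(q$test),
                  r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(q$test, q$ref, method = "pearson")
  tibble(quantity = q$quantity, n = length(q$test),
         r = unname(ct$estimate), p = ct$p.value)
}

#' Per-participant coefficient of variation
#'
#' For each participant with at least two repeated measurements,
#' `CV = 100 * SD / mean` over that participant's repeats on one device;
#' participants with fewer repeats are excluded with a warning. The mean CV
#' across participants is attached as attribute `mean_cv_pct` (the figure
#' validation tables report).
#'
#' @param pairs Data frame with a `participant_id` column and the quantity's
#'   `test_`/`ref_` columns.
#' @inheritParams diff_stats
#' @param device `"test"` or `"ref"`: which device's repeats to summarize.
#' @return A tibble `participant_id`, `n`, `cv_pct`, with attribute
#'   `mean_cv_pct`.
#' @examples
#' pairs <- tibble::tibble(participant_id = c(1, 1, 2, 2),
#'                         test_sbp = c(100, 110, 120, 120),
#'                         ref_sbp = c(100, 108, 121, 119))
#' cv_per_participant(pairs, "sbp")
#' @export
cv_per_participant <- function(pairs, quantity = c("sbp", "dbp", "hr"),
                               device = c("test", "ref")) {
  device <- match.arg(device)
  quantity <- match.arg(quantity)
  col <- paste0(device, "_", quantity)
  if (!all(c("participant_id", col) %in% names(pairs))) {
    abort(sprintf("`pairs` needs columns participant_id, %s", col),
          class = "pttbp_input_error")
  }
  out <- pairs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n = dplyr::n(),
                     cv_pct = 100 * sd(.data[[col]]) / mean(.data[[col]]),
                     .groups = "drop")
  dropped <- out$n < 2
  if (any(dropped)) {
    warn(sprintf("%d participant(s) with < 2 measurements excluded",
                 sum(dropped)))
    out <- out[!dropped, ]
  }
  structure(out, mean_cv_pct = mean(out$cv_pct))
}

#' AAMI/ESH/ISO criterion 1
#'
#' A device passes when the mean test-reference difference is at most
#' 5 mm Hg in magnitude and its SD is at most 8 mm Hg.
#'
#' @param mean_diff,sd_diff Difference statistics, mm Hg.
#' @param mean_max,sd_max Criterion thresholds.
#' @return Logical.
#' @examples
#' aami_criterion1(1.2, 7.1)   # TRUE
#' aami_criterion1(5.1, 7.9)   # FALSE
#' @export
aami_criterion1 <- function(mean_diff, sd_diff, mean_max = 5, sd_max = 8) {
  stopifnot(all(sd_diff >= 0))
  abs(mean_diff) <= mean_max & sd_diff <= sd_max
}
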