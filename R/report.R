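#' Full device-validation report
#'
#' Assembles, per quantity present in the pairs table (SBP, DBP, and HR if
#' provided), the complete statistics surface of an AAMI/ESH/ISO-style
#' validation: paired difference mean/SD, absolute-difference bands,
#' Bland-Altman limits and outliers, Pearson correlation, per-participant
#' coefficient of variation, and the criterion-1 pass flag.
#'
#' @param pairs Data frame with columns `test_sbp`, `test_dbp`, `ref_sbp`,
#'   `ref_dbp` (optionally `test_hr`, `ref_hr`, `participant_id`).
#' @param thresholds Absolute-difference band thresholds, mm Hg.
#' @param k Bland-Altman limit multiple.
#' @param config Optional [pipeline_config()]; when given, its
#'   `band_thresholds_mmhg` and `bland_altman_k` override `thresholds`/`k`
#'   and its hash and seed are embedded in the report.
#' @return A list of class `"bp_validation"`: `n_pairs`, `quantities`, and
#'   per-quantity entries each holding `diff`, `bands`, `bland_altman`,
#'   `pearson`, `cv` (when `participant_id` is present) and `aami_pass`.
#' @examples
#' pairs <- tibble::tibble(
#'   participant_id = rep(1:10, each = 3),
#'   ref_sbp = rnorm(30, 120, 15), test_sbp = ref_sbp + rnorm(30, 1, 5),
#'   ref_dbp = rnorm(30, 80, 10), test_dbp = ref_dbp + rnorm(30, -1, 4))
#' rep <- validate_pairs(pairs)
#' glance(rep)
#' @export
validate_pairs <- function(pairs, thresholds = c(5, 10, 15), k = 2,
                           config = NULL) {
  if (!is.null(config)) {
    thresholds <- config$band_thresholds_mmhg
    k <- config$bland_altman_k
  }
  pairs <- as_tibble(pairs)
  quantities <- c("sbp", "dbp", "hr")
  quantities <- quantities[vapply(
    quantities,
    function(q) all(paste0(c("test_", "ref_"), q) %in% names(pairs)),
    logical(1))]
  if (length(quantities) == 0) {
    abort("`pairs` has no test_/ref_ quantity columns",
          class = "pttbp_input_error")
  }
  has_id <- "participant_id" %in% names(pairs)

  per_q <- lapply(quantities, function(q) {
    ds <- diff_stats(pairs, q)
    list(
      diff = ds,
      bands = band_percentages(pairs, q, thresholds),
      bland_altman = bland_altman(pairs, q, k),
      pearson = pearson_agreement(pairs, q),
      cv = if (has_id) {
        list(test = cv_per_participant(pairs, q, "test"),
             ref = cv_per_participant(pairs, q, "ref"))
      },
      aami_pass = aami_criterion1(ds$mean_diff, ds$sd_diff)
    )
  })
  names(per_q) <- quantities

  structure(list(
    n_pairs = nrow(pairs),
    quantities = quantities,
    results = per_q,
    config_hash = if (!is.null(config)) config_hash(config),
    seed = if (!is.null(config)) config$seed
  ), class = "bp_validation")
}

#' @export
print.bp_validation <- function(x, ...) {
  cat(sprintf("<bp_validation> %d pairs\n", x$n_pairs))
  for (q in x$quantities) {
    r <- x$results[[q]]
    cat(sprintf(
      "  %s: diff %.1f (SD %.1f), AAMI-1 %s; <%s mm Hg: %s%%; BA outside: %.1f%%\n",
      toupper(q), r$diff$mean_diff, r$diff$sd_diff,
      if (r$aami_pass) "pass" else "FAIL",
      paste(r$bands$threshold, collapse = "/"),
      paste(format(r$bands$pct, nsmall = 1), collapse = "/"),
      r$bland_altman$stats$pct_outside))
  }
  invisible(x)
}

#' @rdname validate_pairs
#' @param x,object A `"bp_validation"` report.
#' @param ... Unused.
#' @export
tidy.bp_validation <- function(x, ...) {
  purrr::map_dfr(x$quantities, function(q) {
    r <- x$results[[q]]
    dplyr::bind_rows(
      tibble(quantity = q, statistic = "mean_diff", value = r$diff$mean_diff),
      tibble(quantity = q, statistic = "sd_diff", value = r$diff$sd_diff),
      tibble(quantity = q,
             statistic = paste0("pct_lt_", r$bands$threshold),
             value = r$bands$pct),
      tibble(quantity = q, statistic = "ba_pct_outside",
             value = r$bland_altman$stats$pct_outside),
      tibble(quantity = q, statistic = "pearson_r", value = r$pearson$r),
      tibble(quantity = q, statistic = "aami_pass",
             value = as.numeric(r$aami_pass))
    )
  })
}

#' @rdname validate_pairs
#' @export
glance.bp_validation <- function(x, ...) {
  purrr::map_dfr(x$quantities, function(q) {
    r <- x$results[[q]]
    tibble(quantity = q, n = x$n_pairs,
           mean_diff = r$diff$mean_diff, sd_diff = r$diff$sd_diff,
           ba_pct_outside = r$bland_altman$stats$pct_outside,
           pearson_r = r$pearson$r, aami_pass = r$aami_pass)
  })
}

#' @rdname validate_pairs
#' @export
autoplot.bp_validation <- function(object, ...) {
  pts <- purrr::map_dfr(object$quantities, function(q) {
    ba <- object$results[[q]]$bland_altman
    dplyr::mutate(ba$points, quantity = toupper(q),
                  lower = ba$stats$lower, upper = ba$stats$upper,
                  mean_diff = ba$stats$mean_diff)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outside),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$mean_diff),
                        linewidth = 0.4) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "Mean of test and reference (mm Hg)",
                  y = "Test - reference (mm Hg)") +
    ggplot2::theme_minimal()
}
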