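test_that("difference statistics are the paired mean and sample SD", {
  same <- tibble::tibble(test_sbp = c(118, 125, 131),
                         ref_sbp = c(118, 125, 131))
  expect_equal(diff_stats(same, "sbp")$mean_diff, 0)
  expect_equal(diff_stats(same, "sbp")$sd_diff, 0)

  two <- tibble::tibble(test_dbp = c(81, 83), ref_dbp = c(80, 80))
  ds <- diff_stats(two, "dbp")
  expect_equal(ds$mean_diff, 2)
  expect_equal(ds$sd_diff, sqrt(2))

  expect_error(diff_stats(two[1, ], "dbp"), class = "pttbp_input_error")
})

test_that("simulated differences at the published scale are summarized faithfully", {
  withr::with_seed(261, {
    ref <- rnorm(261, 118.7, 20.2)
    pairs <- tibble::tibble(ref_sbp = ref,
                            test_sbp = ref + rnorm(261, 1.2, 7.1))
  })
  ds <- diff_stats(pairs, "sbp")
  # sampling error bounds: SE(mean) = 7.1/sqrt(261) ~ 0.44, so +/- 1.0 is
  # a > 2-sigma band; SD has SE ~ 7.1/sqrt(2*260) ~ 0.31
  expect_lt(abs(ds$mean_diff - 1.2), 1.0)
  expect_lt(abs(ds$sd_diff - 7.1), 0.8)
  expect_true(aami_criterion1(ds$mean_diff, ds$sd_diff))
})

test_that("band percentages count strictly and round half-up", {
  pairs <- pairs_with_band_counts(c(150, 220, 247), 261)
  b <- band_percentages(pairs, "sbp")
  expect_equal(b$count, c(150, 220, 247))
  expect_equal(b$pct, c(57.5, 84.3, 94.6))

  # a diff exactly at a threshold is NOT inside the band (strict <)
  edge <- tibble::tibble(test_sbp = c(125, 124.999), ref_sbp = c(120, 120))
  expect_equal(band_percentages(edge, "sbp")$count[1], 1L)

  # 1/16 = 6.25% rounds UP to 6.3 (half-even would give 6.2)
  sixteen <- tibble::tibble(test_sbp = c(121, rep(140, 15)),
                            ref_sbp = rep(120, 16))
  expect_equal(band_percentages(sixteen, "sbp")$pct[1], 6.3)

  zero <- tibble::tibble(test_sbp = rep(120, 4), ref_sbp = rep(120, 4))
  expect_equal(band_percentages(zero, "sbp")$pct, c(100, 100, 100))
})

test_that("band percentages are monotone in the threshold", {
  for (s in 1:25) {
    pairs <- random_pairs(sample(5:50, 1), seed = s)
    b <- band_percentages(pairs, "sbp")
    expect_true(!is.unsorted(b$count))
    expect_true(!is.unsorted(b$pct))
    expect_true(all(b$pct >= 0 & b$pct <= 100))
  }
})

test_that("Bland-Altman limits and outlier counts", {
  same <- tibble::tibble(test_sbp = c(118, 125, 131),
                         ref_sbp = c(118, 125, 131))
  ba0 <- bland_altman(same, "sbp")
  expect_equal(ba0$stats$lower, 0)
  expect_equal(ba0$stats$upper, 0)
  expect_equal(ba0$stats$n_outside, 0L)

  # 99 tight diffs and one far out: exactly one point beyond mean +/- 2 SD
  d <- c(rep(0, 99), 10)
  one <- tibble::tibble(test_sbp = 120 + d, ref_sbp = rep(120, 100))
  ba1 <- bland_altman(one, "sbp")
  expect_equal(ba1$stats$n_outside, 1L)
  expect_equal(ba1$stats$pct_outside, 1.0)
  expect_true(ba1$points$outside[100])
  expect_equal(ba1$stats$lower, mean(d) - 2 * sd(d))
})

test_that("Bland-Altman coverage under normal differences is ~4.6% outside 2 SD", {
  withr::with_seed(7, {
    ref <- rnorm(10000, 120, 15)
    pairs <- tibble::tibble(ref_sbp = ref, test_sbp = ref + rnorm(10000, 0, 6))
  })
  ba <- bland_altman(pairs, "sbp")
  expect_lt(abs(ba$stats$pct_outside - 4.6), 0.6)
})

test_that("Pearson agreement handles the exact and degenerate cases", {
  x <- c(100, 110, 120, 135)
  p1 <- pearson_agreement(tibble::tibble(test_sbp = x, ref_sbp = x), "sbp")
  expect_equal(p1$r, 1)
  p2 <- pearson_agreement(tibble::tibble(test_sbp = -x, ref_sbp = x), "sbp")
  expect_equal(p2$r, -1)
  expect_warning(
    pz <- pearson_agreement(tibble::tibble(test_sbp = rep(1, 5),
                                           ref_sbp = 1:5), "sbp"))
  expect_true(is.na(pz$r))
})

test_that("seeded bivariate-normal correlation lands in the Fisher-z interval", {
  withr::with_seed(42, {
    z <- rnorm(200)
    x <- z + rnorm(200, sd = sqrt(1 / 0.9^2 - 1))
  })
  p <- pearson_agreement(tibble::tibble(test_sbp = 120 + 10 * x,
                                        ref_sbp = 120 + 10 * z), "sbp")
  expect_gt(p$r, 0.85)
  expect_lt(p$r, 0.94)
  expect_lt(p$p, 1e-6)
})

test_that("per-participant coefficient of variation", {
  pairs <- tibble::tibble(participant_id = c(1, 1, 2, 2, 2),
                          test_sbp = c(100, 110, 120, 120, 120),
                          ref_sbp = c(99, 111, 119, 121, 120))
  cv <- cv_per_participant(pairs, "sbp", "test")
  expect_equal(cv$cv_pct[1], 100 * sd(c(100, 110)) / 105)
  expect_equal(cv$cv_pct[2], 0)
  expect_equal(attr(cv, "mean_cv_pct"), mean(cv$cv_pct))

  # equal CVs average to the common value
  p3 <- tibble::tibble(participant_id = rep(1:3, each = 2),
                       test_sbp = c(100, 110, 200, 220, 50, 55),
                       ref_sbp = 0)
  cv3 <- cv_per_participant(p3, "sbp", "test")
  expect_equal(attr(cv3, "mean_cv_pct"), cv3$cv_pct[1])

  # singletons are excluded with a warning
  p4 <- dplyr::bind_rows(pairs, tibble::tibble(participant_id = 9,
                                               test_sbp = 130, ref_sbp = 130))
  expect_warning(cv4 <- cv_per_participant(p4, "sbp", "test"), "excluded")
  expect_equal(nrow(cv4), 2)
})

test_that("AAMI criterion 1 thresholds", {
  expect_true(aami_criterion1(1.2, 7.1))
  expect_true(aami_criterion1(-1.0, 6.0))
  expect_false(aami_criterion1(5.1, 7.9))
  expect_false(aami_criterion1(4.9, 8.1))
  expect_true(aami_criterion1(5, 8))     # boundary is inclusive
})

test_that("all statistics match the naive brute-force oracle on random tables", {
  for (s in 1:30) {
    n <- sample(4:50, 1)
    pairs <- random_pairs(n, seed = 1000 + s)
    for (q in c("sbp", "dbp")) {
      test <- pairs[[paste0("test_", q)]]
      ref <- pairs[[paste0("ref_", q)]]
      ds <- diff_stats(pairs, q)
      or <- naive_diff_stats(test, ref)
      expect_equal(ds$mean_diff, unname(or["mean"]), tolerance = 1e-14)
      expect_equal(ds$sd_diff, unname(or["sd"]), tolerance = 1e-14)

      b <- band_percentages(pairs, q)
      expect_identical(b$count, naive_band_counts(test, ref, c(5, 10, 15)))
      expect_identical(b$pct,
                       naive_half_up(100 * b$count / n, 1))

      ba <- bland_altman(pairs, q)$stats
      orb <- naive_bland_altman(test, ref)
      expect_equal(ba$lower, unname(orb["lower"]), tolerance = 1e-14)
      expect_equal(ba$upper, unname(orb["upper"]), tolerance = 1e-14)
      expect_identical(as.integer(ba$n_outside), as.integer(orb["n_outside"]))

      pr <- pearson_agreement(pairs, q)
      ct <- stats::cor.test(test, ref)
      expect_identical(pr$r, unname(ct$estimate))
      expect_identical(pr$p, ct$p.value)
    }
  }
})

test_that("the assembled validation report carries every statistic", {
  pairs <- random_pairs(60, n_participants = 20, seed = 5)
  rep <- validate_pairs(pairs)
  expect_s3_class(rep, "bp_validation")
  expect_equal(rep$n_pairs, 60)
  expect_setequal(rep$quantities, c("sbp", "dbp"))
  r <- rep$results$sbp
  expect_identical(r$diff, diff_stats(pairs, "sbp"))
  expect_identical(r$bands, band_percentages(pairs, "sbp"))
  expect_identical(r$aami_pass,
                   aami_criterion1(r$diff$mean_diff, r$diff$sd_diff))
  td <- tidy(rep)
  expect_true(all(c("pct_lt_5", "ba_pct_outside", "aami_pass") %in%
                    td$statistic))
  gl <- glance(rep)
  expect_equal(nrow(gl), 2)

  pl <- autoplot(rep)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(autoplot(rep$results$sbp$bland_altman), "ggplot")
})
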