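# Naive, loop-based recomputation of every validation statistic, kept
# deliberately independent of the package implementation so it can serve as a
# brute-force oracle on small tables.

naive_diff_stats <- function(test, ref) {
  d <- test - ref
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  c(mean = m, sd = s)
}

naive_band_counts <- function(test, ref, thresholds) {
  vapply(thresholds, function(th) {
    cnt <- 0L
    for (i in seq_along(test)) if (abs(test[i] - ref[i]) < th) cnt <- cnt + 1L
    cnt
  }, integer(1))
}

naive_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

naive_bland_altman <- function(test, ref, k = 2) {
  st <- naive_diff_stats(test, ref)
  lo <- st["mean"] - k * st["sd"]
  hi <- st["mean"] + k * st["sd"]
  d <- test - ref
  out <- 0L
  for (i in seq_along(d)) if (d[i] < lo || d[i] > hi) out <- out + 1L
  c(lower = unname(lo), upper = unname(hi), n_outside = out)
}

naive_cv <- function(values) {
  m <- mean(values)
  100 * sqrt(sum((values - m)^2) / (length(values) - 1)) / m
}

# random measurement-pairs table for property tests
random_pairs <- function(n, n_participants = max(2, n %/% 3), seed = 1) {
  withr::with_seed(seed, {
    ref_sbp <- rnorm(n, 120, 15)
    ref_dbp <- ref_sbp - pmax(20, rnorm(n, 40, 8))
    tibble::tibble(
      participant_id = sample(seq_len(n_participants), n, replace = TRUE),
      ref_sbp = ref_sbp,
      test_sbp = ref_sbp + rnorm(n, 1, 6),
      ref_dbp = ref_dbp,
      test_dbp = ref_dbp + rnorm(n, -1, 5)
    )
  })
}

# pairs table with prescribed absolute-difference band counts: `counts[k]`
# pairs fall strictly below thresholds[k] (cumulative), the rest above all
pairs_with_band_counts <- function(counts, n, thresholds = c(5, 10, 15)) {
  stopifnot(!is.unsorted(counts), counts[length(counts)] <= n)
  in_band <- diff(c(0, counts))
  mids <- c(0, thresholds[-length(thresholds)]) +
    diff(c(0, thresholds)) / 2          # one representative |diff| per band
  d <- c(rep(mids, in_band), rep(thresholds[length(thresholds)] + 5,
                                 n - counts[length(counts)]))
  tibble::tibble(test_sbp = 120 + d, ref_sbp = rep(120, n))
}
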