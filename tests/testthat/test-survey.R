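make_ratings <- function(seed = 1, n_participants = 6, shift = 0) {
  set.seed(seed)
  attrs <- plantarqc:::SURVEY_ATTRIBUTES
  expand <- expand.grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    item = 1:10, approach = c("A", "B"), attribute = attrs,
    stringsAsFactors = FALSE
  )
  expand$rating <- pmin(7, pmax(1, sample(3:6, nrow(expand), TRUE) +
                                  ifelse(expand$approach == "B", shift, 0)))
  expand
}

test_that("subject medians use the midpoint convention", {
  r <- data.frame(
    participant = "P1", item = 1:4, approach = "A",
    attribute = "clarity", rating = c(3L, 4L, 4L, 5L)
  )
  expect_equal(subject_medians(r)$median, 4)
  r2 <- r[1:2, ]; r2$rating <- c(1L, 7L)
  expect_equal(subject_medians(r2)$median, 4)
  r3 <- r; r3$rating <- rep(5L, 4)
  expect_equal(subject_medians(r3)$median, 5)
  expect_error(subject_medians(data.frame(participant = 1)), "columns")
  bad <- r; bad$rating[1] <- 9L
  expect_error(subject_medians(bad), "1..7")
  med <- subject_medians(make_ratings())
  expect_equal(nrow(med), 6 * 2 * 8)
})

test_that("signed-rank p-values match exact enumeration and the t-free oracle", {
  # all differences equal: p = 2 / 2^5
  res <- plantarqc:::wilcoxon_signed_rank(c(1, 2, 3, 4, 5) - c(2, 3, 4, 5, 6))
  expect_equal(res$p_value, 0.0625)
  expect_true(res$exact)

  # matches wilcox.test exact p on tie-free data for n <= 10
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    d <- round(runif(n, -3, 3), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    ours <- plantarqc:::wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
  expect_error(plantarqc:::wilcoxon_signed_rank(rep(0, 4)), "zero")
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  a <- matrix(c(5, 6, 6, 5, 7, 5,
                4, 4, 5, 4, 4, 5), 6, 2,
              dimnames = list(NULL, c("clarity", "simplicity")))
  b <- matrix(c(4, 5, 5, 4, 6, 4,
                4, 5, 4, 5, 4, 4), 6, 2,
              dimnames = list(NULL, c("clarity", "simplicity")))
  out <- paired_wilcoxon_bonferroni(a, b, m_comparisons = 8)
  expect_equal(out$p_adj, pmin(1, out$p_raw * 8))
  expect_true(all(diff(order(out$p_raw)) == diff(order(out$p_adj))))
  # p_raw 0.3 with m = 8 caps at 1
  expect_equal(min(1, 0.3 * 8), 1)

  med <- subject_medians(make_ratings(shift = 1))
  ma <- med[med$approach == "A", ]
  mb <- med[med$approach == "B", ]
  res <- paired_wilcoxon_bonferroni(ma, mb)
  expect_equal(nrow(res), 8)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
})

test_that("bootstrap CI is seeded, ordered and level-monotone", {
  x <- c(2, 3, 3, 4, 5, 5, 6, 7)
  ci <- bootstrap_median_ci(x, n_resamples = 2000, seed = 8)
  ci2 <- bootstrap_median_ci(x, n_resamples = 2000, seed = 8)
  expect_identical(ci, ci2)
  expect_lte(ci[["lo"]], median(x))
  expect_gte(ci[["hi"]], median(x))
  # constant data collapse to a point
  expect_equal(unname(bootstrap_median_ci(rep(4, 10), 500, seed = 1)),
               c(4, 4))
  # wider level, wider interval
  set.seed(77)
  y <- rnorm(25)
  w90 <- bootstrap_median_ci(y, 3000, level = 0.90, seed = 3)
  w99 <- bootstrap_median_ci(y, 3000, level = 0.99, seed = 3)
  expect_gte(diff(w99), diff(w90))
})

test_that("bootstrap CI coverage is near nominal", {
  set.seed(123)
  hits <- vapply(1:300, function(i) {
    x <- rnorm(20, mean = 1)
    ci <- bootstrap_median_ci(x, n_resamples = 400, level = 0.9, seed = i)
    ci[["lo"]] <= qnorm(0.5, 1) && qnorm(0.5, 1) <= ci[["hi"]]
  }, logical(1))
  expect_gt(mean(hits), 0.80)
  expect_lte(mean(hits), 1.0)
})

test_that("post-hoc power reproduces the reported approximation", {
  pw <- posthoc_power(dz = 0.8, n = 16, alpha = 0.05,
                      method = "wilcoxon_are")
  expect_equal(pw, 0.83, tolerance = 0.02)
  # null effect gives alpha
  expect_equal(posthoc_power(0, 16, 0.05, "paired_t"), 0.05,
               tolerance = 1e-6)
  # strictly increasing in n
  pows <- vapply(5:50, function(n) posthoc_power(0.8, n), numeric(1))
  expect_true(all(diff(pows) > 0))
  # the signed-rank discount costs power relative to the paired t
  expect_lt(posthoc_power(0.8, 16, method = "wilcoxon_are"),
            posthoc_power(0.8, 16, method = "paired_t"))
})
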