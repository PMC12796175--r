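# Analysis utilities for the semantic-differential expert survey:
# subject-median aggregation, paired signed-rank tests with Bonferroni
# correction, bootstrap confidence intervals of medians and post-hoc
# power approximations.

SURVEY_ATTRIBUTES <- c(
  "understandability", "correctness", "trustworthiness", "usefulness",
  "clarity", "completeness", "simplicity", "relevance"
)

#' Subject-level median ratings
#'
#' Aggregates item-level Likert ratings (long format) to one median per
#' participant, attribute and approach; the midpoint convention is used
#' for even counts.
#'
#' @param ratings data frame with columns `participant`, `item`,
#'   `approach`, `attribute`, `rating` (integers 1..7).
#' @return Data frame with columns `participant`, `attribute`, `approach`,
#'   `median`.
#' @export
subject_medians <- function(ratings) {
  required <- c("participant", "item", "approach", "attribute", "rating")
  if (!all(required %in% names(ratings))) {
    stop("ratings must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ratings$rating %in% 1:7)) {
    stop("ratings must be integers on the 1..7 scale", call. = FALSE)
  }
  groups <- unique(ratings[c("participant", "attribute", "approach")])
  groups$median <- NA_real_
  for (i in seq_len(nrow(groups))) {
    sel <- ratings$participant == groups$participant[i] &
      ratings$attribute == groups$attribute[i] &
      ratings$approach == groups$approach[i]
    vals <- ratings$rating[sel]
    if (length(vals) == 0) {
      stop(sprintf("no ratings for participant %s, attribute %s, approach %s",
                   groups$participant[i], groups$attribute[i],
                   groups$approach[i]), call. = FALSE)
    }
    groups$median[i] <- stats::median(vals)
  }
  rownames(groups) <- NULL
  groups
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments
# of the non-zero differences (valid with ties); falls back to the normal
# approximation with tie correction for large n.
wilcoxon_signed_rank <- function(d, exact_limit = 20L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero; test undefined", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of V over all 2^n sign patterns
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)  # subset-sum enumeration
    mu <- n * (n + 1) / 4
    p <- 2 * min(mean(sums >= v - 1e-9), mean(sums <= v + 1e-9))
    list(statistic = v, p_value = min(1, p), exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    list(statistic = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         exact = FALSE)
  }
}

#' Paired signed-rank tests with Bonferroni correction
#'
#' Applies the two-sided Wilcoxon signed-rank test (zero differences
#' dropped; exact sign-flip enumeration up to 20 pairs, tie-corrected
#' normal approximation beyond) to each attribute's paired subject medians
#' and Bonferroni-adjusts the p-values.
#'
#' @param med_a,med_b data frames from [subject_medians()] for the two
#'   approaches, or matrices/data frames with one column per attribute and
#'   one row per participant.
#' @param m_comparisons Bonferroni denominator (default: number of
#'   attributes tested).
#' @param alpha significance level applied to the adjusted p-values.
#' @return Data frame: `attribute`, `statistic`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
paired_wilcoxon_bonferroni <- function(med_a, med_b, m_comparisons = NULL,
                                       alpha = 0.05) {
  if (is.data.frame(med_a) && "attribute" %in% names(med_a)) {
    attrs <- unique(med_a$attribute)
    get_vec <- function(df, at) {
      sub <- df[df$attribute == at, ]
      sub$median[order(sub$participant)]
    }
    a_list <- lapply(attrs, get_vec, df = med_a)
    b_list <- lapply(attrs, get_vec, df = med_b)
  } else {
    med_a <- as.data.frame(med_a)
    med_b <- as.data.frame(med_b)
    attrs <- names(med_a)
    a_list <- as.list(med_a)
    b_list <- as.list(med_b)
  }
  if (is.null(m_comparisons)) m_comparisons <- length(attrs)
  out <- data.frame(attribute = as.character(attrs),
                    statistic = NA_real_, p_raw = NA_real_,
                    p_adj = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(attrs)) {
    a <- a_list[[i]]
    b <- b_list[[i]]
    if (length(a) != length(b) || length(a) < 2) {
      stop("paired vectors must have equal length >= 2", call. = FALSE)
    }
    w <- wilcoxon_signed_rank(a - b)
    out$statistic[i] <- w$statistic
    out$p_raw[i] <- w$p_value
    out$p_adj[i] <- min(1, m_comparisons * w$p_value)
    out$significant[i] <- out$p_adj[i] < alpha
  }
  out
}

#' Percentile bootstrap confidence interval of a median
#'
#' @param values numeric vector (>= 2 values).
#' @param n_resamples bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, n_resamples = 5000L, level = 0.95,
                                seed = 1L) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  with_seed(seed, {
    meds <- vapply(seq_len(n_resamples), function(i) {
      stats::median(sample(values, replace = TRUE))
    }, numeric(1))
    alpha <- (1 - level) / 2
    ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE,
                          type = 7)
    c(lo = ci[1], hi = ci[2])
  })
}

#' Post-hoc power for a paired comparison
#'
#' Power of a two-sided paired test at effect size `dz`, approximated via
#' the noncentral t distribution.  For `method = "wilcoxon_are"` the
#' sample size is discounted by the asymptotic relative efficiency of the
#' signed-rank test versus the paired t-test under normality (0.955), the
#' standard large-sample approximation used by power calculators; the
#' noncentrality is `dz * sqrt(ARE * n)` with `ARE * n - 1` degrees of
#' freedom.  `method = "paired_t"` uses the full `n`.
#'
#' @param dz standardized effect size of the paired differences.
#' @param n number of pairs (>= 2).
#' @param alpha two-sided significance level.
#' @param method `"wilcoxon_are"` or `"paired_t"`.
#' @param are efficiency constant for the signed-rank discount.
#' @return Power in (0, 1).
#' @export
posthoc_power <- function(dz, n, alpha = 0.05,
                          method = c("wilcoxon_are", "paired_t"),
                          are = 0.955) {
  method <- match.arg(method)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  n_eff <- if (method == "wilcoxon_are") are * n else n
  df <- n_eff - 1
  ncp <- dz * sqrt(n_eff)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}
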