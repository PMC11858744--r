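#' Mann-Whitney U test on per-subject percentages
#'
#' Rank-sum comparison of two independent samples (typically the
#' per-subject percentage-of-"thicker" tables of two cohorts). Ties get
#' midranks. The U of the first sample (`u`, pairs where `x` exceeds `y`
#' plus half-ties) and the complementary `u_complement = n1*n2 - u` are
#' both reported, because either convention appears in the literature. The
#' two-sided p-value uses the normal approximation with tie correction and
#' a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Object of class `rank_test`: `statistic` (U of `x`),
#'   `u_complement`, `mean_difference` (`mean(x) - mean(y)`, percentage
#'   points when inputs are percentages), `p_value`, `method`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  p <- if (sigma2 <= 0) {
    1
  } else {
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-max(z, 0))
  }
  structure(list(statistic = u, u_complement = n1 * n2 - u,
                 mean_difference = mean(x) - mean(y),
                 p_value = min(p, 1),
                 method = "mann_whitney_u", n1 = n1, n2 = n2),
            class = "rank_test")
}

#' Wilcoxon signed-rank test against a baseline
#'
#' One-sample signed-rank test of paired-style percentages against a fixed
#' baseline (50% for an unbiased 2AFC population). Differences of exactly
#' zero are dropped; ties in `|difference|` get midranks. The statistic is
#' the smaller of the two signed-rank sums. Two-sided p-value via the
#' normal approximation with tie correction and continuity correction.
#'
#' @param values Numeric vector.
#' @param baseline Scalar baseline (default 50).
#' @return Object of class `rank_test`: `statistic` (smaller rank sum W),
#'   `w_plus`, `w_minus`, `mean_difference`, `p_value`, `n1` (non-zero
#'   differences used), `n_zero` (dropped).
#' @export
wilcoxon_signed_rank <- function(values, baseline = 50) {
  values <- values[!is.na(values)]
  d <- values - baseline
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all values equal the baseline; no signed ranks")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  p <- if (sigma2 <= 0) {
    1
  } else {
    z <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-max(z, 0))
  }
  structure(list(statistic = w, w_plus = w_plus, w_minus = w_minus,
                 mean_difference = mean(values) - baseline,
                 p_value = min(p, 1),
                 method = "wilcoxon_signed_rank", n1 = n, n2 = NA_integer_,
                 n_zero = n_zero),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  lab <- if (x$method == "mann_whitney_u") "U" else "W"
  cat(x$method, ": ", lab, " = ", x$statistic,
      ", mean difference = ", signif(x$mean_difference, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
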