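#' Participant-resampling bootstrap of a psychometric fit
#'
#' For each iteration and independently for every test-reference pair, the
#' pooled participant responses are resampled with replacement (N draws,
#' N = number of responses observed for that pair) and the psychometric
#' model is refitted, yielding 5000 (by default) bootstrapped `(w, p)`
#' pairs from which percentile intervals, difference tests and bias tests
#' derive.
#'
#' Per-iteration RNG streams are pre-drawn from the root `seed`, so
#' extending `iterations` leaves earlier draws unchanged and the same seed
#' reproduces draws exactly.
#'
#' In `fixed_p` mode the refits use a vectorized grid + golden-section
#' minimizer over all iterations at once; `free_p` refits call
#' [fit_psychometric()] per iteration.
#'
#' @param table A `response_table` from [aggregate_responses()] (must carry
#'   the `responses` list-column).
#' @param iterations Number of bootstrap iterations (default 5000).
#' @param seed Integer root seed.
#' @param mode `"fixed_p"` or `"free_p"` (see [fit_psychometric()]).
#' @param p_true True reference viscosity (cP).
#' @param constraints A [fit_constraints()] object.
#' @return Object of class `bootstrap_sample`: `w_draws`, `p_draws`,
#'   `converged` (per iteration), `iterations`, `seed`, `mode`, `p_true`,
#'   `group_label`.
#' @export
bootstrap_fit <- function(table, iterations = 5000, seed = 1L,
                          mode = c("fixed_p", "free_p"),
                          p_true = attr(table, "reference_viscosity_cp"),
                          constraints = fit_constraints()) {
  mode <- match.arg(mode)
  if (is.null(table$responses)) {
    stop("table lacks per-response data; build it with aggregate_responses()")
  }
  if (is.null(p_true) || !is.finite(p_true) || p_true <= 0) {
    stop("p_true must be a positive reference viscosity")
  }
  stopifnot(iterations >= 1L)
  n_rows <- nrow(table)
  n_per <- table$n_total

  # per-iteration substreams: sample.int draws sequentially, so the first
  # k seeds are identical for any iterations >= k (prefix stability)
  iter_seeds <- with_local_seed(seed,
                                sample.int(.Machine$integer.max - 1L, iterations))
  k_mat <- matrix(0L, nrow = iterations, ncol = n_rows)
  for (i in seq_len(iterations)) {
    k_mat[i, ] <- with_local_seed(iter_seeds[i], vapply(seq_len(n_rows),
      function(j) {
        resp <- table$responses[[j]]
        sum(resp[sample.int(n_per[j], n_per[j], replace = TRUE)])
      }, integer(1)))
  }

  if (mode == "fixed_p") {
    res <- fit_weber_batch(k_mat, n_per, table$eta_cp, p_true,
                           constraints$w_bounds)
    w_draws <- res$w
    p_draws <- rep(p_true, iterations)
    converged <- res$converged
  } else {
    w_draws <- numeric(iterations)
    p_draws <- numeric(iterations)
    converged <- logical(iterations)
    base <- data.frame(eta_cp = table$eta_cp, n_total = n_per)
    for (i in seq_len(iterations)) {
      base$k_thicker <- k_mat[i, ]
      ft <- fit_psychometric(base, mode = "free_p", p_true = p_true,
                             constraints = constraints)
      w_draws[i] <- ft$w
      p_draws[i] <- ft$p
      converged[i] <- ft$converged
    }
  }

  n_bad <- sum(!converged)
  if (!any(is.finite(w_draws))) {
    stop("no bootstrap iteration produced a usable refit")
  }
  if (n_bad > 0.2 * iterations) {
    warning(n_bad, " of ", iterations,
            " bootstrap refits did not converge cleanly")
  }
  structure(list(iterations = iterations, w_draws = w_draws,
                 p_draws = p_draws, converged = converged,
                 seed = seed, mode = mode, p_true = p_true,
                 group_label = attr(table, "group_label")),
            class = "bootstrap_sample")
}

# Vectorized 1-D maximum-likelihood Weber fits for many bootstrap count
# vectors at once: coarse log-grid argmin, then golden-section refinement
# run in parallel across iterations.
fit_weber_batch <- function(k_mat, n_per, eta, p_true, w_bounds,
                            grid_size = 240L, refine_steps = 45L) {
  z <- log(eta / p_true)                       # length n_rows
  kt <- t(k_mat)                               # rows x iterations
  nk <- n_per - kt
  nll_at <- function(lw) {
    # lw: one log(w) per iteration; returns NLL per iteration
    f <- stats::pnorm(outer(z, 1 / log1p(exp(lw))))
    f <- pmin(pmax(f, .prob_eps), 1 - .prob_eps)
    -colSums(kt * log(f) + nk * log1p(-f))
  }
  lw_grid <- seq(log(w_bounds[1]), log(w_bounds[2]), length.out = grid_size)
  f_grid <- stats::pnorm(outer(z, 1 / log1p(exp(lw_grid))))
  f_grid <- pmin(pmax(f_grid, .prob_eps), 1 - .prob_eps)
  nll_grid <- -(k_mat %*% log(f_grid) + t(nk) %*% log1p(-f_grid))
  idx <- max.col(-nll_grid, ties.method = "first")
  a <- lw_grid[pmax(idx - 1L, 1L)]
  b <- lw_grid[pmin(idx + 1L, grid_size)]
  invphi <- (sqrt(5) - 1) / 2
  x1 <- b - invphi * (b - a)
  x2 <- a + invphi * (b - a)
  f1 <- nll_at(x1)
  f2 <- nll_at(x2)
  for (s in seq_len(refine_steps)) {
    go_left <- f1 <= f2
    b <- ifelse(go_left, x2, b)
    a <- ifelse(go_left, a, x1)
    x1 <- b - invphi * (b - a)
    x2 <- a + invphi * (b - a)
    f1 <- nll_at(x1)
    f2 <- nll_at(x2)
  }
  lw_hat <- (a + b) / 2
  span <- log(w_bounds[2]) - log(w_bounds[1])
  at_bound <- pmin(lw_hat - log(w_bounds[1]),
                   log(w_bounds[2]) - lw_hat) < .bound_tol * span
  degenerate <- rowSums(k_mat) == 0L | rowSums(k_mat) == sum(n_per)
  list(w = exp(lw_hat), converged = !(at_bound | degenerate))
}

#' @export
print.bootstrap_sample <- function(x, ...) {
  cat("Bootstrap sample (", x$mode, "), ", x$iterations, " iterations, seed ",
      x$seed, "\n", sep = "")
  ci_w <- percentile_interval(x$w_draws, 95)
  cat("  w: mean ", signif(ci_w$mean, 4), ", 95% CI [",
      signif(ci_w$lower, 4), ", ", signif(ci_w$upper, 4), "]\n", sep = "")
  if (x$mode == "free_p") {
    ci_p <- percentile_interval(x$p_draws, 95)
    cat("  p: mean ", signif(ci_p$mean, 6), ", 95% CI [",
        signif(ci_p$lower, 6), ", ", signif(ci_p$upper, 6), "]\n", sep = "")
  }
  invisible(x)
}

#' Percentile bootstrap interval
#'
#' Plain percentile interval at the `(100 - level)/2` and
#' `100 - (100 - level)/2` empirical quantiles of the sorted draws, plus
#' the draw mean.
#'
#' @param draws Numeric vector of bootstrap draws (length >= 2).
#' @param level Confidence level in percent (e.g. 95, 99, 99.5).
#' @return List of class `interval_estimate`: `level`, `lower`, `upper`,
#'   `mean`.
#' @export
percentile_interval <- function(draws, level = 95) {
  if (length(draws) < 2L) stop("need at least 2 draws")
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)")
  alpha <- (100 - level) / 200
  qs <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  structure(list(level = level, lower = qs[1], upper = qs[2],
                 mean = mean(draws)),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(x$level, "% interval [", signif(x$lower, 4), ", ",
      signif(x$upper, 4), "], mean ", signif(x$mean, 4), "\n", sep = "")
  invisible(x)
}

#' Fit-quality exclusion rule
#'
#' A Weber-fraction estimate is excluded from reporting when its 95%
#' bootstrap CI is not smaller than 2 units wide — wide intervals flag
#' near-flat psychometric curves whose slope is not identified by the data.
#'
#' @param interval An `interval_estimate` for the Weber fraction at the
#'   95% level.
#' @param threshold Width threshold (default 2).
#' @return `TRUE` if the fit should be excluded (reported as N/A).
#' @export
exclude_poor_fit <- function(interval, threshold = 2) {
  (interval$upper - interval$lower) >= threshold
}

boot_draws <- function(x, parameter) {
  if (inherits(x, "bootstrap_sample")) {
    switch(parameter, w = x$w_draws, p = x$p_draws,
           stop("unknown parameter: ", parameter))
  } else if (is.numeric(x)) {
    x
  } else {
    stop("expected a bootstrap_sample or numeric draws")
  }
}

make_difference_test <- function(d, level, n_comparisons, alpha) {
  b <- length(d)
  delta <- mean(d)
  ci <- percentile_interval(d, level)
  p_emp <- min(1, 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (b + 1))
  s <- stats::sd(d)
  p_norm <- if (s == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta) / s)
  }
  alpha_corrected <- alpha / n_comparisons
  structure(list(delta = delta, ci = ci, p_empirical = p_emp,
                 p_normal = p_norm, n_comparisons = n_comparisons,
                 alpha_corrected = alpha_corrected,
                 significant = p_norm < alpha_corrected,
                 n_draws = b),
            class = "difference_test")
}

#' Bootstrap difference test between two parameter distributions
#'
#' Draw-by-draw differences (iteration i of A minus iteration i of B; the
#' iteration order of independent bootstraps is random, so this equals
#' independent pairing) give the mean difference `delta`, its percentile
#' CI, and two p-value flavours: `p_empirical`, the smoothed two-sided
#' sign fraction `2*min(...)*(r+1)/(B+1)` floored at `1/(B+1)`, and
#' `p_normal`, the two-sided normal tail from the difference-draw mean and
#' SD. The empirical p cannot resolve below `1/(B+1)`; `p_normal` is the
#' headline value used for the `significant` flag, compared against the
#' Bonferroni-corrected level `alpha / n_comparisons`.
#'
#' @param sample_a,sample_b `bootstrap_sample` objects (equal iteration
#'   counts) or plain numeric draw vectors.
#' @param parameter `"w"` or `"p"`.
#' @param level CI level in percent.
#' @param n_comparisons Size of the Bonferroni family.
#' @param alpha Family-wise base significance level.
#' @return Object of class `difference_test`.
#' @export
difference_test <- function(sample_a, sample_b, parameter = c("w", "p"),
                            level = 99, n_comparisons = 1, alpha = 0.05) {
  parameter <- match.arg(parameter)
  da <- boot_draws(sample_a, parameter)
  db <- boot_draws(sample_b, parameter)
  if (length(da) != length(db)) {
    stop("bootstrap samples have different iteration counts (",
         length(da), " vs ", length(db), ")")
  }
  make_difference_test(da - db, level, n_comparisons, alpha)
}

#' Bootstrap bias test of the PSE against the true reference
#'
#' Operates on the bootstrapped distances `p - p_true` of a free-p fit.
#' Positive `delta` means the (transparent) test stimulus must be
#' physically thicker than the (opaque) reference to be perceived as
#' equally thick.
#'
#' @param sample A `bootstrap_sample` with `mode = "free_p"`.
#' @param p_true True reference viscosity (cP); defaults to the value
#'   stored in the sample.
#' @inheritParams difference_test
#' @return Object of class `difference_test` on the PSE-distance scale (cP).
#' @export
bias_test <- function(sample, p_true = sample$p_true, level = 99,
                      n_comparisons = 1, alpha = 0.05) {
  if (!inherits(sample, "bootstrap_sample") || sample$mode != "free_p") {
    stop("bias_test requires a free_p bootstrap sample")
  }
  make_difference_test(sample$p_draws - p_true, level, n_comparisons, alpha)
}

#' @export
print.difference_test <- function(x, ...) {
  cat(sprintf("Delta %.4g, %g%% CI [%.4g, %.4g], p = %.3g (empirical %.3g)%s\n",
              x$delta, x$ci$level, x$ci$lower, x$ci$upper,
              x$p_normal, x$p_empirical,
              if (x$significant) " *" else ""))
  cat("  Bonferroni: n = ", x$n_comparisons, ", corrected alpha = ",
      x$alpha_corrected, "\n", sep = "")
  invisible(x)
}

#' Persist bootstrap draws
#'
#' Writes the draws as a two-column CSV (`w`, `p`) with a JSON sidecar
#' recording seed, iterations and mode.
#'
#' @param sample A `bootstrap_sample`.
#' @param path CSV output path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(sample, path) {
  utils::write.csv(data.frame(w = sample$w_draws, p = sample$p_draws),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = sample$seed, iterations = sample$iterations,
               mode = sample$mode, p_true = sample$p_true,
               group_label = sample$group_label,
               n_converged = sum(sample$converged))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
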