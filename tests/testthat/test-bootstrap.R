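sim_table <- function(seed = 5, n_subjects = 57, group = "C", w = 0.66) {
  des <- one_group_design(group)
  obs <- observer_spec(stats::setNames(w, group))
  cfg <- simulation_config(des, n_subjects, obs, seed = seed)
  aggregate_responses(simulate_experiment(cfg), group)
}

test_that("bootstrap is deterministic and prefix-stable in its seed", {
  tab <- sim_table()
  b1 <- bootstrap_fit(tab, iterations = 200, seed = 9)
  b2 <- bootstrap_fit(tab, iterations = 200, seed = 9)
  expect_identical(b1$w_draws, b2$w_draws)
  b3 <- bootstrap_fit(tab, iterations = 50, seed = 9)
  # growing the iteration count must not reshuffle earlier draws
  expect_identical(b3$w_draws, b1$w_draws[1:50])
  b4 <- bootstrap_fit(tab, iterations = 200, seed = 10)
  expect_false(identical(b4$w_draws, b1$w_draws))
})

test_that("identical responses per pair collapse the bootstrap", {
  # every participant gives the same response per pair: resampling can
  # only reproduce the observed counts, so all draws coincide
  eta <- c(800, 1000, 1300, 1700, 2400)
  tab <- make_table(eta, c(0, 0, 57, 57, 57), 57, p_true = 1300)
  tab$responses <- lapply(tab$k_thicker / tab$n_total,
                          function(f) rep(as.integer(f), 57))
  tab$participants <- rep(list(sprintf("s%03d", 1:57)), 5)
  # the step-function data pins w at its lower bound every iteration, so
  # every refit is flagged non-converged (hence the warning) but the draw
  # distribution is exactly degenerate
  bs <- suppressWarnings(bootstrap_fit(tab, iterations = 100, seed = 1))
  expect_equal(length(unique(bs$w_draws)), 1L)
  ci <- percentile_interval(bs$w_draws, 95)
  expect_equal(ci$upper - ci$lower, 0)
})

test_that("batch refitter agrees with the scalar optimizer", {
  tab <- sim_table(seed = 31)
  bs <- bootstrap_fit(tab, iterations = 40, seed = 2)
  # reconstruct selected resamples via the same seed stream and refit
  # them with the scalar optimizer
  iter_seeds <- viscoweber:::with_local_seed(2,
    sample.int(.Machine$integer.max - 1L, 40))
  for (i in c(1, 7, 23, 40)) {
    k_i <- viscoweber:::with_local_seed(iter_seeds[i], vapply(
      seq_len(nrow(tab)), function(j) {
        resp <- tab$responses[[j]]
        n <- tab$n_total[j]
        sum(resp[sample.int(n, n, replace = TRUE)])
      }, integer(1)))
    tab_i <- make_table(tab$eta_cp, k_i, tab$n_total,
                        p_true = attr(tab, "reference_viscosity_cp"))
    ft <- fit_psychometric(tab_i, "fixed_p")
    expect_equal(bs$w_draws[i], ft$w, tolerance = 1e-4)
  }
})

test_that("percentile intervals match the order-statistic oracle and nest", {
  draws <- as.numeric(1:5000)
  ci <- percentile_interval(draws, 95)
  # type-7 order statistic at rank 1 + 0.025 * 4999
  expect_equal(ci$lower, 125.975, tolerance = 1e-9)
  expect_equal(ci$upper, 5000 - 124.975, tolerance = 1e-9)
  expect_equal(ci$mean, mean(draws))
  # independent sort-and-index check on irregular draws
  set.seed(4)
  x <- rlnorm(777)
  ci2 <- percentile_interval(x, 90)
  s <- sort(x)
  h <- 1 + 0.05 * (length(x) - 1)
  lo <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(ci2$lower, lo, tolerance = 1e-12)
  # constant draws
  cc <- percentile_interval(rep(2.5, 10), 95)
  expect_equal(c(cc$lower, cc$upper, cc$mean), rep(2.5, 3))
  # nesting 99.5 >= 99 >= 95
  c95 <- percentile_interval(x, 95)
  c99 <- percentile_interval(x, 99)
  c995 <- percentile_interval(x, 99.5)
  expect_lte(c995$lower, c99$lower)
  expect_lte(c99$lower, c95$lower)
  expect_gte(c995$upper, c99$upper)
  expect_gte(c99$upper, c95$upper)
  expect_error(percentile_interval(numeric(0), 95), "draws")
})

test_that("the CI-width exclusion rule follows the width-2 threshold", {
  keep <- structure(list(level = 95, lower = 1.01, upper = 2.24,
                         mean = 1.5), class = "interval_estimate")
  expect_false(exclude_poor_fit(keep))   # width 1.23
  drop <- structure(list(level = 95, lower = 0.5, upper = 2.6,
                         mean = 1.5), class = "interval_estimate")
  expect_true(exclude_poor_fit(drop))    # width 2.1
  edge <- structure(list(level = 95, lower = 0, upper = 2,
                         mean = 1), class = "interval_estimate")
  expect_true(exclude_poor_fit(edge))    # boundary counts as excluded
})

test_that("difference tests resolve constructed shifts and Bonferroni", {
  set.seed(12)
  a <- rnorm(2000, 1.0, 0.15)
  dt <- difference_test(a + 0.3, a, level = 99, n_comparisons = 10)
  expect_equal(dt$delta, 0.3, tolerance = 1e-12)
  expect_equal(dt$p_empirical, 2 / 2001, tolerance = 1e-12)  # floored
  expect_equal(dt$alpha_corrected, 0.005)
  expect_true(dt$significant)
  # zero difference: p = 1 under both flavours
  dt0 <- difference_test(a, a)
  expect_equal(dt0$delta, 0)
  expect_equal(dt0$p_normal, 1)
  expect_error(difference_test(a, a[1:10]), "iteration counts")
})

test_that("null difference tests are calibrated", {
  # emulate two bootstraps under a true null: each cohort's point
  # estimate varies around the common truth with SE 0.1, and its
  # bootstrap draws spread around that estimate with the same SE
  set.seed(77)
  hits <- 0L
  for (r in 1:200) {
    a <- rnorm(400, rnorm(1, 0.8, 0.1), 0.1)
    b <- rnorm(400, rnorm(1, 0.8, 0.1), 0.1)
    if (difference_test(a, b)$p_empirical < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.01)
  expect_lte(hits / 200, 0.10)
})

test_that("bias test works on free-p samples and degenerate data", {
  tab <- sim_table(seed = 41)
  bs <- bootstrap_fit(tab, iterations = 150, seed = 6, mode = "free_p")
  bt <- bias_test(bs, level = 95)
  # unbiased same-appearance simulation: CI should straddle 0 comfortably
  expect_lt(bt$ci$lower, bt$delta)
  expect_gt(bt$ci$upper, bt$delta)
  expect_error(bias_test(bootstrap_fit(tab, iterations = 50, seed = 1)),
               "free_p")
  # degenerate: every draw at the reference -> delta 0, p 1
  fake <- structure(list(iterations = 100, w_draws = rep(0.7, 100),
                         p_draws = rep(1560, 100),
                         converged = rep(TRUE, 100), seed = 1,
                         mode = "free_p", p_true = 1560,
                         group_label = "C"),
                    class = "bootstrap_sample")
  bt0 <- bias_test(fake)
  expect_equal(bt0$delta, 0)
  expect_equal(bt0$p_normal, 1)
})

test_that("bootstrap draws persist with their sidecar", {
  tab <- sim_table(seed = 51)
  bs <- bootstrap_fit(tab, iterations = 60, seed = 3)
  tmp <- tempfile(fileext = ".csv")
  write_bootstrap(bs, tmp)
  draws <- utils::read.csv(tmp)
  expect_equal(draws$w, bs$w_draws)
  meta <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(meta$seed, 3)
  expect_equal(meta$mode, "fixed_p")
})
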