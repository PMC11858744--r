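test_that("stimulus table loads, validates, and matches the shipped fixture", {
  path <- system.file("extdata", "stimuli_table.csv", package = "viscoweber")
  stim <- load_stimulus_table(path)
  expect_equal(nrow(stim), 42L)
  expect_identical(stim, silicone_stimuli())
  # printed sample-4 values: transparent 547 cP, opaque 544 cP
  expect_equal(stim$viscosity_cp[stim$sample_id == 4 &
                                   stim$appearance == "transparent"], 547)
  expect_equal(stim$viscosity_cp[stim$sample_id == 4 &
                                   stim$appearance == "opaque"], 544)

  bad <- silicone_stimuli()
  bad$viscosity_cp[1] <- -1
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_stimulus_table(tmp), "non-positive viscosity")
  dup <- rbind(silicone_stimuli(), silicone_stimuli()[1, ])
  utils::write.csv(dup, tmp, row.names = FALSE)
  expect_error(load_stimulus_table(tmp), "duplicate")
})

test_that("group designs resolve the printed reference/test sets", {
  stim <- silicone_stimuli()
  gt <- build_group_designs(stim, reference_appearance = "transparent")
  expect_equal(gt$A$reference$viscosity_cp, 547)
  expect_equal(gt$A$tests$viscosity_cp, c(153, 179, 272, 620, 756, 1040))
  go <- build_group_designs(stim, reference_appearance = "opaque")
  expect_equal(go$E$reference$viscosity_cp, 16850)
  expect_equal(go$E$tests$viscosity_cp,
               c(7420, 10630, 14140, 20440, 25650, 33810))
  # every group brackets its reference 3 below / 3 above
  for (g in gt) {
    expect_equal(sum(g$tests$viscosity_cp < g$reference$viscosity_cp), 3L)
    expect_equal(sum(g$tests$viscosity_cp > g$reference$viscosity_cp), 3L)
  }
  # all tests on one side violates the bracketing invariant
  bad_grouping <- list(A = list(reference = 7L, tests = 1:6))
  expect_error(build_group_designs(stim, bad_grouping), "bracket")
})

test_that("pair enumeration reproduces the task trial counts", {
  stim <- silicone_stimuli()
  gt <- build_group_designs(stim, reference_appearance = "transparent")
  go <- build_group_designs(stim, reference_appearance = "opaque")
  gm <- build_group_designs(stim, reference_appearance = "opaque",
                            test_appearance = "transparent")
  # same-appearance tasks share 3 boundary pairs across adjacent groups
  expect_equal(nrow(enumerate_pairs(gt, TRUE, "within_appearance")), 32L)
  expect_equal(nrow(enumerate_pairs(go, TRUE, "within_appearance")), 32L)
  # mixed appearance: no physical overlap, all 5 x 7 pairs distinct
  expect_equal(nrow(enumerate_pairs(gm, TRUE, "none")), 35L)
  # single group without the catch pair: plain 6 tests
  expect_equal(nrow(enumerate_pairs(gt["C"], FALSE, "within_appearance")), 6L)
  # design configs round through JSON
  d1a <- read_design_config(system.file("extdata", "design_task1a.json",
                                        package = "viscoweber"))
  expect_equal(nrow(d1a), 32L)
  d1c <- read_design_config(system.file("extdata", "design_task1c.json",
                                        package = "viscoweber"))
  expect_equal(nrow(d1c), 35L)
})

test_that("trial files round-trip and duplicates are rejected", {
  cfg <- scenario("task1a", seed = 8)
  cfg$n_subjects <- 3L
  trials <- simulate_experiment(cfg)
  tmp <- tempfile(fileext = ".csv")
  write_trials(trials, tmp)
  back <- read_trials(tmp)
  expect_equal(back, trials)
  dup <- rbind(trials, trials[1, ])
  expect_error(write_trials(dup, tmp), "duplicate")
  # schema mismatch
  tmp2 <- tempfile(fileext = ".csv")
  utils::write.csv(trials[, -1], tmp2, row.names = FALSE)
  expect_error(read_trials(tmp2), "missing column")
})

test_that("degenerate responders are flagged, real observers are not", {
  cfg <- scenario("task1a", seed = 21)
  cfg$n_subjects <- 50L
  trials <- simulate_experiment(cfg)
  # an ideal observer (w = 0.5) answers all-test / all-one-side with
  # probability below 1e-6 on this design: check the binomial bound
  des <- cfg$design
  pr <- psychometric_prob(des$test_viscosity_cp[1], 0.5,
                          des$reference_viscosity_cp[1])
  probs <- mapply(psychometric_prob, des$test_viscosity_cp,
                  p = des$reference_viscosity_cp,
                  MoreArgs = list(w = 0.5))
  expect_lt(prod(probs), 1e-6)        # always test
  expect_lt(prod(1 - probs), 1e-6)    # always reference
  expect_lt(0.5^nrow(des), 1e-6)      # always left / right

  rep <- screen_participants(trials)
  expect_equal(nrow(rep), 50L)
  expect_false(any(rep$flagged))

  # force one stereotyped responder
  forced <- trials
  forced$response_test_thicker[forced$participant_id == "s001"] <- 1L
  rep2 <- screen_participants(forced)
  expect_true(rep2$always_test[rep2$participant_id == "s001"])
  expect_true(rep2$flagged[rep2$participant_id == "s001"])
  # and one side-locked responder: reference chosen iff reference on left
  forced2 <- trials
  sel <- forced2$participant_id == "s002"
  forced2$response_test_thicker[sel] <-
    ifelse(forced2$reference_side[sel] == "left", 0L, 1L)
  rep3 <- screen_participants(forced2)
  expect_true(rep3$always_left[rep3$participant_id == "s002"])
})

test_that("aggregation counts, conserves, and is order-invariant", {
  cfg <- scenario("task1a", seed = 13)
  trials <- simulate_experiment(cfg)
  tab <- aggregate_responses(trials, "A")
  expect_s3_class(tab, "response_table")
  expect_equal(tab$eta_cp, sort(tab$eta_cp))
  expect_true(all(tab$k_thicker >= 0 & tab$k_thicker <= tab$n_total))
  expect_equal(attr(tab, "reference_viscosity_cp"), 547)
  # conservation: sum of k equals the raw count of test-thicker responses
  in_a <- trials$group_label == "A"
  expect_equal(sum(tab$k_thicker), sum(trials$response_test_thicker[in_a]))
  # n per row = number of participants who saw the pair
  expect_equal(tab$n_total, vapply(tab$participants, length, integer(1)))
  # permutation invariance
  set.seed(1)
  shuffled <- trials[sample(nrow(trials)), ]
  tab2 <- aggregate_responses(shuffled, "A")
  expect_equal(tab2$eta_cp, tab$eta_cp)
  expect_equal(tab2$k_thicker, tab$k_thicker)
  expect_error(aggregate_responses(trials[0, ], "A"), "no trials")
  # simulation oracle: empirical frequencies near model probabilities
  big <- scenario("task1a", seed = 3)
  big$n_subjects <- 2000L
  btr <- simulate_experiment(big)
  btab <- aggregate_responses(btr, "C")
  f_true <- psy_ref(btab$eta_cp, 0.57, 1560)
  se <- sqrt(f_true * (1 - f_true) / btab$n_total)
  expect_true(all(abs(btab$k_thicker / btab$n_total - f_true) < 3.5 * se))
})

test_that("per-subject percentages are exact and baseline-centred", {
  cfg <- scenario("task1a", seed = 17)
  trials <- simulate_experiment(cfg)
  pct <- per_subject_percentages(trials)
  expect_true(all(pct$pct_test_thicker >= 0 & pct$pct_test_thicker <= 100))
  # cross-check one cell by hand
  d <- trials[trials$participant_id == "s001" & trials$group_label == "A", ]
  expect_equal(pct$pct_test_thicker[pct$participant_id == "s001" &
                                      pct$group_label == "A"],
               100 * mean(d$response_test_thicker))
  # 3 of 7 -> 42.857%
  toy <- trials[trials$participant_id == "s001" &
                  trials$group_label == "A", ][1:7, ]
  toy$response_test_thicker <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L)
  toy_pct <- per_subject_percentages(toy)
  expect_equal(toy_pct$pct_test_thicker, 300 / 7, tolerance = 1e-12)
  # unbiased cohort: group means sit near their model expectation (the
  # pair sets are not log-symmetric around the reference, so the
  # expectation itself is near, not exactly at, 50%)
  cfg2 <- scenario("task1a")
  des <- cfg2$design
  w_map <- cfg2$observer$w_by_group
  f <- psy_ref(des$test_viscosity_cp, w_map[des$group_label],
               des$reference_viscosity_cp)
  expected <- 100 * tapply(f, des$group_label, mean)
  grp_mean <- tapply(pct$pct_test_thicker, pct$group_label, mean)
  npair <- table(des$group_label)[names(grp_mean)]
  se <- 100 * sqrt(0.25 / (57 * as.integer(npair)))
  expect_true(all(abs(grp_mean - expected[names(grp_mean)]) < 3.5 * se))
})
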