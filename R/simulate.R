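#' Synthetic 2AFC observer specification
#'
#' Describes the generative observer the simulator draws responses from:
#' group-specific Weber fractions, an appearance-dependent perceived-
#' viscosity gain (the bias mechanism: a transparent fluid with
#' `appearance_gain["transparent"] < appearance_gain["opaque"]` looks
#' thinner than an opaque fluid of equal physical viscosity), an optional
#' symmetric lapse rate, and log-normal between-subject heterogeneity on
#' both the Weber fraction and the gain.
#'
#' @param w_by_group Named numeric vector of Weber fractions, one per group
#'   label.
#' @param appearance_gain Named vector with entries `transparent` and
#'   `opaque`. Under the default multiplicative `bias_model` these are
#'   dimensionless gains on perceived viscosity; under `"additive"` they
#'   are offsets in cP.
#' @param lapse Stimulus-independent random-response probability, in
#'   `[0, 0.1]`; enters as `lapse/2 + (1 - lapse) * f`. Default 0 (the
#'   analysis model has no lapse term).
#' @param subject_sd_logw,subject_sd_logbeta SDs of per-subject log-normal
#'   perturbations of `w` and the gains; 0 = homogeneous population.
#' @param bias_model `"multiplicative"` (default) or `"additive"`.
#' @return List of class `observer_spec`.
#' @export
observer_spec <- function(w_by_group,
                          appearance_gain = c(transparent = 1, opaque = 1),
                          lapse = 0,
                          subject_sd_logw = 0,
                          subject_sd_logbeta = 0,
                          bias_model = c("multiplicative", "additive")) {
  bias_model <- match.arg(bias_model)
  stopifnot(all(w_by_group > 0), !is.null(names(w_by_group)),
            all(c("transparent", "opaque") %in% names(appearance_gain)),
            lapse >= 0, lapse <= 0.1,
            subject_sd_logw >= 0, subject_sd_logbeta >= 0)
  if (bias_model == "multiplicative" && any(appearance_gain <= 0)) {
    stop("multiplicative gains must be positive")
  }
  structure(list(w_by_group = w_by_group,
                 appearance_gain = appearance_gain,
                 lapse = lapse,
                 subject_sd_logw = subject_sd_logw,
                 subject_sd_logbeta = subject_sd_logbeta,
                 bias_model = bias_model),
            class = "observer_spec")
}

perceived_viscosity <- function(eta, gain, bias_model) {
  out <- switch(bias_model,
                multiplicative = gain * eta,
                additive = eta + gain)
  pmax(out, .Machine$double.eps)
}

#' Response probability of a (realized) synthetic observer
#'
#' Probability of judging the test thicker for one stimulus pair:
#' `lapse/2 + (1 - lapse) * f(perceived test; p = perceived reference, w)`
#' where perception applies the appearance gain to each side. With unit
#' gains and zero lapse this reduces exactly to [psychometric_prob()].
#'
#' @param test_viscosity_cp,reference_viscosity_cp Physical viscosities (cP).
#' @param test_appearance,reference_appearance `"transparent"` / `"opaque"`.
#' @param w Weber fraction of the (realized) observer for this group.
#' @param observer An [observer_spec()] supplying gains, lapse and bias
#'   model (subject-level perturbations, if any, must already be folded
#'   into `w` and the gains passed via `gain_override`).
#' @param gain_override Optional named vector replacing the spec's gains
#'   (used internally for heterogeneous subjects).
#' @return Probability in (0, 1).
#' @export
response_probability <- function(test_viscosity_cp, reference_viscosity_cp,
                                 test_appearance, reference_appearance,
                                 w, observer, gain_override = NULL) {
  gains <- if (is.null(gain_override)) observer$appearance_gain else gain_override
  eta_perc <- perceived_viscosity(test_viscosity_cp, gains[[test_appearance]],
                                  observer$bias_model)
  p_perc <- perceived_viscosity(reference_viscosity_cp,
                                gains[[reference_appearance]],
                                observer$bias_model)
  observer$lapse / 2 +
    (1 - observer$lapse) * psychometric_prob(eta_perc, w, p_perc)
}

#' Simulation configuration
#'
#' @param design An `experiment_design` from [enumerate_pairs()].
#' @param n_subjects Number of simulated participants (>= 1).
#' @param observer An [observer_spec()].
#' @param seed Integer seed; the simulation is a pure function of
#'   (design, observer, n_subjects, seed).
#' @param task_id Task label stamped on the trials.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(design, n_subjects, observer, seed = 1L,
                              task_id = attr(design, "task_id")) {
  stopifnot(inherits(design, "experiment_design"), n_subjects >= 1,
            inherits(observer, "observer_spec"))
  groups <- unique(design$group_label)
  missing_w <- setdiff(groups, names(observer$w_by_group))
  if (length(missing_w) > 0L) {
    stop("observer lacks Weber fractions for group(s): ",
         paste(missing_w, collapse = ", "))
  }
  if (is.null(task_id) || is.na(task_id)) task_id <- "sim"
  structure(list(design = design, n_subjects = as.integer(n_subjects),
                 observer = observer, seed = as.integer(seed),
                 task_id = task_id),
            class = "simulation_config")
}

#' Simulate a full 2AFC experiment
#'
#' Realizes per-subject parameters (log-normal perturbations of the Weber
#' fractions and appearance gains), draws one Bernoulli response per
#' design pair per subject from [response_probability()], and randomizes
#' the side the reference appears on. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return Trial data.frame in the schema of [read_trials()],
#'   `n_subjects * nrow(design)` rows.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  des <- config$design
  obs <- config$observer
  n_pairs <- nrow(des)
  with_local_seed(config$seed, {
    resp <- matrix(0L, nrow = n_pairs, ncol = config$n_subjects)
    side <- matrix("", nrow = n_pairs, ncol = config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      w_s <- obs$w_by_group *
        exp(stats::rnorm(length(obs$w_by_group), 0, obs$subject_sd_logw))
      gain_s <- obs$appearance_gain *
        exp(stats::rnorm(length(obs$appearance_gain), 0,
                         obs$subject_sd_logbeta))
      # vectorized over pairs; equals response_probability() element-wise
      eta_perc <- perceived_viscosity(des$test_viscosity_cp,
                                      gain_s[des$test_appearance],
                                      obs$bias_model)
      p_perc <- perceived_viscosity(des$reference_viscosity_cp,
                                    gain_s[des$reference_appearance],
                                    obs$bias_model)
      pr <- obs$lapse / 2 + (1 - obs$lapse) *
        stats::pnorm(log(eta_perc / p_perc) /
                       log1p(w_s[des$group_label]))
      resp[, s] <- as.integer(stats::runif(n_pairs) < pr)
      side[, s] <- sample(c("left", "right"), n_pairs, replace = TRUE)
    }
    trials <- data.frame(
      participant_id = rep(sprintf("s%03d", seq_len(config$n_subjects)),
                           each = n_pairs),
      task_id = config$task_id,
      group_label = rep(des$group_label, config$n_subjects),
      reference_viscosity_cp = rep(des$reference_viscosity_cp,
                                   config$n_subjects),
      test_viscosity_cp = rep(des$test_viscosity_cp, config$n_subjects),
      reference_appearance = rep(des$reference_appearance,
                                 config$n_subjects),
      test_appearance = rep(des$test_appearance, config$n_subjects),
      reference_side = as.vector(side),
      response_test_thicker = as.vector(resp),
      stringsAsFactors = FALSE
    )
    rownames(trials) <- NULL
    trials
  })
}

#' Preset simulation scenarios echoing the six study tasks
#'
#' Each scenario reproduces a task's participant count, stimulus design
#' (appearance pairing, pair de-duplication) and plausible group Weber
#' fractions; the mixed-appearance scenarios add the transparent-looks-
#' thinner gain so that the free-p fit recovers a PSE above the opaque
#' reference. Weber fractions echo the fitted study values; for the
#' opaque visual group E, where the study curve was too flat to fit, the
#' scenario uses a large value (2.5) so the exclusion rule engages.
#'
#' @param name One of `"task1a"`, `"task1b"`, `"task1c"`, `"task2"`,
#'   `"task3a"`, `"task3b"`.
#' @param seed Seed stored in the returned config.
#' @param stimuli Stimulus table (defaults to the built-in one).
#' @return A [simulation_config()].
#' @export
scenario <- function(name = c("task1a", "task1b", "task1c",
                              "task2", "task3a", "task3b"),
                     seed = 1L, stimuli = silicone_stimuli()) {
  name <- match.arg(name)
  grouping <- default_grouping()
  same_design <- function(app) {
    groups <- build_group_designs(stimuli, grouping,
                                  reference_appearance = app)
    enumerate_pairs(groups, include_equal_pair = TRUE,
                    dedup = "within_appearance", task_id = name)
  }
  mixed_design <- function() {
    groups <- build_group_designs(stimuli, grouping,
                                  reference_appearance = "opaque",
                                  test_appearance = "transparent")
    enumerate_pairs(groups, include_equal_pair = TRUE,
                    dedup = "none", task_id = name)
  }
  w_visual_t <- c(A = 1.00, B = 0.78, C = 0.57, D = 1.05, E = 1.43)
  w_visual_o <- c(A = 0.87, B = 0.61, C = 0.77, D = 1.06, E = 2.5)
  w_haptic <- c(A = 1.05, B = 1.08, C = 0.66, D = 0.82, E = 0.74)
  w_multi <- c(A = 1.29, B = 0.86, C = 0.63, D = 0.54, E = 0.62)
  # transparent fluids look ~2.6x thinner: an opaque 544 cP reference
  # matches a transparent test near 544/0.38 ~ 1432 cP
  gain_bias <- c(transparent = 0.38, opaque = 1)
  gain_multi <- c(transparent = 0.7, opaque = 1)  # haptics dilute the bias
  gain_none <- c(transparent = 1, opaque = 1)

  preset <- switch(name,
    task1a = list(design = same_design("transparent"), n = 57L,
                  obs = observer_spec(w_visual_t, gain_none)),
    task1b = list(design = same_design("opaque"), n = 57L,
                  obs = observer_spec(w_visual_o, gain_none)),
    task1c = list(design = mixed_design(), n = 110L,
                  obs = observer_spec(w_visual_t, gain_bias)),
    task2 = list(design = same_design("transparent"), n = 64L,
                 obs = observer_spec(w_haptic, gain_none)),
    task3a = list(design = same_design("transparent"), n = 50L,
                  obs = observer_spec(w_multi, gain_none)),
    task3b = list(design = mixed_design(), n = 50L,
                  obs = observer_spec(w_multi, gain_multi))
  )
  simulation_config(preset$design, preset$n, preset$obs, seed = seed,
                    task_id = name)
}
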