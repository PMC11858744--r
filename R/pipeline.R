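#' Pipeline configuration
#'
#' Bundles every tunable of the simulate / fit / bootstrap / compare /
#' report pipeline. Defaults are the analysis-wide conventions: 5000
#' bootstrap iterations, 95% reporting CIs, comparison CIs at
#' `100 - 100 * alpha / n` for a Bonferroni family of size `n` (five
#' reference-wise bias comparisons, ten pairwise Weber comparisons at base
#' alpha 0.05), fit box `w` in `[0.1, 100]`, `p` in `[10, 20500]` cP,
#' start `(0.5, p_true)`, and the CI-width-2 exclusion rule. Every run
#' writes a resolved-config snapshot next to its artifacts.
#'
#' @param out_dir Output directory for all artifacts.
#' @param scenario_name Preset scenario to simulate (see [scenario()]);
#'   `NULL` when analysing an existing trials file.
#' @param trials_path Existing trials CSV; defaults to
#'   `file.path(out_dir, "trials.csv")` (written by the simulate step).
#' @param iterations Bootstrap iterations.
#' @param seed Root seed for simulation and bootstrap.
#' @param ci_level Reporting CI level (percent).
#' @param alpha Base significance level before Bonferroni correction.
#' @param n_bias_comparisons,n_weber_comparisons Bonferroni family sizes
#'   (the tool never infers them from the data).
#' @param constraints A [fit_constraints()] object.
#' @param exclusion_threshold Weber-CI width at/above which a fit is
#'   reported as N/A.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            scenario_name = NULL,
                            trials_path = NULL,
                            iterations = 5000,
                            seed = 1L,
                            ci_level = 95,
                            alpha = 0.05,
                            n_bias_comparisons = 5L,
                            n_weber_comparisons = 10L,
                            constraints = fit_constraints(),
                            exclusion_threshold = 2) {
  structure(list(out_dir = out_dir, scenario_name = scenario_name,
                 trials_path = trials_path %||% file.path(out_dir, "trials.csv"),
                 iterations = iterations, seed = as.integer(seed),
                 ci_level = ci_level, alpha = alpha,
                 n_bias_comparisons = n_bias_comparisons,
                 n_weber_comparisons = n_weber_comparisons,
                 constraints = constraints,
                 exclusion_threshold = exclusion_threshold),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plog <- function(cfg, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = file.path(cfg$out_dir, "pipeline.log"),
      append = TRUE)
  message(msg)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "'; run the '", produced_by,
         "' step first", call. = FALSE)
  }
  path
}

snapshot_config <- function(cfg) {
  snap <- cfg
  snap$constraints <- unclass(snap$constraints)
  jsonlite::write_json(unclass(snap),
                       file.path(cfg$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

pipeline_load_trials <- function(cfg) {
  read_trials(require_artifact(cfg$trials_path, "simulate"))
}

# a mixed-appearance pair means the task measures a PSE: fit p freely
infer_mode <- function(trials) {
  if (any(trials$reference_appearance != trials$test_appearance)) {
    "free_p"
  } else {
    "fixed_p"
  }
}

step_simulate <- function(cfg) {
  if (is.null(cfg$scenario_name)) {
    stop("simulate step needs a scenario_name in the config")
  }
  sim <- scenario(cfg$scenario_name, seed = cfg$seed)
  trials <- simulate_experiment(sim)
  write_trials(trials, cfg$trials_path)
  plog(cfg, "simulate: ", nrow(trials), " trials (", sim$n_subjects,
       " subjects x ", nrow(sim$design), " pairs) -> ", cfg$trials_path)
  invisible(trials)
}

step_fit <- function(cfg) {
  trials <- pipeline_load_trials(cfg)
  mode <- infer_mode(trials)
  groups <- sort(unique(trials$group_label))
  fits <- lapply(groups, function(g) {
    tab <- aggregate_responses(trials, g)
    ft <- fit_psychometric(tab, mode = mode,
                           constraints = cfg$constraints)
    list(group = g, p_true = ft$p_true, mode = ft$mode, w = ft$w, p = ft$p,
         loglik = ft$log_likelihood, converged = ft$converged,
         n_points = ft$n_points)
  })
  names(fits) <- groups
  jsonlite::write_json(fits, file.path(cfg$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  plog(cfg, "fit (", mode, "): groups ", paste(groups, collapse = ", "))
  invisible(fits)
}

step_bootstrap <- function(cfg) {
  trials <- pipeline_load_trials(cfg)
  mode <- infer_mode(trials)
  groups <- sort(unique(trials$group_label))
  for (i in seq_along(groups)) {
    g <- groups[i]
    tab <- aggregate_responses(trials, g)
    bs <- bootstrap_fit(tab, iterations = cfg$iterations,
                        seed = cfg$seed + i, mode = mode,
                        constraints = cfg$constraints)
    write_bootstrap(bs, file.path(cfg$out_dir,
                                  paste0("bootstrap_", g, ".csv")))
    plog(cfg, "bootstrap: group ", g, ", ", cfg$iterations,
         " iterations, ", sum(bs$converged), " converged")
  }
  invisible(groups)
}

read_bootstrap_csv <- function(cfg, g) {
  path <- require_artifact(file.path(cfg$out_dir,
                                     paste0("bootstrap_", g, ".csv")),
                           "bootstrap")
  draws <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(iterations = nrow(draws), w_draws = draws$w,
                 p_draws = draws$p, converged = rep(TRUE, nrow(draws)),
                 seed = meta$seed, mode = meta$mode, p_true = meta$p_true,
                 group_label = g),
            class = "bootstrap_sample")
}

step_compare <- function(cfg) {
  trials <- pipeline_load_trials(cfg)
  groups <- sort(unique(trials$group_label))
  samples <- lapply(groups, read_bootstrap_csv, cfg = cfg)
  names(samples) <- groups

  weber_level <- 100 - 100 * cfg$alpha / cfg$n_weber_comparisons
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  weber <- lapply(pairs, function(pr) {
    dt <- difference_test(samples[[pr[1]]], samples[[pr[2]]], "w",
                          level = weber_level,
                          n_comparisons = cfg$n_weber_comparisons,
                          alpha = cfg$alpha)
    list(group_a = pr[1], group_b = pr[2], delta = dt$delta,
         ci_level = dt$ci$level, ci_lower = dt$ci$lower,
         ci_upper = dt$ci$upper, p_normal = dt$p_normal,
         p_empirical = dt$p_empirical, significant = dt$significant)
  })

  bias <- NULL
  if (samples[[1]]$mode == "free_p") {
    bias_level <- 100 - 100 * cfg$alpha / cfg$n_bias_comparisons
    bias <- lapply(groups, function(g) {
      bt <- bias_test(samples[[g]], level = bias_level,
                      n_comparisons = cfg$n_bias_comparisons,
                      alpha = cfg$alpha)
      list(group = g, reference_cp = samples[[g]]$p_true, delta = bt$delta,
           ci_level = bt$ci$level, ci_lower = bt$ci$lower,
           ci_upper = bt$ci$upper, p_normal = bt$p_normal,
           p_empirical = bt$p_empirical, significant = bt$significant)
    })
  }
  out <- list(weber_pairwise = weber, bias = bias)
  jsonlite::write_json(out, file.path(cfg$out_dir, "compare.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  plog(cfg, "compare: ", length(weber), " pairwise Weber tests",
       if (!is.null(bias)) paste0(", ", length(bias), " bias tests") else "")
  invisible(out)
}

step_report <- function(cfg) {
  trials <- pipeline_load_trials(cfg)
  groups <- sort(unique(trials$group_label))
  fits <- jsonlite::read_json(require_artifact(
    file.path(cfg$out_dir, "fits.json"), "fit"))
  samples <- lapply(groups, read_bootstrap_csv, cfg = cfg)
  names(samples) <- groups

  weber_rows <- lapply(groups, function(g) {
    ci <- percentile_interval(samples[[g]]$w_draws, cfg$ci_level)
    excluded <- exclude_poor_fit(ci, cfg$exclusion_threshold)
    w_hat <- fits[[g]]$w
    data.frame(
      group = g,
      reference_cp = round(fits[[g]]$p_true),
      weber_fraction = if (excluded) "N/A" else sprintf("%.2f", w_hat),
      ci = if (excluded) "N/A" else
        sprintf("%.2f-%.2f", ci$lower, ci$upper),
      excluded = excluded,
      stringsAsFactors = FALSE
    )
  })
  weber_table <- do.call(rbind, weber_rows)
  utils::write.csv(weber_table, file.path(cfg$out_dir, "weber_table.csv"),
                   row.names = FALSE, quote = FALSE)

  jnd_rows <- lapply(groups, function(g) {
    j <- weber_jnd(fits[[g]]$w, fits[[g]]$p)
    data.frame(group = g, reference_cp = round(fits[[g]]$p_true),
               jnd_lower_cp = round(j[["lower"]]),
               jnd_upper_cp = round(j[["upper"]]))
  })
  utils::write.csv(do.call(rbind, jnd_rows),
                   file.path(cfg$out_dir, "jnd_table.csv"),
                   row.names = FALSE, quote = FALSE)

  if (samples[[1]]$mode == "free_p") {
    bias_level <- 100 - 100 * cfg$alpha / cfg$n_bias_comparisons
    bias_rows <- lapply(groups, function(g) {
      bt <- bias_test(samples[[g]], level = bias_level,
                      n_comparisons = cfg$n_bias_comparisons,
                      alpha = cfg$alpha)
      data.frame(group = g, reference_cp = round(samples[[g]]$p_true),
                 pse_cp = round(fits[[g]]$p, 2),
                 delta_cp = round(bt$delta, 2),
                 ci_lower = round(bt$ci$lower, 2),
                 ci_upper = round(bt$ci$upper, 2),
                 p_normal = signif(bt$p_normal, 3),
                 significant = bt$significant)
    })
    utils::write.csv(do.call(rbind, bias_rows),
                     file.path(cfg$out_dir, "bias_table.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  pct <- per_subject_percentages(trials)
  utils::write.csv(pct, file.path(cfg$out_dir, "subject_percentages.csv"),
                   row.names = FALSE, quote = FALSE)
  screen <- screen_participants(trials)
  utils::write.csv(screen, file.path(cfg$out_dir, "subject_screening.csv"),
                   row.names = FALSE, quote = FALSE)
  plog(cfg, "report: weber_table (", nrow(weber_table), " rows), ",
       sum(screen$flagged), " flagged participant(s)")
  invisible(weber_table)
}

#' Run the analysis pipeline
#'
#' Executes one step (or `"all"`) of simulate -> fit -> bootstrap ->
#' compare -> report. Every step reads its inputs from, and writes its
#' artifacts to, `config$out_dir`, so the pipeline output is a pure
#' function of (trials, config, seed) and a step can be re-run in
#' isolation. Missing upstream artifacts raise an error naming the step
#' that produces them.
#'
#' @param config A [pipeline_config()].
#' @param subcommand One of `"simulate"`, `"fit"`, `"bootstrap"`,
#'   `"compare"`, `"report"`, `"all"`.
#' @return The last step's value, invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c("all", "simulate", "fit",
                                        "bootstrap", "compare", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  subcommand <- match.arg(subcommand)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  snapshot_config(config)
  steps <- if (subcommand == "all") {
    c(if (!is.null(config$scenario_name)) "simulate",
      "fit", "bootstrap", "compare", "report")
  } else {
    subcommand
  }
  res <- NULL
  for (s in steps) {
    res <- switch(s,
                  simulate = step_simulate(config),
                  fit = step_fit(config),
                  bootstrap = step_bootstrap(config),
                  compare = step_compare(config),
                  report = step_report(config))
  }
  invisible(res)
}
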