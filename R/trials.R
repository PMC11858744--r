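trial_columns <- c("participant_id", "task_id", "group_label",
                   "reference_viscosity_cp", "test_viscosity_cp",
                   "reference_appearance", "test_appearance",
                   "reference_side", "response_test_thicker")

validate_trials <- function(trials) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0L) {
    stop("trial table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(trials$response_test_thicker %in% c(0L, 1L, TRUE, FALSE))) {
    stop("response_test_thicker must be 0/1")
  }
  bad_side <- !trials$reference_side %in% c("left", "right", "first", "second")
  if (any(bad_side)) {
    stop("invalid reference_side at row(s): ",
         paste(which(bad_side), collapse = ", "))
  }
  if (any(trials$reference_viscosity_cp <= 0) ||
      any(trials$test_viscosity_cp <= 0)) {
    stop("viscosities must be positive")
  }
  # each physical pair is judged once per participant and task
  key <- paste(trials$participant_id, trials$task_id,
               trials$reference_viscosity_cp, trials$test_viscosity_cp,
               trials$reference_appearance, trials$test_appearance)
  if (anyDuplicated(key)) {
    stop("duplicate trial(s) at row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  invisible(trials)
}

#' Read trial-level 2AFC responses from CSV
#'
#' Long format, one row per trial. Columns: `participant_id`, `task_id`,
#' `group_label`, `reference_viscosity_cp`, `test_viscosity_cp`,
#' `reference_appearance`, `test_appearance`, `reference_side`
#' (left/right/first/second) and `response_test_thicker` (0/1). Each
#' participant judges a given physical pair once within a task; duplicates
#' are rejected.
#'
#' @param path CSV file path.
#' @return Validated trial data.frame.
#' @seealso [write_trials()], [simulate_experiment()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(trials)
  trials$response_test_thicker <- as.integer(trials$response_test_thicker)
  trials[trial_columns]
}

#' Write trial-level responses to CSV
#'
#' @param trials Trial data.frame (see [read_trials()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials[trial_columns]
  out$response_test_thicker <- as.integer(out$response_test_thicker)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screen for degenerate responders
#'
#' Flags (never removes) participants whose responses within a task are
#' 100% "test thicker", 100% "reference thicker", 100% left, or 100% right.
#' Such stereotyped responders would skew an aggregated population-level
#' curve and are surfaced for the analyst to inspect.
#'
#' @param trials Trial data.frame.
#' @return Data.frame with one row per participant x task: `n_trials`,
#'   the four `always_*` logical flags, and `flagged`.
#' @export
screen_participants <- function(trials) {
  validate_trials(trials)
  if (nrow(trials) == 0L) stop("no trials to screen")
  split_key <- interaction(trials$participant_id, trials$task_id, drop = TRUE)
  pieces <- split(trials, split_key)
  rows <- lapply(pieces, function(d) {
    resp <- as.integer(d$response_test_thicker)
    # side actually chosen: the reference side if the reference was judged
    # thicker, otherwise the opposite side
    chose_ref <- resp == 0L
    side <- ifelse(d$reference_side %in% c("left", "right"),
                   ifelse(chose_ref, d$reference_side,
                          ifelse(d$reference_side == "left", "right", "left")),
                   NA_character_)
    data.frame(
      participant_id = d$participant_id[1L],
      task_id = d$task_id[1L],
      n_trials = nrow(d),
      always_test = all(resp == 1L),
      always_reference = all(resp == 0L),
      always_left = !anyNA(side) && all(side == "left"),
      always_right = !anyNA(side) && all(side == "right"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$flagged <- out$always_test | out$always_reference |
    out$always_left | out$always_right
  out
}

#' Aggregate trials of one group into a response table
#'
#' Pools responses over participants for each test viscosity in a group,
#' giving the k-of-n "test thicker" counts the psychometric fit consumes.
#' The per-response participant identities and raw 0/1 vectors are retained
#' so the bootstrap can resample at the participant-response level.
#'
#' @param trials Trial data.frame, already filtered to one task.
#' @param group Group label (e.g. `"C"`).
#' @return A `response_table`: data.frame with one row per test viscosity
#'   (`eta_cp`, ascending), counts `k_thicker`, `n_total`, and list-columns
#'   `responses` (0/1 per participant) and `participants`. Attributes carry
#'   the group label and the true reference viscosity.
#' @export
aggregate_responses <- function(trials, group) {
  validate_trials(trials)
  d <- trials[trials$group_label == group, , drop = FALSE]
  if (nrow(d) == 0L) stop("no trials for group ", group)
  if (length(unique(d$task_id)) > 1L) {
    stop("trials span multiple tasks; filter to one task first")
  }
  p_true <- unique(d$reference_viscosity_cp)
  if (length(p_true) != 1L) {
    stop("group ", group, " has inconsistent reference viscosities")
  }
  etas <- sort(unique(d$test_viscosity_cp))
  rows <- lapply(etas, function(eta) {
    dd <- d[d$test_viscosity_cp == eta, , drop = FALSE]
    resp <- as.integer(dd$response_test_thicker)
    list(eta = eta, k = sum(resp), n = length(resp),
         responses = resp, participants = dd$participant_id)
  })
  tab <- data.frame(
    eta_cp = vapply(rows, `[[`, numeric(1), "eta"),
    k_thicker = vapply(rows, `[[`, integer(1), "k"),
    n_total = vapply(rows, `[[`, integer(1), "n")
  )
  tab$responses <- lapply(rows, `[[`, "responses")
  tab$participants <- lapply(rows, `[[`, "participants")
  structure(tab, group_label = group, reference_viscosity_cp = p_true,
            class = c("response_table", "data.frame"))
}

#' @export
print.response_table <- function(x, ...) {
  cat("Response table, group ", attr(x, "group_label"),
      " (reference ", attr(x, "reference_viscosity_cp"), " cP)\n", sep = "")
  print(data.frame(eta_cp = x$eta_cp, k_thicker = x$k_thicker,
                   n_total = x$n_total,
                   freq = round(x$k_thicker / x$n_total, 3)))
  invisible(x)
}

#' Per-subject percentage of "test thicker" responses
#'
#' One percentage per participant and group, the unit of the rank-based
#' robustness checks (aggregation-artefact controls). Participants with no
#' trials in a group get `NA` and a message.
#'
#' @param trials Trial data.frame, filtered to one task.
#' @return Data.frame `participant_id`, `group_label`, `n_trials`,
#'   `pct_test_thicker` (0-100).
#' @export
per_subject_percentages <- function(trials) {
  validate_trials(trials)
  if (length(unique(trials$task_id)) > 1L) {
    stop("trials span multiple tasks; filter to one task first")
  }
  participants <- unique(trials$participant_id)
  groups <- sort(unique(trials$group_label))
  grid <- expand.grid(participant_id = participants, group_label = groups,
                      stringsAsFactors = FALSE)
  key <- paste(trials$participant_id, trials$group_label)
  counts <- tapply(as.integer(trials$response_test_thicker), key, sum)
  totals <- tapply(rep(1L, nrow(trials)), key, sum)
  gkey <- paste(grid$participant_id, grid$group_label)
  grid$n_trials <- ifelse(is.na(totals[gkey]), 0L, totals[gkey])
  grid$pct_test_thicker <- 100 * counts[gkey] / totals[gkey]
  rownames(grid) <- NULL
  n_missing <- sum(grid$n_trials == 0L)
  if (n_missing > 0L) {
    message(n_missing, " participant-group cell(s) with no trials; NA returned")
  }
  grid
}
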