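#' Silicone-oil stimulus table
#'
#' The measured shear viscosities (cP) of the 21 silicone-oil stimulus
#' fluids, each prepared in a transparent and an opaque (zinc-oxide doped)
#' variant. These are the physical stimuli of the discrimination studies;
#' all designs are built by referencing `sample_id` + `appearance`.
#'
#' @return A data.frame with columns `sample_id` (integer), `appearance`
#'   (`"transparent"` or `"opaque"`) and `viscosity_cp` (positive numeric),
#'   42 rows.
#' @examples
#' head(silicone_stimuli())
#' @export
silicone_stimuli <- function() {
  transparent <- c(153, 179, 272, 547, 620, 756, 1040, 1130, 1290, 1560,
                   1930, 2580, 3520, 5520, 7060, 9480, 12950, 15530, 18930,
                   22780, 31160)
  opaque <- c(152, 202, 306, 544, 687, 827, 1110, 1230, 1420, 1710,
              2140, 2980, 4050, 5870, 7420, 10630, 14140, 16850, 20440,
              25650, 33810)
  data.frame(
    sample_id = rep(seq_len(21), 2L),
    appearance = rep(c("transparent", "opaque"), each = 21L),
    viscosity_cp = c(transparent, opaque),
    stringsAsFactors = FALSE
  )
}

#' Read a stimulus table from CSV
#'
#' Expects columns `sample_id`, `appearance`, `viscosity_cp`. Viscosities
#' must be strictly positive and `(sample_id, appearance)` unique.
#'
#' @param path Path to a CSV file.
#' @return Validated stimulus data.frame (see [silicone_stimuli()]).
#' @export
load_stimulus_table <- function(path) {
  if (!file.exists(path)) stop("stimulus table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "appearance", "viscosity_cp")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("stimulus table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab$sample_id <- as.integer(tab$sample_id)
  tab$viscosity_cp <- as.numeric(tab$viscosity_cp)
  validate_stimuli(tab)
  tab[required]
}

validate_stimuli <- function(tab) {
  bad_app <- !tab$appearance %in% c("transparent", "opaque")
  if (any(bad_app)) {
    stop("invalid appearance at row(s): ",
         paste(which(bad_app), collapse = ", "))
  }
  if (!is.numeric(tab$viscosity_cp) || anyNA(tab$viscosity_cp)) {
    stop("viscosity_cp must be numeric and non-missing")
  }
  bad_visc <- tab$viscosity_cp <= 0
  if (any(bad_visc)) {
    stop("non-positive viscosity at row(s): ",
         paste(which(bad_visc), collapse = ", "))
  }
  key <- paste(tab$sample_id, tab$appearance)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, appearance) at row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  invisible(tab)
}

#' Default constant-stimuli grouping
#'
#' Five groups (A-E), each a reference sample bracketed by six test samples
#' (three thinner, three thicker), expressed as stimulus sample ids. The
#' same id grouping applies to the transparent and the opaque stimulus
#' variants.
#'
#' @return Named list of groups; each group is a list with `reference`
#'   (sample id) and `tests` (six sample ids, ascending viscosity).
#' @export
default_grouping <- function() {
  list(
    A = list(reference = 4L,  tests = c(1L, 2L, 3L, 5L, 6L, 7L)),
    B = list(reference = 7L,  tests = c(4L, 5L, 6L, 8L, 9L, 10L)),
    C = list(reference = 10L, tests = c(7L, 8L, 9L, 11L, 12L, 13L)),
    D = list(reference = 13L, tests = c(10L, 11L, 12L, 14L, 15L, 16L)),
    E = list(reference = 18L, tests = c(15L, 16L, 17L, 19L, 20L, 21L))
  )
}

stimulus_lookup <- function(stimuli, sample_id, appearance) {
  row <- stimuli[stimuli$sample_id == sample_id &
                   stimuli$appearance == appearance, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown stimulus: sample_id=", sample_id, " appearance=", appearance)
  }
  row
}

#' Build constant-stimuli group designs
#'
#' Resolves a grouping of sample ids against a stimulus table into concrete
#' group designs. Reference and test sides may use different appearances
#' (mixed-appearance tasks pair an opaque reference with transparent tests).
#'
#' @param stimuli Stimulus table (see [silicone_stimuli()]).
#' @param grouping Named list of groups as returned by [default_grouping()].
#' @param reference_appearance,test_appearance `"transparent"` or `"opaque"`.
#' @return A list of group designs (class `group_design`), each with
#'   `label`, `reference` (one stimulus row) and `tests` (six stimulus
#'   rows, ascending viscosity).
#' @export
build_group_designs <- function(stimuli,
                                grouping = default_grouping(),
                                reference_appearance = "transparent",
                                test_appearance = reference_appearance) {
  validate_stimuli(stimuli)
  groups <- lapply(names(grouping), function(lab) {
    g <- grouping[[lab]]
    ref <- stimulus_lookup(stimuli, g$reference, reference_appearance)
    tests <- do.call(rbind, lapply(g$tests, stimulus_lookup,
                                   stimuli = stimuli,
                                   appearance = test_appearance))
    tests <- tests[order(tests$viscosity_cp), , drop = FALSE]
    rownames(tests) <- NULL
    if (anyDuplicated(tests$viscosity_cp)) {
      stop("group ", lab, ": duplicate test viscosities")
    }
    n_below <- sum(tests$viscosity_cp < ref$viscosity_cp)
    n_above <- sum(tests$viscosity_cp > ref$viscosity_cp)
    if (n_below == 0L || n_above == 0L) {
      stop("group ", lab, ": tests must bracket the reference (",
           n_below, " below, ", n_above, " above)")
    }
    equal_test <- stimulus_lookup(stimuli, g$reference, test_appearance)
    structure(list(label = lab, reference = ref, tests = tests,
                   equal_test = equal_test),
              class = "group_design")
  })
  names(groups) <- names(grouping)
  groups
}

#' @export
print.group_design <- function(x, ...) {
  cat("Group ", x$label, ": reference ", x$reference$viscosity_cp, " cP (",
      x$reference$appearance, "), tests ",
      paste(x$tests$viscosity_cp, collapse = ", "), " cP (",
      x$tests$appearance[1L], ")\n", sep = "")
  invisible(x)
}

#' Enumerate unique stimulus pairs of an experiment
#'
#' Expands group designs into the flat list of reference/test pairs an
#' observer judges. Optionally appends an equal-viscosity catch pair per
#' group (the test-side counterpart of the reference sample). Under
#' `dedup = "within_appearance"` a physical pair shared between two
#' adjacent groups (possible only when reference and test appearance
#' coincide, e.g. the 1710/1110 cP pairing sitting in both group B and C of
#' the opaque set) is kept once, in its first group.
#'
#' @param groups List of group designs from [build_group_designs()].
#' @param include_equal_pair Append the reference-vs-reference pair?
#' @param dedup `"within_appearance"` or `"none"`.
#' @param task_id Optional task label attached to the design.
#' @return Data.frame of class `experiment_design` with one row per unique
#'   pair: group label, reference and test sample id / appearance /
#'   viscosity, and `is_equal_pair`.
#' @export
enumerate_pairs <- function(groups, include_equal_pair = TRUE,
                            dedup = c("within_appearance", "none"),
                            task_id = NA_character_) {
  dedup <- match.arg(dedup)
  rows <- lapply(groups, function(g) {
    tests <- g$tests
    if (include_equal_pair) {
      # catch pair: the test-side variant of the reference sample
      tests <- rbind(tests, g$equal_test)
    }
    data.frame(
      group_label = g$label,
      reference_id = g$reference$sample_id,
      reference_appearance = g$reference$appearance,
      reference_viscosity_cp = g$reference$viscosity_cp,
      test_id = tests$sample_id,
      test_appearance = tests$appearance,
      test_viscosity_cp = tests$viscosity_cp,
      stringsAsFactors = FALSE
    )
  })
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  design$is_equal_pair <- design$reference_id == design$test_id
  if (dedup == "within_appearance") {
    a <- paste(design$reference_appearance, design$reference_id)
    b <- paste(design$test_appearance, design$test_id)
    key <- ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
    design <- design[!duplicated(key), , drop = FALSE]
    rownames(design) <- NULL
  }
  structure(design,
            task_id = task_id, dedup = dedup,
            include_equal_pair = include_equal_pair,
            class = c("experiment_design", "data.frame"))
}

#' Read an experiment design from a structured JSON config
#'
#' The config names the grouping (reference and test sample ids per group
#' label), the appearance of each side, whether the equal-viscosity catch
#' pair is included, and the pair de-duplication policy.
#'
#' @param path JSON config path.
#' @param stimuli Stimulus table the sample ids resolve against.
#' @return An `experiment_design` (see [enumerate_pairs()]).
#' @export
read_design_config <- function(path, stimuli = silicone_stimuli()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("groups", "reference_appearance", "test_appearance",
                "include_equal_pair", "dedup_policy")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L) {
    stop("design config missing key(s): ", paste(missing, collapse = ", "))
  }
  grouping <- lapply(cfg$groups, function(g) {
    list(reference = as.integer(g$reference), tests = as.integer(g$tests))
  })
  groups <- build_group_designs(stimuli, grouping,
                                reference_appearance = cfg$reference_appearance,
                                test_appearance = cfg$test_appearance)
  enumerate_pairs(groups,
                  include_equal_pair = isTRUE(cfg$include_equal_pair),
                  dedup = cfg$dedup_policy,
                  task_id = cfg$task_id %||% NA_character_)
}
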