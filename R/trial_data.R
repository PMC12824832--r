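#' Construct a nested longitudinal + survival trial dataset
#'
#' Bundles the three tables of a cluster randomized trial -- long-format
#' repeated measurements, one-row-per-subject survival records, and a
#' group table carrying the (cluster-level) treatment indicator -- into a
#' validated container. Subjects are nested in groups; repeated
#' measurements are nested in subjects.
#'
#' Identifiers are treated as opaque strings. A dense integer index
#' (subject 1..n, group 1..L, in first-appearance order of the survival
#' table) is built at construction time and stored in `$subjects` and
#' `$groups$group_index`, giving a stable, reproducible parameter
#' ordering for model fitting.
#'
#' @param longitudinal data frame with columns `subject_id`, `group_id`,
#'   `time` (years, >= 0), `y`, plus optional covariate columns.
#' @param survival data frame with columns `subject_id`, `group_id`,
#'   `observed_time` (years, > 0), `event` (0/1), plus optional covariates.
#' @param groups data frame with columns `group_id`, `treatment` (0/1),
#'   plus optional group-level covariates.
#' @return An object of class `trial_dataset`: a list with elements
#'   `longitudinal`, `survival`, `groups` (the input tables, with
#'   `subject_index`/`group_index` columns added) and `subjects` (the
#'   id-to-index map).
#' @export
trial_dataset <- function(longitudinal, survival, groups) {
  check_schema(longitudinal, c("subject_id", "group_id", "time", "y"), "longitudinal")
  check_schema(survival, c("subject_id", "group_id", "observed_time", "event"), "survival")
  check_schema(groups, c("group_id", "treatment"), "groups")

  if (nrow(longitudinal) == 0L) stop_mjm("schema", "no longitudinal records")
  if (nrow(survival) == 0L) stop_mjm("schema", "no survival records")

  longitudinal$subject_id <- as.character(longitudinal$subject_id)
  longitudinal$group_id <- as.character(longitudinal$group_id)
  survival$subject_id <- as.character(survival$subject_id)
  survival$group_id <- as.character(survival$group_id)
  groups$group_id <- as.character(groups$group_id)

  if (anyDuplicated(survival$subject_id))
    stop_mjm("duplicate", "duplicate subject_id in survival table (one record per subject required)")
  if (anyDuplicated(groups$group_id))
    stop_mjm("duplicate", "duplicate group_id in groups table")
  dup <- duplicated(longitudinal[, c("subject_id", "time")])
  if (any(dup))
    stop_mjm("duplicate", sprintf(
      "duplicate (subject_id, time) pairs in longitudinal table: %s",
      paste(utils::head(unique(longitudinal$subject_id[dup]), 5), collapse = ", ")))

  only_long <- setdiff(longitudinal$subject_id, survival$subject_id)
  only_surv <- setdiff(survival$subject_id, longitudinal$subject_id)
  if (length(only_long) || length(only_surv))
    stop_mjm("linkage", sprintf(
      "subjects present in one table but not the other (longitudinal-only: %d, survival-only: %d)",
      length(only_long), length(only_surv)))
  missing_grp <- setdiff(union(longitudinal$group_id, survival$group_id), groups$group_id)
  if (length(missing_grp))
    stop_mjm("linkage", sprintf("group ids missing from groups table: %s",
                                paste(utils::head(missing_grp, 5), collapse = ", ")))

  if (any(longitudinal$time < 0)) stop_mjm("domain", "longitudinal time must be >= 0")
  if (any(survival$observed_time <= 0)) stop_mjm("domain", "observed_time must be > 0")
  if (!all(survival$event %in% c(0, 1))) stop_mjm("domain", "event must be 0 or 1")
  if (!all(groups$treatment %in% c(0, 1))) stop_mjm("domain", "treatment must be 0 or 1")

  groups$group_index <- seq_len(nrow(groups))
  subjects <- data.frame(
    subject_id = survival$subject_id,
    group_id = survival$group_id,
    subject_index = seq_len(nrow(survival)),
    group_index = groups$group_index[match(survival$group_id, groups$group_id)],
    stringsAsFactors = FALSE
  )
  survival$subject_index <- subjects$subject_index
  survival$group_index <- subjects$group_index
  lmatch <- match(longitudinal$subject_id, subjects$subject_id)
  longitudinal$subject_index <- subjects$subject_index[lmatch]
  # the subject's canonical group (from the survival table) drives model
  # indexing; disagreement between tables is reported by validate_nesting()
  longitudinal$group_index <- subjects$group_index[lmatch]

  structure(
    list(longitudinal = longitudinal, survival = survival,
         groups = groups, subjects = subjects),
    class = "trial_dataset"
  )
}

check_schema <- function(df, required, name) {
  if (!is.data.frame(df)) stop_mjm("schema", sprintf("%s must be a data frame", name))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_mjm("schema", sprintf("%s table is missing required column(s): %s",
                               name, paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Read a trial dataset from three CSV files
#'
#' Expects the documented schemas: `longitudinal.csv`
#' (`subject_id,group_id,time,y[,<covariate>...]`), `survival.csv`
#' (`subject_id,group_id,observed_time,event[,<covariate>...]`) and
#' `groups.csv` (`group_id,treatment[,<covariate>...]`); comma-delimited,
#' UTF-8, header row, `.` decimal separator.
#'
#' @param long_path,surv_path,group_path paths to the three CSV files.
#' @return A validated [trial_dataset()].
#' @export
read_trial <- function(long_path, surv_path, group_path) {
  for (p in c(long_path, surv_path, group_path))
    if (!file.exists(p)) stop_mjm("io", sprintf("file not found: %s", p))
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = NA, check.names = FALSE)
  trial_dataset(rd(long_path), rd(surv_path), rd(group_path))
}

#' Write a trial dataset to three CSV files
#'
#' Numeric fields are written with 15 significant digits, so a
#' read/write round trip is lossless well beyond 12 significant digits.
#'
#' @param data a [trial_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_trial <- function(data, dir) {
  stopifnot(inherits(data, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drop_idx <- function(df) df[, setdiff(names(df), c("subject_index", "group_index")), drop = FALSE]
  paths <- file.path(dir, c("longitudinal.csv", "survival.csv", "groups.csv"))
  tabs <- list(drop_idx(data$longitudinal), drop_idx(data$survival), drop_idx(data$groups))
  for (i in seq_along(paths)) {
    df <- tabs[[i]]
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
    utils::write.csv(df, paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Validate the three-level nesting of a trial dataset
#'
#' Checks that repeated measurements nest in subjects and subjects nest
#' in groups, consistently across all three tables. Measurements
#' recorded strictly after a subject's observed event time are flagged
#' as warnings, not errors: designs in which the longitudinal window is
#' shorter than survival follow-up legitimately produce arbitrary
#' observation patterns, and the fitting functions tolerate them.
#'
#' @param data a [trial_dataset()].
#' @return An object of class `validation_report`: list with data frames
#'   `errors` (columns `subject_id`, `problem`) and `warnings`.
#' @export
validate_nesting <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  errors <- list()
  warnings <- list()

  grp_long <- tapply(data$longitudinal$group_id, data$longitudinal$subject_id,
                     function(g) unique(g), simplify = FALSE)
  multi <- names(grp_long)[vapply(grp_long, length, 1L) > 1L]
  if (length(multi))
    errors[[length(errors) + 1L]] <- data.frame(
      subject_id = multi, problem = "subject mapped to multiple groups in longitudinal table")

  surv_grp <- stats::setNames(data$survival$group_id, data$survival$subject_id)
  one_grp <- vapply(grp_long, `[`, "", 1L)
  mism <- names(one_grp)[one_grp != surv_grp[names(one_grp)]]
  if (length(mism))
    errors[[length(errors) + 1L]] <- data.frame(
      subject_id = mism, problem = "group differs between longitudinal and survival tables")

  obs_t <- stats::setNames(data$survival$observed_time, data$survival$subject_id)
  late <- data$longitudinal$time > obs_t[data$longitudinal$subject_id]
  if (any(late))
    warnings[[length(warnings) + 1L]] <- data.frame(
      subject_id = unique(data$longitudinal$subject_id[late]),
      problem = "measurement time after observed event/censoring time")

  empty <- data.frame(subject_id = character(), problem = character())
  structure(
    list(errors = if (length(errors)) do.call(rbind, errors) else empty,
         warnings = if (length(warnings)) do.call(rbind, warnings) else empty),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Nesting validation: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) { cat("Errors:\n"); print(x$errors) }
  if (nrow(x$warnings)) { cat("Warnings:\n"); print(x$warnings) }
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "Trial dataset: %d groups, %d subjects, %d longitudinal measurements, %d events (%.1f%% censored)\n",
    nrow(x$groups), nrow(x$survival), nrow(x$longitudinal),
    sum(x$survival$event), 100 * mean(1 - x$survival$event)))
  invisible(x)
}
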