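#' Interval grid for the piecewise-constant hazard
#'
#' The follow-up period is divided into Q intervals
#' \eqn{[\tau_{q-1}, \tau_q)}, \eqn{q = 1, \dots, Q}, with
#' \eqn{\tau_0 = 0}. The final cut closes the grid at the administrative
#' end of follow-up (the baseline hazard is constant within each
#' interval, so events cannot be observed beyond \eqn{\tau_Q}).
#'
#' @param cuts strictly increasing cut points, starting at 0.
#' @return An object of class `interval_grid` with elements `cuts` and `Q`.
#' @export
interval_grid <- function(cuts) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 2L) stop_mjm("argument", "need at least two cut points")
  if (cuts[1] != 0) stop_mjm("argument", "first cut point must be 0")
  if (any(diff(cuts) <= 0)) stop_mjm("argument", "cut points must be strictly increasing")
  structure(list(cuts = cuts, Q = length(cuts) - 1L), class = "interval_grid")
}

#' Equal-length interval grid
#'
#' Splits `[0, max_time]` into `Q` intervals of equal length, the common
#' choice when intervals should align with a regular measurement
#' schedule.
#'
#' @param max_time end of follow-up (years, > 0).
#' @param Q number of intervals (>= 1); `Q = 1` gives the exponential
#'   (single constant hazard) limit.
#' @return An [interval_grid()].
#' @export
equal_length_grid <- function(max_time, Q) {
  if (length(Q) != 1L || Q < 1 || Q != round(Q)) stop_mjm("argument", "Q must be an integer >= 1")
  if (max_time <= 0) stop_mjm("argument", "max_time must be > 0")
  interval_grid(seq(0, max_time, length.out = Q + 1L))
}

# Index of the interval a time belongs to under the closed-right
# boundary convention: a time exactly equal to a cut falls in the
# interval ENDING at that cut, so no zero-exposure record (whose
# log-offset would be -Inf) is ever created.
interval_of <- function(time, grid) {
  q <- findInterval(time, grid$cuts, left.open = TRUE)
  q[time <= 0] <- NA_integer_
  q[time > grid$cuts[grid$Q + 1L]] <- NA_integer_
  q
}

#' Split one subject's follow-up into pseudo-Poisson records
#'
#' Produces one record per interval up to and including the interval
#' containing the observed time. The exposure is the full interval
#' length for completed intervals and \eqn{T - \tau_{q-1}} in the final
#' one; the pseudo-outcome `d` is 1 only in the final record and only
#' for an observed event.
#'
#' @param observed_time observed event/censoring time (years, > 0).
#' @param event event indicator (0/1).
#' @param grid an [interval_grid()]; `observed_time` must not exceed its
#'   final cut.
#' @param eval_rule where within each interval the current value
#'   \eqn{m(t)} is evaluated: at the interval start (default; coincides
#'   with a measurement occasion when the grid mirrors the collection
#'   schedule), the midpoint of the exposed part, or its end
#'   (event/censoring time in the final interval).
#' @return data frame with columns `q`, `exposure`, `d`, `eval_time`.
#' @export
split_subject <- function(observed_time, event,
                          grid, eval_rule = c("interval_start", "interval_mid", "event_or_end")) {
  eval_rule <- match.arg(eval_rule)
  if (observed_time <= 0) stop_mjm("domain", "observed_time must be > 0")
  tauQ <- grid$cuts[grid$Q + 1L]
  if (observed_time > tauQ)
    stop_mjm("out_of_grid", sprintf("observed_time %g exceeds final cut %g", observed_time, tauQ))
  qT <- interval_of(observed_time, grid)
  q <- seq_len(qT)
  lower <- grid$cuts[q]
  exposure <- pmin(observed_time, grid$cuts[q + 1L]) - lower
  d <- integer(qT)
  d[qT] <- as.integer(event)
  eval_time <- switch(eval_rule,
    interval_start = lower,
    interval_mid = lower + exposure / 2,
    event_or_end = lower + exposure)
  data.frame(q = q, exposure = exposure, d = d, eval_time = eval_time)
}

#' Build the pseudo-Poisson table for a whole dataset
#'
#' Applies [split_subject()] to every survival record, carrying subject
#' and group identifiers and indices. Records are emitted in
#' (subject, q) order so likelihood assembly is deterministic. The
#' resulting table carries the survival likelihood of the
#' piecewise-constant proportional-hazards model in auxiliary Poisson
#' form: total exposure per subject equals the observed time and the
#' total pseudo-events equal the total observed events.
#'
#' @param data a [trial_dataset()].
#' @inheritParams split_subject
#' @return data frame with columns `subject_id`, `group_id`,
#'   `subject_index`, `group_index`, `q`, `exposure`, `d`, `eval_time`.
#' @export
split_dataset <- function(data, grid,
                          eval_rule = c("interval_start", "interval_mid", "event_or_end")) {
  stopifnot(inherits(data, "trial_dataset"), inherits(grid, "interval_grid"))
  eval_rule <- match.arg(eval_rule)
  sv <- data$survival
  pieces <- lapply(seq_len(nrow(sv)), function(i) {
    ps <- split_subject(sv$observed_time[i], sv$event[i], grid, eval_rule)
    cbind(data.frame(subject_id = sv$subject_id[i], group_id = sv$group_id[i],
                     subject_index = sv$subject_index[i], group_index = sv$group_index[i],
                     stringsAsFactors = FALSE),
          ps)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a pseudo-Poisson record table as CSV
#'
#' @param pseudo output of [split_dataset()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_pseudo <- function(pseudo, path) {
  utils::write.csv(
    pseudo[, c("subject_id", "group_id", "q", "exposure", "d", "eval_time")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
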