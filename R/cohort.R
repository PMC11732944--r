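#' Irregular longitudinal cohort
#'
#' Builds the cohort container used by [interp_esn()] from a long-format
#' data frame with one row per visit: a participant id column, a visit time
#' column, `k` marker columns, and an outcome column that is constant within
#' each participant. Visit times may be irregular; they are stored in months
#' relative to nothing in particular (each participant's first record
#' defines month 0 at interpolation time). Participants with a single visit
#' carry no trajectory information and are dropped with a message.
#'
#' @param data data frame with columns `id`, `time`, the marker columns and
#'   `outcome` (names configurable below).
#' @param id,time,outcome names of the id, time and outcome columns.
#' @param markers character vector of marker column names; default all
#'   remaining numeric columns in their original order.
#' @param time_unit `"months"` (default) or `"years"`; years are converted
#'   to months (x 12), the package's canonical unit.
#' @param outcome_levels optional character vector fixing the outcome factor
#'   levels; the FIRST level is treated as the negative (control) class and
#'   the LAST as the positive (case) class throughout the package. Defaults
#'   to the sorted unique outcomes.
#' @return An object of class `"esn_cohort"`: a list with `participants`
#'   (each holding `id`, `times`, `values`, `outcome`), `marker_names`,
#'   `levels` and `n_dropped` (single-visit exclusions).
#' @examples
#' df <- data.frame(id = c(1, 1, 2, 2, 2), time = c(0, 3, 0, 5, 9),
#'                  m1 = rnorm(5), outcome = c("a", "a", "b", "b", "b"))
#' cohort(df)
#' @export
cohort <- function(data, id = "id", time = "time", outcome = "outcome",
                   markers = NULL, time_unit = c("months", "years"),
                   outcome_levels = NULL) {
  time_unit <- match.arg(time_unit)
  need <- c(id, time, outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(markers))
    markers <- setdiff(names(data), need)
  if (!length(markers))
    stop("no marker columns found", call. = FALSE)
  for (m in markers)
    if (!is.numeric(data[[m]]))
      stop("marker column '", m, "' is not numeric", call. = FALSE)
  if (anyNA(data[c(time, markers)]))
    stop("missing values in time or marker columns are not supported",
         call. = FALSE)

  scale <- if (time_unit == "years") 12 else 1
  if (is.null(outcome_levels))
    outcome_levels <- sort(unique(as.character(data[[outcome]])))

  parts <- list(); dropped <- 0L
  for (pid in unique(data[[id]])) {
    rows <- data[data[[id]] == pid, , drop = FALSE]
    rows <- rows[order(rows[[time]]), , drop = FALSE]
    if (length(unique(as.character(rows[[outcome]]))) > 1L)
      stop("participant '", pid, "' has conflicting outcomes", call. = FALSE)
    tm <- rows[[time]] * scale
    if (anyDuplicated(tm))
      stop("participant '", pid, "' has duplicate visit times",
           call. = FALSE)
    if (nrow(rows) < 2L) { dropped <- dropped + 1L; next }
    parts[[length(parts) + 1L]] <- list(
      id = pid, times = tm,
      values = as.matrix(rows[markers]),
      outcome = as.character(rows[[outcome]][1L]))
  }
  if (dropped > 0L)
    message(dropped, " participant(s) with a single visit dropped")
  if (!length(parts))
    stop("cohort is empty after filtering", call. = FALSE)
  bad <- setdiff(vapply(parts, `[[`, "", "outcome"), outcome_levels)
  if (length(bad))
    stop("outcome value(s) not in outcome_levels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(participants = parts, marker_names = markers,
                 levels = outcome_levels, n_dropped = dropped),
            class = "esn_cohort")
}

#' @export
print.esn_cohort <- function(x, ...) {
  nv <- vapply(x$participants, function(p) length(p$times), 0L)
  oc <- vapply(x$participants, `[[`, "", "outcome")
  cat("Irregular longitudinal cohort:", length(x$participants),
      "participants,", length(x$marker_names), "markers\n")
  cat("  visits per participant:", min(nv), "-", max(nv), "\n")
  cat("  outcomes:",
      paste(sprintf("%s = %d", x$levels, tabulate(factor(oc, x$levels))),
            collapse = ", "), "\n")
  if (x$n_dropped > 0L)
    cat("  (", x$n_dropped, " single-visit participant(s) dropped)\n",
        sep = "")
  invisible(x)
}

#' Outcomes of a cohort, one per participant
#' @param x an [cohort()] object.
#' @return Factor of participant outcomes (cohort levels), named by id.
#' @export
cohort_outcomes <- function(x) {
  stopifnot(inherits(x, "esn_cohort"))
  oc <- factor(vapply(x$participants, `[[`, "", "outcome"), x$levels)
  names(oc) <- vapply(x$participants, function(p) as.character(p$id), "")
  oc
}

#' Subset a cohort by participant index
#' @param x an [cohort()] object.
#' @param idx integer indices of participants to keep.
#' @return A new `esn_cohort` with the selected participants.
#' @export
subset_cohort <- function(x, idx) {
  stopifnot(inherits(x, "esn_cohort"))
  structure(list(participants = x$participants[idx],
                 marker_names = x$marker_names, levels = x$levels,
                 n_dropped = 0L),
            class = "esn_cohort")
}

#' @export
as.data.frame.esn_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$participants, function(p) {
    df <- data.frame(id = p$id, time = p$times)
    v <- as.data.frame(p$values)
    names(v) <- x$marker_names
    cbind(df, v, outcome = p$outcome)
  }))
}

#' Read an irregular cohort from a delimited file
#'
#' Reads the longitudinal CSV schema (columns `id`, `time`, one column per
#' marker, `outcome`; one row per visit) and assembles an [cohort()].
#' Rows are grouped by id and sorted by time; participants with only one
#' visit are dropped with a message. Conflicting outcomes or duplicate
#' visit times within a participant are an error, never silently repaired.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @inheritParams cohort
#' @return An `esn_cohort`.
#' @export
read_cohort <- function(path, sep = ",", time_unit = c("months", "years"),
                        outcome_levels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cohort(df, time_unit = match.arg(time_unit),
         outcome_levels = outcome_levels)
}

#' Write a cohort to a delimited file
#'
#' Inverse of [read_cohort()]; values round-trip at full double precision.
#'
#' @param x an [cohort()] object.
#' @param path file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "esn_cohort"))
  df <- as.data.frame(x)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
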