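#' Construct an event log
#'
#' An event log is the raw material of care-pathway analysis: one trace per
#' case (patient), each trace a chronologically ordered sequence of timestamped
#' activities. Case-level attributes (age, screening flag, diagnosis codes,
#' severity categories, ...) live on the trace, one patient being one case;
#' set-valued attributes are allowed so that a patient can belong to several
#' attribute-defined populations at once.
#'
#' Events are ordered within a case by timestamp, then by `seq_index` (an
#' optional non-negative within-day tie-breaker, as used when several events of
#' a patient share a calendar date), then by stable input order. Ties on
#' timestamp without a `seq_index` trigger a warning, because the resulting
#' order is only as meaningful as the input order.
#'
#' @param events A data frame with columns `case_id`, `activity`, `timestamp`
#'   (`POSIXct` or coercible), and optionally `seq_index` (non-negative
#'   integer or `NA`).
#' @param case_attrs Named list, one element per case id, each a named list of
#'   attribute values (atomic vectors; length > 1 means set-valued).
#' @param name Population label for the log.
#' @return An object of class `event_log`.
#' @examples
#' ev <- data.frame(
#'   case_id = c("p1", "p1", "p2"),
#'   activity = c("radiology", "pathology", "radiology"),
#'   timestamp = as.POSIXct(c("2020-01-01", "2020-01-03", "2020-01-02"), tz = "UTC")
#' )
#' log <- event_log(ev, case_attrs = list(p1 = list(age = 61), p2 = list(age = 44)))
#' n_cases(log)
#' activities(log)
#' @export
event_log <- function(events, case_attrs = list(), name = "log") {
  stopifnot(is.data.frame(events))
  required <- c("case_id", "activity", "timestamp")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(events) == 0) {
    stop("an event log must contain at least one event")
  }
  events$case_id <- as.character(events$case_id)
  events$activity <- as.character(events$activity)
  if (!inherits(events$timestamp, "POSIXct")) {
    events$timestamp <- as.POSIXct(events$timestamp, tz = "UTC")
  }
  if (is.null(events$seq_index)) {
    events$seq_index <- NA_integer_
  } else {
    events$seq_index <- as.integer(events$seq_index)
    if (any(events$seq_index < 0L, na.rm = TRUE)) {
      stop("seq_index must be non-negative")
    }
  }
  if (any(is.na(events$activity) | events$activity == "")) {
    stop("every event must have a non-empty activity label")
  }
  if (any(is.na(events$case_id) | events$case_id == "")) {
    stop("every event must have a case id")
  }
  if (any(is.na(events$timestamp))) {
    stop("every event must have a timestamp")
  }

  # seq_index must be unique within (case, calendar date) where present
  has_seq <- !is.na(events$seq_index)
  if (any(has_seq)) {
    key <- paste(events$case_id[has_seq],
                 format(events$timestamp[has_seq], "%Y-%m-%d"),
                 events$seq_index[has_seq])
    if (anyDuplicated(key)) {
      stop("seq_index must be unique within (case_id, date)")
    }
  }

  # stable chronological order: timestamp, then seq_index, then input order
  ord <- order(events$case_id, events$timestamp,
               ifelse(is.na(events$seq_index), .Machine$integer.max,
                      events$seq_index),
               seq_len(nrow(events)), method = "radix")
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL

  tie_key <- paste(events$case_id, events$timestamp)
  tied <- duplicated(tie_key) | duplicated(tie_key, fromLast = TRUE)
  if (any(tied & is.na(events$seq_index))) {
    warning("timestamp ties without seq_index; ordering those events by ",
            "stable input order", call. = FALSE)
  }

  cids <- unique(events$case_id)
  extra_attrs <- setdiff(names(case_attrs), cids)
  if (length(extra_attrs) > 0) {
    stop("case_attrs given for unknown case id(s): ",
         paste(utils::head(extra_attrs, 5), collapse = ", "))
  }

  structure(
    list(
      events = events,
      case_attrs = case_attrs,
      name = as.character(name)[1],
      alphabet = sort(unique(events$activity))
    ),
    class = "event_log"
  )
}

#' Build an event log from a list of activity sequences
#'
#' Convenience constructor used throughout examples and simulation: each trace
#' is a character vector of activities, and synthetic strictly increasing
#' timestamps (one day apart) are generated.
#'
#' @param traces Named or unnamed list of character vectors. Unnamed traces get
#'   case ids `case_1`, `case_2`, ...
#' @param case_attrs,name Passed to [event_log()].
#' @param start A `POSIXct` origin for the synthetic timestamps.
#' @return An `event_log`.
#' @export
log_from_traces <- function(traces, case_attrs = list(), name = "log",
                            start = as.POSIXct("2020-01-01", tz = "UTC")) {
  stopifnot(is.list(traces), length(traces) > 0)
  ids <- names(traces)
  if (is.null(ids) || any(ids == "")) {
    ids <- sprintf("case_%d", seq_along(traces))
    names(traces) <- ids
  }
  n <- lengths(traces)
  if (any(n == 0)) stop("every trace must contain at least one event")
  events <- data.frame(
    case_id = rep(ids, n),
    activity = unlist(traces, use.names = FALSE),
    timestamp = start + 86400 * unlist(lapply(n, seq_len)),
    stringsAsFactors = FALSE
  )
  event_log(events, case_attrs = case_attrs, name = name)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log '%s': %d cases, %d events, %d activities\n",
              x$name, n_cases(x), nrow(x$events), length(x$alphabet)))
  cat("activities:", paste(x$alphabet, collapse = ", "), "\n")
  invisible(x)
}

#' Number of cases in an event log
#' @param log An `event_log`.
#' @return Integer count of distinct cases.
#' @export
n_cases <- function(log) {
  stopifnot(inherits(log, "event_log"))
  length(unique(log$events$case_id))
}

#' Activity alphabet of an event log
#' @param log An `event_log`.
#' @return Sorted character vector of distinct activity labels.
#' @export
activities <- function(log) {
  stopifnot(inherits(log, "event_log"))
  log$alphabet
}

#' Case identifiers of an event log
#' @param log An `event_log`.
#' @return Character vector of case ids in order of first appearance.
#' @export
case_ids <- function(log) {
  stopifnot(inherits(log, "event_log"))
  unique(log$events$case_id)
}

#' Extract traces as activity sequences
#'
#' @param log An `event_log`.
#' @return Named list (by case id) of character vectors, each the
#'   chronologically ordered activities of one case.
#' @export
traces <- function(log) {
  stopifnot(inherits(log, "event_log"))
  split(log$events$activity, factor(log$events$case_id,
                                    levels = unique(log$events$case_id)))
}

#' Tabulate trace variants
#'
#' Groups cases by their activity sequence. Conformance and discovery
#' operations work per variant and weight by its frequency, which is what
#' makes replay on logs with thousands of cases cheap.
#'
#' @param log An `event_log`.
#' @return A list with elements `variants` (list of character vectors),
#'   `counts` (integer vector), and `case_ids` (list of character vectors of
#'   the cases showing each variant).
#' @export
trace_variants <- function(log) {
  tr <- traces(log)
  key <- vapply(tr, function(t) paste(t, collapse = "\037"), character(1))
  idx <- split(seq_along(tr), key)
  # preserve order of first appearance
  idx <- idx[order(vapply(idx, min, integer(1)))]
  list(
    variants = unname(lapply(idx, function(i) tr[[i[1]]])),
    counts = unname(vapply(idx, length, integer(1))),
    case_ids = unname(lapply(idx, function(i) names(tr)[i]))
  )
}

#' Events of an event log as a tibble
#' @param log An `event_log`.
#' @return A tibble with columns `case_id`, `activity`, `timestamp`,
#'   `seq_index`.
#' @export
log_events <- function(log) {
  stopifnot(inherits(log, "event_log"))
  tibble::as_tibble(log$events)
}
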