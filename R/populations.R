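#' Declarative case-attribute filter
#'
#' Populations are defined by filters over case attributes: equality, numeric
#' comparison, set membership, or a closed numeric range. For set-valued
#' attributes (e.g. a patient carrying several diagnosis codes) the filter
#' matches if any value matches, which is how one patient can fall into more
#' than one population.
#'
#' @param attribute Attribute name.
#' @param op One of `"=="`, `"!="`, `">="`, `">"`, `"<="`, `"<"`, `"in"`,
#'   `"range"`.
#' @param value Comparison value; for `"in"` a vector of allowed values, for
#'   `"range"` a length-2 numeric `c(lo, hi)` (inclusive).
#' @return An object of class `attr_filter`.
#' @examples
#' attr_filter("age", ">=", 50)
#' attr_filter("icd9", "range", c(150, 159))
#' @export
attr_filter <- function(attribute, op, value) {
  op <- match.arg(op, c("==", "!=", ">=", ">", "<=", "<", "in", "range"))
  if (op == "range" && (!is.numeric(value) || length(value) != 2)) {
    stop("a range filter needs value = c(lo, hi)")
  }
  structure(list(attribute = attribute, op = op, value = value),
            class = "attr_filter")
}

#' @export
print.attr_filter <- function(x, ...) {
  cat(sprintf("<attr_filter> %s %s %s\n", x$attribute, x$op,
              paste(x$value, collapse = ",")))
  invisible(x)
}

eval_filter <- function(filt, attrs, available) {
  v <- attrs[[filt$attribute]]
  if (is.null(v)) {
    stop("case attribute '", filt$attribute, "' not present; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  switch(filt$op,
    "in" = any(v %in% filt$value),
    "range" = any(as.numeric(v) >= filt$value[1] &
                  as.numeric(v) <= filt$value[2]),
    "==" = any(v == filt$value),
    "!=" = all(v != filt$value),
    any(get(filt$op)(as.numeric(v), as.numeric(filt$value)))
  )
}

#' Split a population out of an event log
#'
#' Returns the sub-log containing exactly the traces whose case attributes
#' satisfy every given filter (filters combine conjunctively). The input log
#' is not modified. An empty result is permitted here — downstream discovery
#' rejects empty logs.
#'
#' @param log An [event_log()].
#' @param ... One or more [attr_filter()] objects.
#' @param name Label for the resulting population; defaults to a rendering of
#'   the filters.
#' @return An `event_log` (possibly with zero traces, represented as a
#'   zero-row events table of class `event_log`).
#' @examples
#' log <- log_from_traces(
#'   list(p1 = c("A", "B"), p2 = c("A")),
#'   case_attrs = list(p1 = list(age = 61), p2 = list(age = 44))
#' )
#' old <- split_population(log, attr_filter("age", ">=", 50))
#' case_ids(old)
#' @export
split_population <- function(log, ..., name = NULL) {
  stopifnot(inherits(log, "event_log"))
  filters <- list(...)
  if (length(filters) == 0) stop("at least one attr_filter is required")
  if (!all(vapply(filters, inherits, logical(1), "attr_filter"))) {
    stop("filters must be attr_filter objects")
  }
  available <- sort(unique(unlist(lapply(log$case_attrs, names))))
  cids <- case_ids(log)
  keep <- vapply(cids, function(cid) {
    attrs <- log$case_attrs[[cid]]
    if (is.null(attrs)) attrs <- list()
    all(vapply(filters, eval_filter, logical(1), attrs = attrs,
               available = available))
  }, logical(1))
  if (is.null(name)) {
    name <- paste(vapply(filters, function(f) {
      paste0(f$attribute, f$op, paste(f$value, collapse = ":"))
    }, character(1)), collapse = "&")
  }
  kept <- cids[keep]
  if (length(kept) == 0) {
    ev <- log$events[0, , drop = FALSE]
    return(structure(list(events = ev, case_attrs = list(), name = name,
                          alphabet = character(0)),
                     class = "event_log"))
  }
  ev <- log$events[log$events$case_id %in% kept, , drop = FALSE]
  rownames(ev) <- NULL
  event_log(ev, case_attrs = log$case_attrs[intersect(names(log$case_attrs),
                                                      kept)],
            name = name)
}

#' Jaccard overlap of two patient populations
#'
#' The ratio of the number of patients the two populations have in common
#' (set intersection of case ids) to the total number of unique patient ids
#' (set union).
#'
#' @param popA,popB Two [event_log()] objects.
#' @return A fraction in \[0, 1\].
#' @examples
#' a <- log_from_traces(list(p1 = "A", p2 = "A", p3 = "A"))
#' b <- log_from_traces(list(p2 = "A", p3 = "A", p4 = "A"))
#' jaccard_overlap(a, b)  # 2 shared of 4 unique -> 0.5
#' @export
jaccard_overlap <- function(popA, popB) {
  stopifnot(inherits(popA, "event_log"), inherits(popB, "event_log"))
  a <- unique(popA$events$case_id)
  b <- unique(popB$events$case_id)
  if (length(a) == 0 && length(b) == 0) {
    stop("Jaccard overlap is undefined for two empty populations")
  }
  length(intersect(a, b)) / length(union(a, b))
}
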