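#' Read an event log from XES or CSV
#'
#' XES files follow the IEEE 1849 layout: the activity is the event's
#' `concept:name`, the timestamp is `time:timestamp`, the case id is the
#' trace's `concept:name`, and any further trace-level attributes are read as
#' case attributes (repeated keys collect into set-valued attributes).
#'
#' CSV files are RFC-4180 UTF-8 with ISO-8601 timestamps and require an
#' explicit `column_map` naming the case/activity/timestamp columns; header
#' sniffing is deliberately not attempted so that a log is read the same way
#' on every machine.
#'
#' @param path File to read.
#' @param format `"xes"` or `"csv"`.
#' @param column_map For CSV: a named list with entries `case_id`, `activity`,
#'   `timestamp`, and optionally `seq_index` and `attributes` (character
#'   vector of case-attribute columns). Attribute columns must be constant
#'   within a case; values containing `|` are split into set-valued
#'   attributes.
#' @param name Population label; defaults to the file name.
#' @return An [event_log()].
#' @export
read_log <- function(path, format = c("xes", "csv"), column_map = NULL,
                     name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    xes = read_xes(path, name),
    csv = read_log_csv(path, column_map, name)
  )
}

#' Write an event log to XES or CSV
#'
#' Writing then reading a log is the identity on the event-log data model:
#' trace order, activity labels, timestamps, seq indices and case attributes
#' are preserved (CSV stores attribute values as text; XES keeps their type).
#'
#' @param log An [event_log()].
#' @param path Output file.
#' @param format `"xes"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path, format = c("xes", "csv")) {
  stopifnot(inherits(log, "event_log"))
  format <- match.arg(format)
  switch(format,
    xes = write_xes(log, path),
    csv = write_log_csv(log, path)
  )
  invisible(path)
}

fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC", usetz = FALSE)

parse_ts <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  plain <- is.na(out)
  if (any(plain)) out[plain] <- as.POSIXct(x[plain], tz = "UTC")
  if (any(is.na(out))) {
    stop("unparseable ISO-8601 timestamp(s), e.g. ", x[which(is.na(out))[1]])
  }
  out
}

read_log_csv <- function(path, column_map, name) {
  if (is.null(column_map) ||
      !all(c("case_id", "activity", "timestamp") %in% names(column_map))) {
    stop("column_map must name the case_id, activity and timestamp columns")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("empty event-log file: ", path)
  needed <- unlist(column_map[c("case_id", "activity", "timestamp",
                                "seq_index")], use.names = FALSE)
  needed <- c(needed, column_map$attributes)
  absent <- setdiff(needed, names(df))
  if (length(absent) > 0) {
    stop("column_map refers to missing column(s): ",
         paste(absent, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "))
  }
  events <- data.frame(
    case_id = as.character(df[[column_map$case_id]]),
    activity = as.character(df[[column_map$activity]]),
    timestamp = parse_ts(as.character(df[[column_map$timestamp]])),
    stringsAsFactors = FALSE
  )
  if (!is.null(column_map$seq_index)) {
    events$seq_index <- as.integer(df[[column_map$seq_index]])
  }
  case_attrs <- list()
  if (length(column_map$attributes) > 0) {
    for (cid in unique(events$case_id)) {
      rows <- df[events$case_id == cid, column_map$attributes, drop = FALSE]
      attrs <- lapply(rows, function(col) {
        vals <- unique(as.character(col))
        vals <- unlist(strsplit(vals, "|", fixed = TRUE), use.names = FALSE)
        unique(vals)
      })
      case_attrs[[cid]] <- attrs
    }
  }
  event_log(events, case_attrs = case_attrs, name = name)
}

write_log_csv <- function(log, path) {
  ev <- log$events
  df <- data.frame(
    case_id = ev$case_id,
    activity = ev$activity,
    timestamp = fmt_ts(ev$timestamp),
    seq_index = ev$seq_index,
    stringsAsFactors = FALSE
  )
  attr_names <- unique(unlist(lapply(log$case_attrs, names)))
  for (a in attr_names) {
    df[[a]] <- vapply(ev$case_id, function(cid) {
      v <- log$case_attrs[[cid]][[a]]
      if (is.null(v)) NA_character_ else paste(as.character(v), collapse = "|")
    }, character(1), USE.NAMES = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

xes_attr_node <- function(parent, key, value) {
  if (inherits(value, "POSIXct")) {
    xml2::xml_add_child(parent, "date", key = key,
                        value = paste0(fmt_ts(value), "Z"))
  } else if (is.numeric(value) && all(value == round(value))) {
    for (v in value) xml2::xml_add_child(parent, "int", key = key,
                                         value = format(v, scientific = FALSE))
  } else if (is.numeric(value)) {
    for (v in value) xml2::xml_add_child(parent, "float", key = key,
                                         value = format(v, digits = 17))
  } else if (is.logical(value)) {
    for (v in value) xml2::xml_add_child(parent, "boolean", key = key,
                                         value = tolower(as.character(v)))
  } else {
    for (v in as.character(value)) xml2::xml_add_child(parent, "string",
                                                       key = key, value = v)
  }
}

write_xes <- function(log, path) {
  doc <- xml2::xml_new_root("log", "xes.version" = "1.0",
                            "xes.features" = "nested-attributes")
  xes_attr_node(doc, "concept:name", log$name)
  tr <- split(seq_len(nrow(log$events)),
              factor(log$events$case_id, levels = unique(log$events$case_id)))
  for (cid in names(tr)) {
    tnode <- xml2::xml_add_child(doc, "trace")
    xes_attr_node(tnode, "concept:name", cid)
    attrs <- log$case_attrs[[cid]]
    for (a in names(attrs)) xes_attr_node(tnode, a, attrs[[a]])
    for (i in tr[[cid]]) {
      enode <- xml2::xml_add_child(tnode, "event")
      xes_attr_node(enode, "concept:name", log$events$activity[i])
      xes_attr_node(enode, "time:timestamp", log$events$timestamp[i])
      if (!is.na(log$events$seq_index[i])) {
        xes_attr_node(enode, "seq_index", log$events$seq_index[i])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

xes_read_attrs <- function(node) {
  kids <- xml2::xml_find_all(node, "./*[@key]")
  out <- list()
  for (k in kids) {
    key <- xml2::xml_attr(k, "key")
    val <- xml2::xml_attr(k, "value")
    typed <- switch(xml2::xml_name(k),
      int = as.integer(val),
      float = as.numeric(val),
      boolean = as.logical(toupper(val)),
      date = parse_ts(sub("Z$", "", val)),
      val
    )
    if (is.null(out[[key]])) out[[key]] <- typed
    else out[[key]] <- c(out[[key]], typed)   # repeated key: set-valued
  }
  out
}

read_xes <- function(path, name) {
  if (file.size(path) == 0) stop("empty event-log file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XES in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (xml2::xml_name(doc) != "log") {
    stop("malformed XES: root element is <", xml2::xml_name(doc),
         ">, expected <log>")
  }
  trace_nodes <- xml2::xml_find_all(doc, "./trace")
  if (length(trace_nodes) == 0) stop("XES file contains no traces: ", path)
  log_attrs <- xes_read_attrs(doc)
  if (!is.null(log_attrs[["concept:name"]])) name <- log_attrs[["concept:name"]]

  rows <- list()
  case_attrs <- list()
  for (ti in seq_along(trace_nodes)) {
    tnode <- trace_nodes[[ti]]
    tattrs <- xes_read_attrs(tnode)
    cid <- tattrs[["concept:name"]]
    if (is.null(cid)) {
      stop("malformed XES: <trace> #", ti, " lacks a concept:name attribute")
    }
    tattrs[["concept:name"]] <- NULL
    if (length(tattrs) > 0) case_attrs[[cid]] <- tattrs
    for (enode in xml2::xml_find_all(tnode, "./event")) {
      eattrs <- xes_read_attrs(enode)
      if (is.null(eattrs[["concept:name"]]) ||
          is.null(eattrs[["time:timestamp"]])) {
        stop("malformed XES: <event> in trace '", cid,
             "' lacks concept:name or time:timestamp")
      }
      rows[[length(rows) + 1]] <- data.frame(
        case_id = cid,
        activity = eattrs[["concept:name"]],
        timestamp = eattrs[["time:timestamp"]],
        seq_index = if (is.null(eattrs[["seq_index"]])) NA_integer_ else
          as.integer(eattrs[["seq_index"]]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) stop("XES file contains no events: ", path)
  event_log(do.call(rbind, rows), case_attrs = case_attrs, name = name)
}
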