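test_that("event logs order events chronologically with seq_index tie-break", {
  ev <- data.frame(
    case_id = c("p1", "p1", "p2"),
    activity = c("B", "A", "A"),
    timestamp = as.POSIXct(c("2020-01-02", "2020-01-01", "2020-01-01"),
                           tz = "UTC")
  )
  log <- event_log(ev)
  expect_equal(n_cases(log), 2)
  expect_equal(activities(log), c("A", "B"))
  expect_equal(traces(log)$p1, c("A", "B"))

  # same date, seq_index 2 then 1 in the input: seq 1 is emitted first
  ev2 <- data.frame(
    case_id = "p1", activity = c("late", "early"),
    timestamp = as.POSIXct("2020-01-01", tz = "UTC"),
    seq_index = c(2L, 1L)
  )
  expect_equal(traces(event_log(ev2))$p1, c("early", "late"))

  # ties without seq_index warn and keep stable input order
  ev3 <- data.frame(
    case_id = "p1", activity = c("first", "second"),
    timestamp = as.POSIXct("2020-01-01", tz = "UTC")
  )
  expect_warning(log3 <- event_log(ev3), "seq_index")
  expect_equal(traces(log3)$p1, c("first", "second"))
})

test_that("invalid events are rejected", {
  ts <- as.POSIXct("2020-01-01", tz = "UTC")
  expect_error(event_log(data.frame(case_id = "p", activity = "",
                                    timestamp = ts)), "non-empty")
  expect_error(event_log(data.frame(case_id = "p", activity = "A",
                                    timestamp = ts)[0, ]), "at least one")
  expect_error(
    event_log(data.frame(case_id = "p", activity = c("A", "B"),
                         timestamp = ts, seq_index = c(1L, 1L))),
    "unique within")
})

test_that("csv and xes round trips preserve the log", {
  log <- log_from_traces(
    list(p1 = c("radiology", "pathologieë"), p2 = "radiology"),
    case_attrs = list(p1 = list(age = 61L, icd = c("151", "152")),
                      p2 = list(age = 44L)),
    name = "ward"
  )
  xes <- tempfile(fileext = ".xes")
  write_log(log, xes, "xes")
  back <- read_log(xes, "xes")
  expect_equal(log_events(back), log_events(log))
  expect_equal(back$case_attrs, log$case_attrs)
  expect_equal(back$name, "ward")

  csv <- tempfile(fileext = ".csv")
  write_log(log, csv, "csv")
  back2 <- read_log(csv, "csv",
                    column_map = list(case_id = "case_id",
                                      activity = "activity",
                                      timestamp = "timestamp",
                                      seq_index = "seq_index",
                                      attributes = c("age", "icd")))
  expect_equal(log_events(back2), log_events(log))
  # non-ASCII labels survive verbatim; set-valued attribute split on |
  expect_equal(traces(back2)$p1[2], "pathologieë")
  expect_equal(back2$case_attrs$p1$icd, c("151", "152"))
})

test_that("csv reader rejects bad configuration and empty input", {
  f <- tempfile(fileext = ".csv")
  writeLines("case,act,when", f)  # header only
  cmap <- list(case_id = "case", activity = "act", timestamp = "when")
  expect_error(read_log(f, "csv", cmap), "empty")
  expect_error(read_log(f, "csv", list(case_id = "case")), "column_map")
  writeLines(c("case,act,when", "p1,A,2020-01-01T00:00:00"), f)
  expect_error(read_log(f, "csv", list(case_id = "case", activity = "act",
                                       timestamp = "missing")),
               "available")
  expect_silent(log <- read_log(f, "csv", cmap))
  expect_equal(n_cases(log), 1)
})

test_that("malformed xes is reported with the offending element", {
  f <- tempfile(fileext = ".xes")
  writeLines("<notalog></notalog>", f)
  expect_error(read_log(f, "xes"), "root element")
  writeLines(c("<log>", "<trace><event/></trace>", "</log>"), f)
  expect_error(read_log(f, "xes"), "trace")
})

test_that("population splitting filters by case attributes", {
  log <- log_from_traces(
    list(p1 = c("A", "B"), p2 = "A", p3 = c("B", "B")),
    case_attrs = list(p1 = list(age = 40, icd = "151"),
                      p2 = list(age = 50, icd = c("151", "210")),
                      p3 = list(age = 60, icd = "210"))
  )
  old <- split_population(log, attr_filter("age", ">=", 50))
  expect_setequal(case_ids(old), c("p2", "p3"))
  # threshold is inclusive
  expect_true("p2" %in% case_ids(old))
  # original untouched
  expect_equal(n_cases(log), 3)

  # set-valued membership: p2 falls into both diagnosis populations
  g151 <- split_population(log, attr_filter("icd", "in", "151"))
  g210 <- split_population(log, attr_filter("icd", "in", "210"))
  expect_setequal(case_ids(g151), c("p1", "p2"))
  expect_setequal(case_ids(g210), c("p2", "p3"))
  # numeric code range
  rng <- split_population(log, attr_filter("icd", "range", c(150, 159)))
  expect_setequal(case_ids(rng), c("p1", "p2"))

  # no match: empty log with empty alphabet
  none <- split_population(log, attr_filter("age", ">", 99))
  expect_equal(length(case_ids(none)), 0)
  expect_equal(none$alphabet, character(0))

  # absent attribute names the available ones
  expect_error(split_population(log, attr_filter("sex", "==", "f")),
               "available: age, icd")
})

test_that("complementary predicates partition cases on a total attribute", {
  log <- log_from_traces(
    stats::setNames(rep(list("A"), 10), paste0("p", 1:10)),
    case_attrs = stats::setNames(
      lapply(c(31:35, 51:55), function(a) list(age = a)), paste0("p", 1:10))
  )
  lo <- split_population(log, attr_filter("age", "<", 50))
  hi <- split_population(log, attr_filter("age", ">=", 50))
  expect_length(intersect(case_ids(lo), case_ids(hi)), 0)
  expect_setequal(c(case_ids(lo), case_ids(hi)), case_ids(log))
})

test_that("jaccard overlap matches intersection over union", {
  mk <- function(ids) log_from_traces(stats::setNames(rep(list("A"),
                                                          length(ids)), ids))
  a <- mk(c("1", "2", "3")); b <- mk(c("2", "3", "4"))
  expect_equal(jaccard_overlap(a, b), 0.5)
  expect_equal(jaccard_overlap(a, a), 1)
  expect_equal(jaccard_overlap(a, mk(c("7", "8"))), 0)
  # symmetric and bounded
  expect_equal(jaccard_overlap(a, b), jaccard_overlap(b, a))
  expect_gte(jaccard_overlap(a, b), 0)
  expect_lte(jaccard_overlap(a, b), 1)
})
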