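#' Specification for a synthetic clinical event log
#'
#' Describes one simulated patient population: the generating process tree
#' (with branch probabilities on exclusive choices and a continuation
#' probability on loops), the number of cases, the per-trace deviation rate
#' and the admissible deviation edits, the random seed, and the timing model
#' (start date and mean inter-event gap in days; gaps are exponential,
#' rounded up to whole seconds, so timestamps are strictly increasing within
#' a trace).
#'
#' @param tree A [process_tree] generator.
#' @param n_cases Number of cases to sample.
#' @param deviation_rate Fraction of traces receiving one random edit.
#' @param deviation_kinds Subset of `c("insert", "skip", "swap")`.
#' @param seed Integer seed; the same spec always yields the same log.
#' @param start_date `POSIXct` start of the observation window.
#' @param mean_gap_days Mean of the exponential inter-event gap.
#' @param name Population label; also the case-id prefix.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(tree, n_cases = 300, deviation_rate = 0,
                           deviation_kinds = c("insert", "skip", "swap"),
                           seed = 1L,
                           start_date = as.POSIXct("2020-01-01",
                                                   tz = "UTC"),
                           mean_gap_days = 3, name = "synthetic") {
  stopifnot(inherits(tree, "process_tree"), n_cases >= 1)
  if (deviation_rate < 0 || deviation_rate > 1) {
    stop("deviation_rate must lie in [0, 1]")
  }
  deviation_kinds <- match.arg(deviation_kinds, several.ok = TRUE)
  check_probs <- function(nd) {
    if (nd$kind == "xor" && !is.null(nd$probs) &&
        abs(sum(nd$probs) - 1) > 1e-9) {
      stop("xor branch probabilities must sum to 1")
    }
    if (nd$kind == "loop" && (is.null(nd$cont) || nd$cont >= 1)) {
      stop("loop continuation probability must be < 1")
    }
    lapply(nd$children, check_probs)
    invisible(NULL)
  }
  check_probs(tree)
  structure(list(tree = tree, n_cases = as.integer(n_cases),
                 deviation_rate = deviation_rate,
                 deviation_kinds = deviation_kinds, seed = as.integer(seed),
                 start_date = start_date, mean_gap_days = mean_gap_days,
                 name = name),
            class = "generator_spec")
}

sample_trace <- function(nd) {
  switch(nd$kind,
    leaf = nd$label,
    tau = character(0),
    seq = unlist(lapply(nd$children, sample_trace), use.names = FALSE),
    xor = {
      p <- nd$probs
      if (is.null(p)) p <- rep(1 / length(nd$children), length(nd$children))
      sample_trace(nd$children[[sample.int(length(nd$children), 1,
                                           prob = p)]])
    },
    and = {
      parts <- lapply(nd$children, sample_trace)
      # uniform random interleaving: tag each event with its part, shuffle
      # the merge order while preserving within-part order
      idx <- rep(seq_along(parts), lengths(parts))
      if (length(idx) == 0) return(character(0))
      ord <- sample.int(length(idx))
      merged <- character(length(idx))
      take <- integer(length(parts))
      pos <- 1
      for (k in idx[ord]) {
        take[k] <- take[k] + 1L
        merged[pos] <- parts[[k]][take[k]]
        pos <- pos + 1
      }
      merged
    },
    loop = {
      out <- sample_trace(nd$children[[1]])
      while (stats::runif(1) < nd$cont) {
        redo <- nd$children[-1]
        out <- c(out,
                 sample_trace(redo[[sample.int(length(redo), 1)]]),
                 sample_trace(nd$children[[1]]))
      }
      out
    }
  )
}

#' Sample a synthetic event log from a generator spec
#'
#' Each case is an independent random walk through the tree: exclusive
#' choices follow their branch probabilities (uniform by default), parallel
#' branches are merged by a uniformly random interleaving, and loops continue
#' with their geometric continuation probability. Timestamps are strictly
#' increasing within each trace. With `deviation_rate = 0` every trace lies
#' in the tree's language; otherwise [inject_deviations()] is applied.
#'
#' @param spec A [generator_spec()].
#' @return An [event_log()]; attribute `deviated_cases` lists the edited
#'   cases.
#' @examples
#' log <- sample_log(generator_spec(pt_seq("A", "B"), n_cases = 5))
#' traces(log)
#' @export
sample_log <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  ids <- sprintf("%s_%05d", spec$name, seq_len(spec$n_cases))
  tr <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    t <- sample_trace(spec$tree)
    tries <- 0
    while (length(t) == 0 && tries < 100) {
      t <- sample_trace(spec$tree)
      tries <- tries + 1
    }
    if (length(t) == 0) {
      stop("generator tree produces only empty traces")
    }
    tr[[i]] <- t
  }
  names(tr) <- ids
  log <- traces_with_times(tr, spec)
  if (spec$deviation_rate > 0) {
    log <- inject_deviations(log, spec$deviation_rate,
                             spec$deviation_kinds,
                             seed = spec$seed + 1L,
                             spec = spec)
  } else {
    attr(log, "deviated_cases") <- character(0)
  }
  log
}

traces_with_times <- function(tr, spec) {
  n <- lengths(tr)
  gaps <- ceiling(stats::rexp(sum(n),
                              rate = 1 / spec$mean_gap_days) * 86400)
  offsets <- unlist(lapply(split(gaps, rep(seq_along(n), n)), cumsum),
                    use.names = FALSE)
  events <- data.frame(
    case_id = rep(names(tr), n),
    activity = unlist(tr, use.names = FALSE),
    timestamp = spec$start_date + offsets,
    stringsAsFactors = FALSE
  )
  event_log(events, name = spec$name)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Inject per-trace deviations into a log
#'
#' Each trace independently deviates with probability `rate` by one
#' uniformly chosen edit: `insert` a random alphabet activity at a random
#' position, `skip` (drop) one event, or `swap` two adjacent events. A skip
#' on a length-one trace falls back to an insert. Edited traces get fresh
#' synthetic daily timestamps (their length may have changed). This
#' operationalizes deviating patients — cases whose behaviour departs from
#' the modeled pathway.
#'
#' @param log An [event_log()].
#' @param rate Deviation probability per trace.
#' @param kinds Subset of `c("insert", "skip", "swap")`.
#' @param seed Integer seed.
#' @param spec Optional [generator_spec()] supplying the timing model.
#' @return An [event_log()] with attribute `deviated_cases`.
#' @export
inject_deviations <- function(log, rate, kinds = c("insert", "skip",
                                                   "swap"),
                              seed = 1L, spec = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  kinds <- match.arg(kinds, several.ok = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr <- traces(log)
  alphabet <- log$alphabet
  deviate <- stats::runif(length(tr)) < rate
  for (i in which(deviate)) {
    t <- tr[[i]]
    kind <- kinds[sample.int(length(kinds), 1)]
    if (kind != "insert" && length(t) == 1) kind <- "insert"
    tr[[i]] <- switch(kind,
      insert = {
        pos <- sample.int(length(t) + 1, 1)
        append(t, alphabet[sample.int(length(alphabet), 1)], after = pos - 1)
      },
      skip = t[-sample.int(length(t), 1)],
      swap = {
        j <- sample.int(length(t) - 1, 1)
        t[c(j, j + 1)] <- t[c(j + 1, j)]
        t
      }
    )
  }
  if (is.null(spec)) {
    spec <- list(start_date = min(log$events$timestamp), mean_gap_days = 1)
  }
  out <- traces_with_times(tr, list(start_date = spec$start_date,
                                    mean_gap_days = spec$mean_gap_days))
  out$name <- log$name
  out$case_attrs <- log$case_attrs
  attr(out, "deviated_cases") <- names(tr)[deviate]
  out
}

#' Build populations with controlled patient overlap
#'
#' Samples one log per spec, then realizes pairwise overlap targets
#' constructively: for a target Jaccard coefficient `j` between populations
#' of sizes `nA` and `nB`, `s = round(j (nA + nB) / (1 + j))` cases of the
#' first population are copied — identical case ids and identical traces —
#' into the second, replacing unshared cases. Shared cases therefore carry
#' the first population's pathway in both logs. Targets are checked for
#' feasibility (enough unshared cases on both sides) before any sampling.
#'
#' @param specs Named list of [generator_spec()]s.
#' @param overlap Data frame with columns `pop1`, `pop2`, `jaccard`
#'   (targets; omit or empty for disjoint populations).
#' @return Named list of [event_log()]s.
#' @examples
#' sp <- list(
#'   a = generator_spec(pt_seq("A", "B"), n_cases = 50, seed = 1, name = "a"),
#'   b = generator_spec(pt_seq("A", "C"), n_cases = 50, seed = 2, name = "b")
#' )
#' pops <- make_populations(sp, data.frame(pop1 = "a", pop2 = "b",
#'                                         jaccard = 0.25))
#' jaccard_overlap(pops$a, pops$b)
#' @export
make_populations <- function(specs, overlap = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1,
            !is.null(names(specs)), all(nzchar(names(specs))))
  for (s in specs) stopifnot(inherits(s, "generator_spec"))
  if (is.null(overlap)) {
    overlap <- data.frame(pop1 = character(0), pop2 = character(0),
                          jaccard = numeric(0))
  }
  if (nrow(overlap) > 0) {
    bad <- setdiff(c(overlap$pop1, overlap$pop2), names(specs))
    if (length(bad) > 0) stop("overlap names unknown population(s): ",
                              paste(bad, collapse = ", "))
    if (any(overlap$jaccard < 0 | overlap$jaccard > 1)) {
      stop("jaccard targets must lie in [0, 1]")
    }
    shares <- integer(nrow(overlap))
    for (i in seq_len(nrow(overlap))) {
      nA <- specs[[overlap$pop1[i]]]$n_cases
      nB <- specs[[overlap$pop2[i]]]$n_cases
      shares[i] <- round(overlap$jaccard[i] * (nA + nB) /
                           (1 + overlap$jaccard[i]))
      if (shares[i] > min(nA, nB)) {
        stop("infeasible overlap target ", overlap$jaccard[i], " for '",
             overlap$pop1[i], "'/'", overlap$pop2[i], "'")
      }
    }
    demand <- stats::aggregate(
      c(shares, shares),
      by = list(pop = c(overlap$pop1, overlap$pop2)), FUN = sum)
    for (k in seq_len(nrow(demand))) {
      if (demand$x[k] > specs[[demand$pop[k]]]$n_cases) {
        stop("infeasible overlap system: population '", demand$pop[k],
             "' would need ", demand$x[k], " shared cases but has only ",
             specs[[demand$pop[k]]]$n_cases)
      }
    }
  }
  logs <- lapply(specs, sample_log)
  touched <- stats::setNames(vector("list", length(specs)), names(specs))
  if (nrow(overlap) > 0) {
    for (i in seq_len(nrow(overlap))) {
      a <- overlap$pop1[i]; b <- overlap$pop2[i]
      s <- round(overlap$jaccard[i] *
                   (specs[[a]]$n_cases + specs[[b]]$n_cases) /
                   (1 + overlap$jaccard[i]))
      if (s == 0) next
      free_a <- setdiff(case_ids(logs[[a]]), unlist(touched[[a]]))
      free_b <- setdiff(case_ids(logs[[b]]), unlist(touched[[b]]))
      share_ids <- free_a[seq_len(s)]
      replace_ids <- free_b[seq_len(s)]
      ev_b <- logs[[b]]$events
      ev_b <- ev_b[!(ev_b$case_id %in% replace_ids), , drop = FALSE]
      ev_shared <- logs[[a]]$events
      ev_shared <- ev_shared[ev_shared$case_id %in% share_ids, ,
                             drop = FALSE]
      logs[[b]] <- event_log(rbind(ev_b, ev_shared),
                             name = logs[[b]]$name)
      touched[[a]] <- c(touched[[a]], share_ids)
      touched[[b]] <- c(touched[[b]], share_ids)
    }
  }
  logs
}

#' Preset generator trees shaped like clinical domains
#'
#' Two ready-made process trees for simulation: `"breast"` is a four-activity
#' breast-cancer-like pathway (radiology always first, then an optional
#' pathology workup with a possible multidisciplinary-board review, then an
#' optional surgery); `"icu"` is an eight-activity ICU-procedure-like
#' pathway (evaluation and management first, imaging and laboratory work in
#' parallel, a medicine/surgery treatment loop, then optional anesthesia and
#' a performance-measurement step). Labels only — no clinical claims.
#'
#' @param name `"breast"` or `"icu"`.
#' @return A [process_tree] with branch probabilities set.
#' @export
preset_tree <- function(name = c("breast", "icu")) {
  name <- match.arg(name)
  if (name == "breast") {
    pt_seq(
      "radiology",
      pt_xor(pt_seq("pathology",
                    pt_xor("mdo", pt_tau(), probs = c(0.4, 0.6))),
             pt_tau(), probs = c(0.75, 0.25)),
      pt_xor("surgery", pt_tau(), probs = c(0.3, 0.7))
    )
  } else {
    pt_seq(
      "evaluation_management",
      pt_and(pt_xor("radiology", "emerging_technology",
                    probs = c(0.85, 0.15)),
             "pathology_laboratory"),
      pt_loop(pt_xor("medicine", "surgery", probs = c(0.7, 0.3)),
              cont = 0.25),
      pt_xor("anesthesia", pt_tau(), probs = c(0.3, 0.7)),
      pt_xor("performance_measurement", pt_tau(), probs = c(0.5, 0.5))
    )
  }
}
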