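#' Discover a process tree from an event log
#'
#' Inductive-miner-family discovery: the directly-follows graph of the log is
#' recursively partitioned by cut detection, in the fixed order sequence,
#' exclusive choice, parallel, loop, with lexicographic tie-breaking, so that
#' the same log always yields the same tree. When no cut is found the
#' recursion falls back to a flower model (a loop over the exclusive choice of
#' all activities), which accepts any ordering of the involved activities.
#'
#' Frequency-based noise filtering: before cut detection, directly-follows
#' edges whose frequency is below `(1 - noise_threshold)` times the largest
#' edge frequency leaving the same activity are dropped. `noise_threshold = 1`
#' keeps every edge (no filtering), in which case every input trace is
#' replayable on the discovered model — the classic inductive-miner fitness
#' guarantee. Lower thresholds prune rare behaviour, and traces relying on it
#' become deviations.
#'
#' @param log An [event_log()].
#' @param noise_threshold Fraction in \[0, 1\]; 1 keeps all behaviour.
#' @return A [process_tree] object.
#' @examples
#' log <- log_from_traces(list(p1 = c("A", "B"), p2 = c("A", "B")))
#' discover_tree(log)  # SEQ(A,B)
#' @export
discover_tree <- function(log, noise_threshold = 1) {
  stopifnot(inherits(log, "event_log"))
  if (nrow(log$events) == 0 || length(log$alphabet) == 0) {
    stop("cannot discover a model from an empty log")
  }
  if (noise_threshold < 0 || noise_threshold > 1) {
    stop("noise_threshold must lie in [0, 1]")
  }
  tv <- trace_variants(log)
  tr <- rep(tv$variants, tv$counts)
  im_discover(tr, noise_threshold)
}

#' Directly-follows graph of an event log
#'
#' Counts, over all traces, how often activity `a` is immediately followed by
#' activity `b`, plus how often each activity starts or ends a trace.
#'
#' @param log An [event_log()].
#' @return A list with `edges` (data frame `from`, `to`, `n`), `starts` and
#'   `ends` (named integer vectors).
#' @export
directly_follows <- function(log) {
  stopifnot(inherits(log, "event_log"))
  dfg_from_traces(traces(log))
}

dfg_from_traces <- function(tr) {
  from <- character(0); to <- character(0)
  starts <- character(0); ends <- character(0)
  for (t in tr) {
    if (length(t) == 0) next
    starts <- c(starts, t[1])
    ends <- c(ends, t[length(t)])
    if (length(t) > 1) {
      from <- c(from, t[-length(t)])
      to <- c(to, t[-1])
    }
  }
  if (length(from) > 0) {
    key <- paste(from, to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, character(1), 1),
      to = vapply(parts, `[`, character(1), 2),
      n = as.integer(tab),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        n = integer(0), stringsAsFactors = FALSE)
  }
  list(
    edges = edges[order(edges$from, edges$to), , drop = FALSE],
    starts = table_to_named_int(starts),
    ends = table_to_named_int(ends)
  )
}

table_to_named_int <- function(x) {
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

filter_dfg <- function(dfg, noise_threshold) {
  if (noise_threshold >= 1) return(dfg)
  # the filter is relative to the strongest outgoing connection of the same
  # activity, with trace ends counting as an edge to a virtual END node —
  # without the END convention a terminal activity's only outgoing edges are
  # noise, the maximum is itself noise, and nothing gets filtered
  out_max <- function(a) {
    max(c(dfg$edges$n[dfg$edges$from == a],
          unname(dfg$ends[a])), 0, na.rm = TRUE)
  }
  floor_of <- function(a) (1 - noise_threshold) * out_max(a)
  if (nrow(dfg$edges) > 0) {
    keep <- dfg$edges$n >= vapply(dfg$edges$from, floor_of, numeric(1))
    dfg$edges <- dfg$edges[keep, , drop = FALSE]
  }
  if (length(dfg$ends) > 0) {
    dfg$ends <- dfg$ends[dfg$ends >=
                           vapply(names(dfg$ends), floor_of, numeric(1))]
  }
  # starts filter against the strongest start (virtual START node)
  if (length(dfg$starts) > 0) {
    dfg$starts <- dfg$starts[dfg$starts >=
                               (1 - noise_threshold) * max(dfg$starts)]
  }
  dfg
}

im_discover <- function(tr, noise_threshold) {
  n_all <- length(tr)
  n_empty <- sum(lengths(tr) == 0)
  # an empty-trace share below the noise floor is infrequent behaviour
  has_empty <- n_empty > 0 &&
    (noise_threshold >= 1 || n_empty > (1 - noise_threshold) * n_all)
  tr <- tr[lengths(tr) > 0]
  if (length(tr) == 0) return(pt_tau())
  alpha <- sort(unique(unlist(tr, use.names = FALSE)))

  sub <- NULL
  if (length(alpha) == 1) {
    a <- alpha
    n_rep <- sum(lengths(tr) > 1)
    loops <- n_rep > 0 &&
      (noise_threshold >= 1 || n_rep > (1 - noise_threshold) * length(tr))
    if (!loops) {
      sub <- pt_leaf(a)
    } else {
      # repeated single activity: tight self-loop
      sub <- pt_loop(pt_leaf(a))
    }
  } else {
    dfg <- filter_dfg(dfg_from_traces(tr), noise_threshold)
    # traces may lose edges to filtering; cut detection sees the kept graph
    cut <- find_seq_cut(dfg, alpha)
    kind <- "seq"
    if (is.null(cut)) { cut <- find_xor_cut(dfg, alpha); kind <- "xor" }
    if (is.null(cut)) { cut <- find_and_cut(dfg, alpha); kind <- "and" }
    if (is.null(cut)) { cut <- find_loop_cut(dfg, alpha); kind <- "loop" }
    if (is.null(cut)) {
      sub <- flower_model(alpha)
    } else {
      logs <- project_traces(tr, cut, kind)
      children <- lapply(logs, im_discover, noise_threshold = noise_threshold)
      sub <- switch(kind,
        seq = pt_node("seq", children),
        xor = pt_node("xor", children),
        and = pt_node("and", children),
        loop = pt_node("loop", children, cont = 0.5)
      )
    }
  }
  if (has_empty) pt_node("xor", list(sub, pt_tau())) else sub
}

#' Flower model over an activity alphabet
#'
#' The fallback model accepting any sequence (including repetitions) of the
#' given activities: a loop whose redo part is the exclusive choice of all
#' activities.
#'
#' @param alphabet Character vector of activities.
#' @return A [process_tree].
#' @export
flower_model <- function(alphabet) {
  stopifnot(length(alphabet) >= 1)
  alphabet <- sort(alphabet)
  choice <- if (length(alphabet) == 1) pt_leaf(alphabet) else
    do.call(pt_xor, lapply(alphabet, pt_leaf))
  pt_node("loop", list(pt_tau(), choice), cont = 0.5)
}

reach_closure <- function(adj, alpha) {
  # boolean reachability over the directly-follows edges (transitive closure)
  n <- length(alpha)
  m <- matrix(FALSE, n, n, dimnames = list(alpha, alpha))
  if (nrow(adj) > 0) m[cbind(adj$from, adj$to)] <- TRUE
  for (k in seq_len(n)) m <- m | (m[, k] %o% m[k, ])
  m
}

find_seq_cut <- function(dfg, alpha) {
  # merge mutually reachable (and mutually unreachable) activities, then
  # order the groups by reachability; >= 2 ordered groups is a sequence cut
  reach <- reach_closure(dfg$edges, alpha)
  n <- length(alpha)
  same <- (reach & t(reach)) | (!reach & !t(reach))
  diag(same) <- TRUE
  groups <- components_of(same, alpha)
  if (length(groups) < 2) return(NULL)
  # order groups: g1 before g2 iff some activity of g1 reaches g2; a valid
  # sequence cut gives each group as many predecessors as its position
  before <- function(g1, g2) any(reach[g1, g2])
  n_pred <- vapply(groups, function(g) {
    sum(vapply(groups, before, logical(1), g2 = g))
  }, numeric(1))
  groups <- groups[order(n_pred)]
  # validate total order
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j && (!before(groups[[i]], groups[[j]]) ||
                  before(groups[[j]], groups[[i]]))) {
      return(NULL)
    }
  }
  groups
}

components_of <- function(conn, alpha) {
  # connected components of a boolean symmetric relation, lexicographic order
  n <- length(alpha)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(apply(conn[frontier, , drop = FALSE], 2, any) &
                   is.na(comp))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  lapply(seq_len(cur), function(k) alpha[comp == k])
}

find_xor_cut <- function(dfg, alpha) {
  n <- length(alpha)
  conn <- matrix(FALSE, n, n, dimnames = list(alpha, alpha))
  if (nrow(dfg$edges) > 0) {
    conn[cbind(dfg$edges$from, dfg$edges$to)] <- TRUE
    conn <- conn | t(conn)
  }
  groups <- components_of(conn, alpha)
  if (length(groups) < 2) return(NULL)
  groups
}

find_and_cut <- function(dfg, alpha) {
  # join a,b when NOT doubly connected; components of that graph are the
  # parallel parts, each of which must contain a start and an end activity
  n <- length(alpha)
  adj <- matrix(FALSE, n, n, dimnames = list(alpha, alpha))
  if (nrow(dfg$edges) > 0) adj[cbind(dfg$edges$from, dfg$edges$to)] <- TRUE
  dbl <- adj & t(adj)
  joined <- !dbl
  diag(joined) <- TRUE
  groups <- components_of(joined, alpha)
  if (length(groups) < 2) return(NULL)
  s <- names(dfg$starts); e <- names(dfg$ends)
  for (g in groups) {
    if (!any(g %in% s) || !any(g %in% e)) return(NULL)
  }
  groups
}

find_loop_cut <- function(dfg, alpha) {
  # body = activities connected to trace starts/ends; redo = the rest, with
  # edges only from ends into redo and from redo back into starts
  s <- names(dfg$starts); e <- names(dfg$ends)
  body <- union(s, e)
  redo <- setdiff(alpha, body)
  if (length(redo) == 0) return(NULL)
  edges <- dfg$edges
  for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]; t <- edges$to[i]
    if (f %in% body && t %in% redo && !(f %in% e)) return(NULL)
    if (f %in% redo && t %in% body && !(t %in% s)) return(NULL)
  }
  # split redo into its weakly connected components, each a redo child
  sub <- edges[edges$from %in% redo & edges$to %in% redo, , drop = FALSE]
  n <- length(redo)
  conn <- matrix(FALSE, n, n, dimnames = list(redo, redo))
  if (nrow(sub) > 0) {
    conn[cbind(sub$from, sub$to)] <- TRUE
    conn <- conn | t(conn)
  }
  c(list(sort(body)), components_of(conn, redo))
}

project_traces <- function(tr, groups, kind) {
  if (kind == "seq") {
    # split each trace at group boundaries (activities keep their group)
    lapply(seq_along(groups), function(k) {
      g <- groups[[k]]
      lapply(tr, function(t) t[t %in% g])
    })
  } else if (kind == "xor") {
    assign_grp <- function(t) {
      hits <- vapply(groups, function(g) sum(t %in% g), integer(1))
      which.max(hits)
    }
    grp <- vapply(tr, assign_grp, integer(1))
    lapply(seq_along(groups), function(k) {
      sel <- tr[grp == k]
      # activities outside the group are dropped (noise-filtered behaviour)
      lapply(sel, function(t) t[t %in% groups[[k]]])
    })
  } else if (kind == "and") {
    lapply(groups, function(g) lapply(tr, function(t) t[t %in% g]))
  } else { # loop: body is groups[[1]], redo parts follow
    body <- groups[[1]]
    out <- vector("list", length(groups))
    for (k in seq_along(groups)) out[[k]] <- list()
    for (t in tr) {
      in_body <- t %in% body
      if (length(t) == 0) next
      # segment the trace into alternating body/redo runs
      runs <- rle(in_body)
      pos <- cumsum(c(1, runs$lengths))
      for (r in seq_along(runs$values)) {
        seg <- t[pos[r]:(pos[r + 1] - 1)]
        if (runs$values[r]) {
          out[[1]] <- c(out[[1]], list(seg))
        } else {
          k <- which(vapply(groups[-1], function(g) seg[1] %in% g,
                            logical(1)))[1] + 1L
          out[[k]] <- c(out[[k]], list(seg[seg %in% groups[[k]]]))
        }
      }
    }
    # a redo group with no observed segment still needs a child
    for (k in seq_along(out)) {
      if (length(out[[k]]) == 0) out[[k]] <- list(groups[[k]][1])
    }
    out
  }
}
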