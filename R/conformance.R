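#' Token-based replay of a log on a Petri net
#'
#' Each trace is replayed from the initial marking. When the transition for
#' the next activity is not enabled, the shortest sequence of silent
#' transitions that enables it is fired first (breadth-first search, depth
#' capped, ties broken by lexicographic transition id); if that fails, the
#' missing input tokens are inserted (and counted) to force the firing. At
#' the end of the trace the final marking is consumed, inserting missing
#' tokens where needed, and leftover tokens are counted as remaining.
#' Produced and consumed totals include the initial-marking production and
#' final-marking consumption. An activity absent from the net's alphabet is a
#' log-only move: it contributes one missing and one consumed token and moves
#' on — never a crash.
#'
#' Replay runs once per trace variant and weights the token counts by the
#' variant frequency.
#'
#' @param log An [event_log()].
#' @param net A workflow [petri_net()].
#' @param silent_depth Maximum silent-transition sequence searched when
#'   enabling a label.
#' @return A `replay_result`: per-variant token counts (`produced`,
#'   `consumed`, `missing`, `remaining`, `reached_final`, `n_cases`) and
#'   their weighted `totals`.
#' @export
token_replay <- function(log, net, silent_depth = 10) {
  stopifnot(inherits(log, "event_log"), inherits(net, "petri_net"))
  tv <- trace_variants(log)
  rows <- lapply(tv$variants, replay_variant, net = net,
                 silent_depth = silent_depth)
  per <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(per)) {
    per <- data.frame(produced = numeric(0), consumed = numeric(0),
                      missing = numeric(0), remaining = numeric(0),
                      reached_final = logical(0))
  }
  per$n_cases <- tv$counts
  totals <- c(
    produced = sum(per$produced * per$n_cases),
    consumed = sum(per$consumed * per$n_cases),
    missing = sum(per$missing * per$n_cases),
    remaining = sum(per$remaining * per$n_cases)
  )
  structure(list(per_variant = per, totals = totals,
                 variants = tv$variants),
            class = "replay_result")
}

#' @export
print.replay_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "Token replay: produced=%g consumed=%g missing=%g remaining=%g\n",
    t["produced"], t["consumed"], t["missing"], t["remaining"]))
  cat(sprintf("%d/%d variants reached the final marking\n",
              sum(x$per_variant$reached_final), nrow(x$per_variant)))
  invisible(x)
}

# BFS for the shortest silent firing sequence enabling transition `target`
silent_enable <- function(net, m, target, depth) {
  if (is_enabled(net, m, target)) return(character(0))
  silent <- sort(net$transitions$id[is.na(net$transitions$label)])
  frontier <- list(list(m = m, seq = character(0)))
  seen <- new.env(hash = TRUE)
  seen[[marking_key(m)]] <- TRUE
  for (d in seq_len(depth)) {
    nxt <- list()
    for (st in frontier) {
      for (tid in silent) {
        if (!is_enabled(net, st$m, tid)) next
        m2 <- fire(net, st$m, tid)
        key <- marking_key(m2)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        s2 <- c(st$seq, tid)
        if (is_enabled(net, m2, target)) return(s2)
        nxt[[length(nxt) + 1]] <- list(m = m2, seq = s2)
      }
    }
    if (length(nxt) == 0) break
    frontier <- nxt
  }
  NULL
}

replay_variant <- function(trace, net, silent_depth = 10) {
  labels <- stats::setNames(net$transitions$label, net$transitions$id)
  m <- net$im
  produced <- sum(net$im)
  consumed <- 0; missing <- 0
  alphabet <- net_activities(net)

  fire_count <- function(tid) {
    consumed <<- consumed + length(net$pre[[tid]])
    produced <<- produced + length(net$post[[tid]])
    m <<- fire(net, m, tid)
  }

  for (a in trace) {
    if (!(a %in% alphabet)) {
      # log-only move: the model has no transition for this activity
      missing <- missing + 1
      consumed <- consumed + 1
      next
    }
    cands <- sort(names(labels)[!is.na(labels) & labels == a])
    fired <- FALSE
    for (tid in cands) {
      if (is_enabled(net, m, tid)) {
        fire_count(tid)
        fired <- TRUE
        break
      }
    }
    if (fired) next
    for (tid in cands) {
      taus <- silent_enable(net, m, tid, silent_depth)
      if (!is.null(taus)) {
        for (s in taus) fire_count(s)
        fire_count(tid)
        fired <- TRUE
        break
      }
    }
    if (fired) next
    # force the firing: insert missing tokens for the cheapest candidate
    deficits <- vapply(cands, function(tid) {
      need <- table(net$pre[[tid]])
      have <- m[names(need)]; have[is.na(have)] <- 0L
      sum(pmax(as.integer(need) - as.integer(have), 0))
    }, numeric(1))
    tid <- cands[which.min(deficits)]
    need <- table(net$pre[[tid]])
    for (p in names(need)) {
      have <- if (is.na(m[p])) 0L else m[p]
      if (have < need[[p]]) {
        missing <- missing + (need[[p]] - have)
        m[p] <- as.integer(need[[p]])
      }
    }
    fire_count(tid)
  }

  # reach for the final marking through silent transitions if needed
  if (!marking_eq(m, net$fm)) {
    path <- silent_to_marking(net, m, net$fm, silent_depth)
    if (!is.null(path)) for (s in path) fire_count(s)
  }
  reached <- marking_eq(m, net$fm)
  # consume the final marking
  for (p in names(net$fm)) {
    have <- if (is.na(m[p])) 0L else m[p]
    if (have < net$fm[p]) missing <- missing + (net$fm[p] - have)
    m[p] <- max(have - net$fm[p], 0L)
    consumed <- consumed + net$fm[p]
  }
  remaining <- sum(m)
  list(produced = produced, consumed = consumed, missing = missing,
       remaining = remaining, reached_final = reached)
}

silent_to_marking <- function(net, m, fm, depth) {
  if (marking_eq(m, fm)) return(character(0))
  silent <- sort(net$transitions$id[is.na(net$transitions$label)])
  frontier <- list(list(m = m, seq = character(0)))
  seen <- new.env(hash = TRUE)
  seen[[marking_key(m)]] <- TRUE
  for (d in seq_len(depth)) {
    nxt <- list()
    for (st in frontier) {
      for (tid in silent) {
        if (!is_enabled(net, st$m, tid)) next
        m2 <- fire(net, st$m, tid)
        key <- marking_key(m2)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        s2 <- c(st$seq, tid)
        if (marking_eq(m2, fm)) return(s2)
        nxt[[length(nxt) + 1]] <- list(m = m2, seq = s2)
      }
    }
    if (length(nxt) == 0) break
    frontier <- nxt
  }
  NULL
}

#' Token-replay fitness
#'
#' The standard token-replay fitness
#' `1/2 (1 - missing/consumed) + 1/2 (1 - remaining/produced)`:
#' 1 exactly when replay needed no missing tokens and left none behind.
#'
#' @param rep A `replay_result` from [token_replay()].
#' @return A fraction in \[0, 1\].
#' @export
fitness <- function(rep) {
  stopifnot(inherits(rep, "replay_result"))
  t <- rep$totals
  if (t["consumed"] == 0 || t["produced"] == 0) {
    stop("fitness is undefined without produced and consumed tokens")
  }
  unname(0.5 * (1 - t["missing"] / t["consumed"]) +
         0.5 * (1 - t["remaining"] / t["produced"]))
}

#' Escaping-edges precision
#'
#' Replays every observed trace prefix on the net and compares, at each
#' replay state, the activities the model enables (through silent-transition
#' closure) with the activities actually observed next in the log. Precision
#' is one minus the visit-weighted fraction of enabled activities that are
#' never observed ("escaping edges"). A model that allows exactly the
#' observed behaviour scores 1; a flower model, which enables everything
#' everywhere, scores strictly lower on any non-trivial log.
#'
#' @param log An [event_log()].
#' @param net A workflow [petri_net()].
#' @param silent_depth Silent-closure search depth.
#' @return A fraction in \[0, 1\].
#' @export
precision <- function(log, net, silent_depth = 10) {
  stopifnot(inherits(log, "event_log"), inherits(net, "petri_net"))
  tv <- trace_variants(log)
  states <- new.env(hash = TRUE)  # prefix key -> list(marking, w, observed)
  for (i in seq_along(tv$variants)) {
    trace <- tv$variants[[i]]
    w <- tv$counts[i]
    m <- net$im
    for (pos in 0:length(trace)) {
      key <- paste0("k:", paste(trace[seq_len(pos)], collapse = "\r"))
      nxt <- if (pos < length(trace)) trace[pos + 1] else NULL
      st <- states[[key]]
      if (is.null(st)) {
        st <- list(m = m, w = 0, observed = character(0))
      }
      st$w <- st$w + w
      if (!is.null(nxt)) st$observed <- union(st$observed, nxt)
      states[[key]] <- st
      if (pos < length(trace)) {
        m <- replay_step(net, m, trace[pos + 1], silent_depth)
      }
    }
  }
  num <- 0; den <- 0
  for (key in ls(states)) {
    st <- states[[key]]
    enabled <- enabled_labels(net, st$m, silent_depth)
    den <- den + st$w * length(enabled)
    num <- num + st$w * length(setdiff(enabled, st$observed))
  }
  if (den == 0) return(1)
  1 - num / den
}

# advance a marking by one labeled step, with the token_replay mechanics
replay_step <- function(net, m, a, silent_depth) {
  labels <- stats::setNames(net$transitions$label, net$transitions$id)
  cands <- sort(names(labels)[!is.na(labels) & labels == a])
  if (length(cands) == 0) return(m)  # log-only move leaves the marking
  for (tid in cands) {
    if (is_enabled(net, m, tid)) return(fire(net, m, tid))
  }
  for (tid in cands) {
    taus <- silent_enable(net, m, tid, silent_depth)
    if (!is.null(taus)) {
      for (s in taus) m <- fire(net, m, s)
      return(fire(net, m, tid))
    }
  }
  tid <- cands[1]
  need <- table(net$pre[[tid]])
  for (p in names(need)) {
    have <- if (is.na(m[p])) 0L else m[p]
    if (have < need[[p]]) m[p] <- as.integer(need[[p]])
  }
  fire(net, m, tid)
}

# labels reachable by firing at most `depth` silent transitions
enabled_labels <- function(net, m, depth) {
  labels <- stats::setNames(net$transitions$label, net$transitions$id)
  labeled <- names(labels)[!is.na(labels)]
  silent <- sort(names(labels)[is.na(labels)])
  out <- character(0)
  frontier <- list(m)
  seen <- new.env(hash = TRUE)
  seen[[marking_key(m)]] <- TRUE
  for (d in 0:depth) {
    for (mm in frontier) {
      for (tid in labeled) {
        if (is_enabled(net, mm, tid)) out <- union(out, labels[[tid]])
      }
    }
    nxt <- list()
    for (mm in frontier) {
      for (tid in silent) {
        if (!is_enabled(net, mm, tid)) next
        m2 <- fire(net, mm, tid)
        key <- marking_key(m2)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1]] <- m2
        }
      }
    }
    if (length(nxt) == 0) break
    frontier <- nxt
  }
  out
}

#' Cross-log conformance of two populations
#'
#' Replays each population's log on the other population's model: `F12`/`P12`
#' are the fitness and precision of log 1 against model 2, `F21`/`P21` the
#' mirrored direction, and `F_avg`/`P_avg` their means.
#'
#' @param logA,logB [event_log()]s of the two populations.
#' @param netA,netB Their models as [petri_net()]s; discovered from the
#'   respective logs when omitted.
#' @param noise_threshold Discovery noise threshold used when a net must be
#'   discovered.
#' @return A `cross_result`: list with `F12`, `P12`, `F21`, `P21`, `F_avg`,
#'   `P_avg`.
#' @export
cross_conformance <- function(logA, logB, netA = NULL, netB = NULL,
                              noise_threshold = 1) {
  stopifnot(inherits(logA, "event_log"), inherits(logB, "event_log"))
  if (is.null(netA)) netA <- tree_to_petri(discover_tree(logA,
                                                         noise_threshold))
  if (is.null(netB)) netB <- tree_to_petri(discover_tree(logB,
                                                         noise_threshold))
  F12 <- fitness(token_replay(logA, netB))
  P12 <- precision(logA, netB)
  F21 <- fitness(token_replay(logB, netA))
  P21 <- precision(logB, netA)
  structure(list(F12 = F12, P12 = P12, F21 = F21, P21 = P21,
                 F_avg = (F12 + F21) / 2, P_avg = (P12 + P21) / 2),
            class = "cross_result")
}

#' @export
print.cross_result <- function(x, ...) {
  cat(sprintf(
    "Cross conformance: F12=%.3f P12=%.3f F21=%.3f P21=%.3f F=%.3f P=%.3f\n",
    x$F12, x$P12, x$F21, x$P21, x$F_avg, x$P_avg))
  invisible(x)
}
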