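#' Construct a Petri net
#'
#' A workflow Petri net: places, transitions (labeled transitions are
#' observable events, unlabeled ones are silent routing steps), directed arcs
#' between places and transitions, and initial/final markings. Validity is
#' checked on construction: arcs must connect a place to a transition or vice
#' versa, and markings must reference existing places.
#'
#' @param places Character vector of place ids.
#' @param transitions Data frame with columns `id`, `label` (`NA` for silent)
#'   and optionally `node` (provenance tag used by frequency annotation).
#' @param arcs Data frame with columns `from`, `to` (ids of places and
#'   transitions).
#' @param im,fm Named integer vectors: tokens per place in the initial and
#'   final marking.
#' @return A `petri_net` object.
#' @export
petri_net <- function(places, transitions, arcs, im, fm) {
  stopifnot(is.character(places), is.data.frame(transitions),
            is.data.frame(arcs))
  if (!"node" %in% names(transitions)) transitions$node <- NA_character_
  transitions$id <- as.character(transitions$id)
  transitions$label <- as.character(transitions$label)
  if (anyDuplicated(c(places, transitions$id))) {
    stop("place and transition ids must be unique")
  }
  is_place_from <- arcs$from %in% places
  is_place_to <- arcs$to %in% places
  is_trans_from <- arcs$from %in% transitions$id
  is_trans_to <- arcs$to %in% transitions$id
  ok <- (is_place_from & is_trans_to) | (is_trans_from & is_place_to)
  if (nrow(arcs) > 0 && !all(ok)) {
    stop("arcs must connect place->transition or transition->place")
  }
  if (!all(names(im) %in% places) || !all(names(fm) %in% places)) {
    stop("markings must reference existing places")
  }
  net <- structure(list(places = places, transitions = transitions,
                        arcs = arcs, im = im[im > 0], fm = fm[fm > 0]),
                   class = "petri_net")
  net$pre <- split(as.character(arcs$from[is_place_from]),
                   factor(arcs$to[is_place_from], levels = transitions$id))
  net$post <- split(as.character(arcs$to[is_trans_from]),
                    factor(arcs$from[is_trans_from], levels = transitions$id))
  net
}

#' @export
print.petri_net <- function(x, ...) {
  n_lab <- sum(!is.na(x$transitions$label))
  cat(sprintf(
    "Petri net: %d places, %d transitions (%d labeled, %d silent), %d arcs\n",
    length(x$places), nrow(x$transitions), n_lab,
    nrow(x$transitions) - n_lab, nrow(x$arcs)))
  invisible(x)
}

#' Labeled activities of a Petri net
#' @param net A `petri_net`.
#' @return Sorted character vector of transition labels.
#' @export
net_activities <- function(net) {
  sort(unique(net$transitions$label[!is.na(net$transitions$label)]))
}

#' Convert a process tree into a workflow Petri net
#'
#' Compositional construction with a single source and a single sink place:
#' sequence children chain through shared places, exclusive-choice children
#' share their entry and exit places, parallel children are wrapped in silent
#' fork/join transitions, and a loop gets silent enter/exit transitions with
#' each redo part closing the cycle back to the body. Every transition is
#' tagged with the tree node it implements, which is what lets frequency
#' annotation attribute replayed behaviour back to tree nodes.
#'
#' @param tree A [process_tree].
#' @return A [petri_net()] whose language equals the tree's.
#' @examples
#' net <- tree_to_petri(pt_seq("A", "B"))
#' net  # 3 places, 2 labeled transitions
#' @export
tree_to_petri <- function(tree) {
  stopifnot(inherits(tree, "process_tree"))
  env <- new.env()
  env$places <- character(0)
  env$trans <- list()
  env$arcs_from <- character(0)
  env$arcs_to <- character(0)
  env$np <- 0L; env$nt <- 0L

  new_place <- function() {
    env$np <- env$np + 1L
    p <- sprintf("p%d", env$np)
    env$places <- c(env$places, p)
    p
  }
  new_trans <- function(label, node) {
    env$nt <- env$nt + 1L
    id <- sprintf("t%d", env$nt)
    env$trans[[length(env$trans) + 1]] <-
      data.frame(id = id, label = label, node = node,
                 stringsAsFactors = FALSE)
    id
  }
  arc <- function(from, to) {
    env$arcs_from <- c(env$arcs_from, from)
    env$arcs_to <- c(env$arcs_to, to)
  }

  build <- function(nd, p_in, p_out, path) {
    switch(nd$kind,
      leaf = {
        t <- new_trans(nd$label, path)
        arc(p_in, t); arc(t, p_out)
      },
      tau = {
        t <- new_trans(NA_character_, path)
        arc(p_in, t); arc(t, p_out)
      },
      seq = {
        k <- length(nd$children)
        mids <- c(p_in, replicate(k - 1, new_place()), p_out)
        for (i in seq_len(k)) {
          build(nd$children[[i]], mids[i], mids[i + 1],
                paste0(path, ".", i))
        }
      },
      xor = {
        for (i in seq_along(nd$children)) {
          build(nd$children[[i]], p_in, p_out, paste0(path, ".", i))
        }
      },
      and = {
        fork <- new_trans(NA_character_, paste0(path, ".fork"))
        join <- new_trans(NA_character_, paste0(path, ".join"))
        arc(p_in, fork); arc(join, p_out)
        for (i in seq_along(nd$children)) {
          pi_ <- new_place(); po_ <- new_place()
          arc(fork, pi_); arc(po_, join)
          build(nd$children[[i]], pi_, po_, paste0(path, ".", i))
        }
      },
      loop = {
        enter <- new_trans(NA_character_, paste0(path, ".enter"))
        exit <- new_trans(NA_character_, paste0(path, ".exit"))
        p1 <- new_place(); p2 <- new_place()
        arc(p_in, enter); arc(enter, p1)
        arc(p2, exit); arc(exit, p_out)
        build(nd$children[[1]], p1, p2, paste0(path, ".1"))
        for (i in seq_along(nd$children)[-1]) {
          build(nd$children[[i]], p2, p1, paste0(path, ".", i))
        }
      }
    )
  }

  source_p <- new_place(); sink_p <- new_place()
  build(tree, source_p, sink_p, "r")
  transitions <- do.call(rbind, env$trans)
  arcs <- data.frame(from = env$arcs_from, to = env$arcs_to,
                     stringsAsFactors = FALSE)
  petri_net(env$places, transitions, arcs,
            im = stats::setNames(1L, source_p),
            fm = stats::setNames(1L, sink_p))
}

marking_key <- function(m) {
  m <- m[m > 0]
  m <- m[order(names(m))]
  paste(names(m), m, sep = ":", collapse = ",")
}

marking_eq <- function(a, b) marking_key(a) == marking_key(b)

is_enabled <- function(net, m, tid) {
  pre <- net$pre[[tid]]
  if (length(pre) == 0) return(TRUE)
  need <- table(pre)
  all(names(need) %in% names(m)) &&
    all(m[names(need)] >= as.integer(need))
}

fire <- function(net, m, tid) {
  for (p in net$pre[[tid]]) m[p] <- m[p] - 1L
  post <- net$post[[tid]]
  for (p in post) m[p] <- if (is.na(m[p])) 1L else m[p] + 1L
  m[is.na(m)] <- 0L
  m[m > 0]
}

#' Replay a trace exactly on a Petri net
#'
#' Searches for a firing sequence that reproduces the trace's activities in
#' order (interleaved with silent transitions) and ends in the final marking.
#' This is a language-membership check: it either returns the full firing
#' sequence or `NULL` when the trace does not fit the model.
#'
#' @param net A [petri_net()].
#' @param trace Character vector of activities.
#' @return Character vector of fired transition ids, or `NULL`.
#' @export
replay_trace_exact <- function(net, trace) {
  stopifnot(inherits(net, "petri_net"))
  tids <- net$transitions$id
  labels <- stats::setNames(net$transitions$label, tids)
  silent <- tids[is.na(labels)]
  failed <- new.env(hash = TRUE)

  dfs <- function(m, pos, path_seen) {
    key <- paste0(marking_key(m), "|", pos)
    if (!is.null(failed[[key]]) || !is.null(path_seen[[key]])) return(NULL)
    path_seen[[key]] <- TRUE
    on.exit(rm(list = key, envir = path_seen), add = TRUE)
    if (pos > length(trace)) {
      if (marking_eq(m, net$fm)) return(character(0))
    } else {
      want <- trace[pos]
      for (tid in tids[!is.na(labels) & labels == want]) {
        if (is_enabled(net, m, tid)) {
          res <- dfs(fire(net, m, tid), pos + 1L, new.env(hash = TRUE))
          if (!is.null(res)) return(c(tid, res))
        }
      }
    }
    for (tid in silent) {
      if (is_enabled(net, m, tid)) {
        res <- dfs(fire(net, m, tid), pos, path_seen)
        if (!is.null(res)) return(c(tid, res))
      }
    }
    failed[[key]] <- TRUE
    NULL
  }
  dfs(net$im, 1L, new.env(hash = TRUE))
}

#' Enumerate the bounded language of a Petri net
#'
#' All label sequences of length at most `max_len` that can be produced by
#' firing sequences from the initial to the final marking. Exponential;
#' intended for verifying small nets against [tree_language()].
#'
#' @param net A [petri_net()].
#' @param max_len Maximum trace length enumerated.
#' @return List of unique character vectors.
#' @export
petri_language <- function(net, max_len = 8) {
  out <- new.env(hash = TRUE)
  labels <- stats::setNames(net$transitions$label, net$transitions$id)
  rec <- function(m, seq_, seen) {
    key <- paste0(marking_key(m), "|", paste(seq_, collapse = "\r"))
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    if (marking_eq(m, net$fm)) {
      out[[paste(seq_, collapse = "\r")]] <- seq_
    }
    for (tid in net$transitions$id) {
      if (!is_enabled(net, m, tid)) next
      lab <- labels[[tid]]
      if (is.na(lab)) {
        rec(fire(net, m, tid), seq_, seen)
      } else if (length(seq_) < max_len) {
        rec(fire(net, m, tid), c(seq_, lab), seen)
      }
    }
  }
  rec(net$im, character(0), new.env(hash = TRUE))
  vals <- as.list(out)
  vals <- vals[order(names(vals))]
  names(vals) <- NULL
  lapply(vals, function(v) if (length(v) == 1 && v == "") character(0) else v)
}

#' Write a Petri net to PNML
#'
#' Standard place/transition PNML with the final marking recorded in a
#' `<finalmarkings>` element (the convention used by process-mining tools).
#' Silent transitions are written without a `<name>` element.
#'
#' @param net A [petri_net()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pnml <- function(net, path) {
  doc <- xml2::xml_new_root("pnml")
  nnode <- xml2::xml_add_child(doc, "net", id = "net1",
    type = "http://www.pnml.org/version-2009/grammar/pnmlcoremodel")
  page <- xml2::xml_add_child(nnode, "page", id = "page1")
  for (p in net$places) {
    pn <- xml2::xml_add_child(page, "place", id = p)
    tok <- net$im[p]
    if (!is.na(tok) && tok > 0) {
      mk <- xml2::xml_add_child(pn, "initialMarking")
      xml2::xml_add_child(mk, "text", as.character(tok))
    }
  }
  for (i in seq_len(nrow(net$transitions))) {
    tn <- xml2::xml_add_child(page, "transition",
                              id = net$transitions$id[i])
    lab <- net$transitions$label[i]
    if (!is.na(lab)) {
      nm <- xml2::xml_add_child(tn, "name")
      xml2::xml_add_child(nm, "text", lab)
    }
  }
  for (i in seq_len(nrow(net$arcs))) {
    xml2::xml_add_child(page, "arc", id = sprintf("a%d", i),
                        source = net$arcs$from[i], target = net$arcs$to[i])
  }
  fms <- xml2::xml_add_child(nnode, "finalmarkings")
  mk <- xml2::xml_add_child(fms, "marking")
  for (p in names(net$fm)) {
    pl <- xml2::xml_add_child(mk, "place", idref = p)
    xml2::xml_add_child(pl, "text", as.character(net$fm[p]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Petri net from PNML
#'
#' @param path PNML file written by [write_pnml()] or a compatible tool.
#' @return A [petri_net()].
#' @export
read_pnml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed PNML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  pnodes <- xml2::xml_find_all(doc, ".//page/place")
  places <- xml2::xml_attr(pnodes, "id")
  im <- integer(0)
  for (pn in pnodes) {
    tok <- xml2::xml_find_first(pn, "./initialMarking/text")
    if (!inherits(tok, "xml_missing")) {
      im[xml2::xml_attr(pn, "id")] <- as.integer(xml2::xml_text(tok))
    }
  }
  tnodes <- xml2::xml_find_all(doc, ".//page/transition")
  transitions <- data.frame(
    id = xml2::xml_attr(tnodes, "id"),
    label = vapply(tnodes, function(tn) {
      nm <- xml2::xml_find_first(tn, "./name/text")
      if (inherits(nm, "xml_missing")) NA_character_ else xml2::xml_text(nm)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  anodes <- xml2::xml_find_all(doc, ".//page/arc")
  arcs <- data.frame(from = xml2::xml_attr(anodes, "source"),
                     to = xml2::xml_attr(anodes, "target"),
                     stringsAsFactors = FALSE)
  fm <- integer(0)
  for (pl in xml2::xml_find_all(doc, ".//finalmarkings/marking/place")) {
    fm[xml2::xml_attr(pl, "idref")] <-
      as.integer(xml2::xml_text(xml2::xml_find_first(pl, "./text")))
  }
  if (length(fm) == 0) {
    # fall back: sink places (no outgoing arcs) carry one token
    sinks <- setdiff(places, arcs$from)
    fm <- stats::setNames(rep(1L, length(sinks)), sinks)
  }
  petri_net(places, transitions, arcs, im, fm)
}

#' Render a Petri net as DOT
#'
#' @param net A [petri_net()].
#' @return A character scalar with Graphviz DOT source.
#' @export
petri_dot <- function(net) {
  lines <- c("digraph petri {", "  rankdir=LR;")
  for (p in net$places) {
    lines <- c(lines, sprintf("  \"%s\" [shape=circle,label=\"\"];", p))
  }
  for (i in seq_len(nrow(net$transitions))) {
    lab <- net$transitions$label[i]
    style <- if (is.na(lab)) ",style=filled,fillcolor=black,label=\"\""
             else sprintf(",label=\"%s\"", lab)
    lines <- c(lines, sprintf("  \"%s\" [shape=box%s];",
                              net$transitions$id[i], style))
  }
  for (i in seq_len(nrow(net$arcs))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                              net$arcs$from[i], net$arcs$to[i]))
  }
  paste(c(lines, "}"), collapse = "\n")
}
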