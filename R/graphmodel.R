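#' Construct a typed directed graph
#'
#' The common substrate both graph-similarity instruments operate on. Nodes
#' carry a type — `PLACE`, `TRANSITION` and `EVENT` for graphs derived from
#' Petri nets; `EVENT`, `AND_SPLIT`, `AND_JOIN`, `XOR_SPLIT`, `XOR_JOIN` and
#' `LOOP` for graphs derived from operator models — and only `EVENT` nodes
#' carry an activity label. Edges are directed and, for operator-model
#' graphs, weighted with replay frequencies.
#'
#' Node ids are opaque: the similarity layer never looks at them, only at
#' types and labels.
#'
#' @param nodes Data frame with columns `id`, `type`, `label` (`NA` except
#'   for `EVENT` nodes).
#' @param edges Data frame with columns `from`, `to` and, when `weighted`,
#'   `weight` (positive).
#' @param weighted Logical flag.
#' @return A `typed_graph` object.
#' @export
typed_graph <- function(nodes, edges, weighted = FALSE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  node_types <- c("PLACE", "TRANSITION", "EVENT", "AND_SPLIT", "AND_JOIN",
                  "XOR_SPLIT", "XOR_JOIN", "LOOP")
  nodes$id <- as.character(nodes$id)
  nodes$type <- as.character(nodes$type)
  if (!"label" %in% names(nodes)) nodes$label <- NA_character_
  nodes$label <- as.character(nodes$label)
  if (!all(nodes$type %in% node_types)) {
    stop("unknown node type(s): ",
         paste(setdiff(nodes$type, node_types), collapse = ", "))
  }
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  ev <- nodes$type == "EVENT"
  if (any(ev & (is.na(nodes$label) | nodes$label == ""))) {
    stop("EVENT nodes must carry a non-empty activity label")
  }
  if (any(!ev & !is.na(nodes$label))) {
    stop("only EVENT nodes may carry a label")
  }
  if (nrow(edges) > 0) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!all(c(edges$from, edges$to) %in% nodes$id)) {
      stop("edges must reference existing node ids")
    }
  }
  if (weighted) {
    if (nrow(edges) > 0 &&
        (is.null(edges$weight) || any(is.na(edges$weight)) ||
         any(edges$weight <= 0))) {
      stop("a weighted graph needs a positive weight on every edge")
    }
  } else if (is.null(edges$weight)) {
    edges$weight <- rep(NA_real_, nrow(edges))
  }
  structure(list(nodes = nodes[, c("id", "type", "label")],
                 edges = edges[, c("from", "to", "weight")],
                 weighted = isTRUE(weighted)),
            class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  cat(sprintf("Typed %s graph: %d nodes, %d edges\n",
              if (x$weighted) "weighted" else "unweighted",
              nrow(x$nodes), nrow(x$edges)))
  tab <- table(x$nodes$type)
  cat("node types:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of nodes / edges of a typed graph
#' @param g A [typed_graph()].
#' @return Integer.
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Convert a Petri net into an unweighted typed graph
#'
#' One `PLACE` node per place, one `EVENT` node (labeled with the activity)
#' per labeled transition, one `TRANSITION` node per silent transition; every
#' arc becomes one directed edge. Node and edge counts therefore equal the
#' net's place/transition/arc counts exactly.
#'
#' @param net A [petri_net()].
#' @return An unweighted [typed_graph()].
#' @export
petri_to_graph <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  silent <- is.na(net$transitions$label)
  nodes <- data.frame(
    id = c(net$places, net$transitions$id),
    type = c(rep("PLACE", length(net$places)),
             ifelse(silent, "TRANSITION", "EVENT")),
    label = c(rep(NA_character_, length(net$places)),
              net$transitions$label),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = net$arcs$from, to = net$arcs$to,
                      stringsAsFactors = FALSE)
  typed_graph(nodes, edges, weighted = FALSE)
}

#' Convert a frequency-annotated process tree into a weighted typed graph
#'
#' The operator-model graph: each activity leaf becomes an `EVENT` node; an
#' exclusive or parallel operator becomes a split node before its branches
#' and a join node after them; a loop becomes a single `LOOP` node whose back
#' edge closes the cycle. Sequences introduce no operator nodes — consecutive
#' steps are wired directly. Silent branches (skips) become a direct
#' split-to-join edge. Every edge carries the annotated traversal frequency,
#' so flow is conserved at every split and join.
#'
#' @param tree A [process_tree] annotated by [annotate_frequencies()].
#' @return A weighted [typed_graph()].
#' @export
ivm_to_graph <- function(tree) {
  stopifnot(inherits(tree, "process_tree"))
  if (!is_annotated(tree)) {
    stop("tree is not frequency-annotated; run annotate_frequencies() first")
  }
  env <- new.env()
  env$nodes <- list()
  env$edges <- list()
  env$n <- 0L
  new_node <- function(type, label = NA_character_) {
    env$n <- env$n + 1L
    id <- sprintf("n%d", env$n)
    env$nodes[[env$n]] <- data.frame(id = id, type = type, label = label,
                                     stringsAsFactors = FALSE)
    id
  }
  edge <- function(from, to, w) {
    if (w > 0) {
      env$edges[[length(env$edges) + 1]] <-
        data.frame(from = from, to = to, weight = w,
                   stringsAsFactors = FALSE)
    }
  }

  # each construct reports its entry and exit node; NULL = silent passthrough
  build <- function(nd) {
    switch(nd$kind,
      leaf = {
        id <- new_node("EVENT", nd$label)
        list(entry = id, exit = id)
      },
      tau = NULL,
      seq = {
        parts <- Filter(Negate(is.null), lapply(nd$children, build))
        if (length(parts) == 0) return(NULL)
        if (length(parts) > 1) {
          for (i in seq_len(length(parts) - 1)) {
            edge(parts[[i]]$exit, parts[[i + 1]]$entry, nd$freq)
          }
        }
        list(entry = parts[[1]]$entry, exit = parts[[length(parts)]]$exit)
      },
      xor = {
        split <- new_node("XOR_SPLIT"); join <- new_node("XOR_JOIN")
        for (ch in nd$children) {
          part <- build(ch)
          if (is.null(part)) {
            edge(split, join, ch$freq)
          } else {
            edge(split, part$entry, ch$freq)
            edge(part$exit, join, ch$freq)
          }
        }
        list(entry = split, exit = join)
      },
      and = {
        split <- new_node("AND_SPLIT"); join <- new_node("AND_JOIN")
        for (ch in nd$children) {
          part <- build(ch)
          if (is.null(part)) {
            edge(split, join, ch$freq)
          } else {
            edge(split, part$entry, ch$freq)
            edge(part$exit, join, ch$freq)
          }
        }
        list(entry = split, exit = join)
      },
      loop = {
        lnode <- new_node("LOOP")
        entries <- nd$freq
        redo_freq <- sum(vapply(nd$children[-1], `[[`, numeric(1), "freq"))
        body <- build(nd$children[[1]])
        if (is.null(body)) {
          # silent do-part: the loop node itself is the junction
          for (ch in nd$children[-1]) {
            part <- build(ch)
            if (is.null(part)) next
            edge(lnode, part$entry, ch$freq)
            edge(part$exit, lnode, ch$freq)
          }
          list(entry = lnode, exit = lnode)
        } else {
          edge(lnode, body$entry, entries + redo_freq)
          for (ch in nd$children[-1]) {
            part <- build(ch)
            if (is.null(part)) {
              edge(body$exit, lnode, ch$freq)   # back edge closes the cycle
            } else {
              edge(body$exit, part$entry, ch$freq)
              edge(part$exit, lnode, ch$freq)
            }
          }
          list(entry = lnode, exit = body$exit)
        }
      }
    )
  }
  build(tree)
  nodes <- do.call(rbind, env$nodes)
  edges <- if (length(env$edges) > 0) do.call(rbind, env$edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  typed_graph(nodes, edges, weighted = TRUE)
}

#' Convert a typed graph to an igraph object
#'
#' Types and labels become vertex attributes, weights edge attributes; used
#' for the feature-vector statistics and for GraphML export.
#'
#' @param g A [typed_graph()].
#' @return An `igraph` graph.
#' @export
graph_to_igraph <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")],
    directed = TRUE,
    vertices = g$nodes[, c("id", "type", "label")]
  )
  if (g$weighted && nrow(g$edges) > 0) {
    igraph::E(ig)$weight <- g$edges$weight
  }
  ig
}

#' Export a typed graph to GraphML
#'
#' @param g A [typed_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  ig <- graph_to_igraph(g)
  # graphml chokes on NA character attributes
  lab <- igraph::V(ig)$label
  igraph::V(ig)$label <- ifelse(is.na(lab), "", lab)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Render a typed graph as DOT
#'
#' @param g A [typed_graph()].
#' @return A character scalar with Graphviz DOT source.
#' @export
graph_dot <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  shape <- c(PLACE = "circle", TRANSITION = "box", EVENT = "box",
             AND_SPLIT = "diamond", AND_JOIN = "diamond",
             XOR_SPLIT = "diamond", XOR_JOIN = "diamond", LOOP = "ellipse")
  lines <- "digraph typed {"
  for (i in seq_len(nrow(g$nodes))) {
    lab <- if (g$nodes$type[i] == "EVENT") g$nodes$label[i] else
      g$nodes$type[i]
    lines <- c(lines, sprintf("  \"%s\" [shape=%s,label=\"%s\"];",
                              g$nodes$id[i], shape[[g$nodes$type[i]]], lab))
  }
  for (i in seq_len(nrow(g$edges))) {
    w <- if (g$weighted) sprintf(" [label=\"%g\"]", g$edges$weight[i]) else ""
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;",
                              g$edges$from[i], g$edges$to[i], w))
  }
  paste(c(lines, "}"), collapse = "\n")
}
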