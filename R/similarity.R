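#' Type-aware node matching
#'
#' Two nodes match — i.e., substituting one for the other during graph
#' comparison is free — iff they have the same type, and, for event nodes,
#' additionally represent the same activity. Node identifiers never influence
#' the result.
#'
#' @param a,b Nodes: lists (or one-row data frames) with elements `type` and
#'   `label`.
#' @return Logical.
#' @examples
#' node_match(list(type = "EVENT", label = "Radiology"),
#'            list(type = "EVENT", label = "Radiology"))  # TRUE
#' node_match(list(type = "EVENT", label = "Radiology"),
#'            list(type = "EVENT", label = "Surgery"))    # FALSE
#' node_match(list(type = "XOR_SPLIT", label = NA),
#'            list(type = "XOR_SPLIT", label = NA))       # TRUE
#' @export
node_match <- function(a, b) {
  if (a$type != b$type) return(FALSE)
  if (a$type != "EVENT") return(TRUE)
  identical(as.character(a$label), as.character(b$label))
}

node_classes <- function(g1, g2) {
  # integer match classes: equal class <=> node_match holds
  key <- function(g) ifelse(g$nodes$type == "EVENT",
                            paste0("EVENT\r", g$nodes$label),
                            g$nodes$type)
  k1 <- key(g1); k2 <- key(g2)
  lev <- unique(c(k1, k2))
  list(cls1 = match(k1, lev) - 1L, cls2 = match(k2, lev) - 1L,
       ncls = length(lev))
}

adj_matrix <- function(g) {
  n <- nrow(g$nodes)
  m <- matrix(0L, n, n)
  if (nrow(g$edges) > 0) {
    m[cbind(match(g$edges$from, g$nodes$id),
            match(g$edges$to, g$nodes$id))] <- 1L
  }
  m
}

#' Typed graph edit distance
#'
#' Minimum number of unit-cost edit operations (node and edge insertions,
#' deletions and substitutions; substitution free only under [node_match()])
#' transforming one typed graph into the other. Edge weights are ignored.
#' The computation is NP-hard, so a branch-and-bound search with an anytime
#' budget is used: the reported distance is the minimum found within the
#' budget, an upper bound on the true distance that never increases with a
#' larger budget, and is exact when `converged` is `TRUE`. Both operand
#' orders are searched and the smaller result reported, which also makes the
#' approximation symmetric.
#'
#' @param g1,g2 [typed_graph()] objects from the same family (both
#'   Petri-derived or both operator-derived).
#' @param budget Time budget in seconds (total across both search orders).
#' @return A `ged_result`: list with `distance` (non-negative integer),
#'   `converged`, `elapsed` (seconds) and `budget`.
#' @examples
#' ga1 <- typed_graph(
#'   data.frame(id = c("s", "e", "j"),
#'              type = c("XOR_SPLIT", "EVENT", "XOR_JOIN"),
#'              label = c(NA, "Radiology", NA)),
#'   data.frame(from = c("s", "e"), to = c("e", "j")))
#' ga2 <- typed_graph(
#'   data.frame(id = c("x9", "x3", "x7"),
#'              type = c("XOR_SPLIT", "EVENT", "XOR_JOIN"),
#'              label = c(NA, "Radiology", NA)),
#'   data.frame(from = c("x9", "x3"), to = c("x3", "x7")))
#' ged(ga1, ga2)$distance  # 0: ids do not matter
#' @export
ged <- function(g1, g2, budget = 60) {
  stopifnot(inherits(g1, "typed_graph"), inherits(g2, "typed_graph"))
  if (budget <= 0) stop("budget must be positive")
  t0 <- Sys.time()
  cls <- node_classes(g1, g2)
  a1 <- adj_matrix(g1); a2 <- adj_matrix(g2)
  r1 <- .ged_bnb(a1, a2, cls$cls1, cls$cls2, cls$ncls, budget / 2)
  if (r1$converged) {
    # exact: no need to search the swapped order
    res <- r1
  } else {
    r2 <- .ged_bnb(a2, a1, cls$cls2, cls$cls1, cls$ncls, budget / 2)
    res <- list(distance = min(r1$distance, r2$distance),
                converged = r1$converged || r2$converged)
  }
  structure(list(distance = as.integer(round(res$distance)),
                 converged = isTRUE(res$converged),
                 elapsed = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")),
                 budget = budget),
            class = "ged_result")
}

#' @export
print.ged_result <- function(x, ...) {
  cat(sprintf("GED = %d (%s, %.2fs of %gs budget)\n", x$distance,
              if (x$converged) "exact" else "anytime upper bound",
              x$elapsed, x$budget))
  invisible(x)
}

#' Global feature vector of a typed graph
#'
#' For weighted (operator-model) graphs the components, in order, are: number
#' of nodes, number of edges, average degree, average weighted degree,
#' average clustering coefficient, average shortest path, average closeness,
#' and average betweenness centrality. For unweighted (Petri-net-derived)
#' graphs the weighted degree (identical to the degree) and the clustering
#' coefficient (identically zero on such bipartite-like graphs) are omitted,
#' giving six components.
#'
#' Conventions (fixed, since the named statistics admit variants): degree is
#' in plus out; weighted degree sums in- and out-edge weights; clustering is
#' the mean local clustering coefficient of the undirected projection with
#' isolated and degree-one nodes contributing zero; the average shortest path
#' is over ordered reachable pairs only (the graphs need not be strongly
#' connected); closeness of a node is computed from incoming geodesics with
#' the reachable-fraction normalization, and betweenness is directed,
#' normalized by `(n-1)(n-2)`. Path-based components of a single-node graph
#' are zero.
#'
#' @param g A [typed_graph()].
#' @return A named numeric vector of class `feature_vector` (length 8 when
#'   weighted, 6 when unweighted).
#' @export
feature_vector <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  n <- nrow(g$nodes)
  if (n == 0) stop("feature vector of an empty graph is undefined")
  ig <- graph_to_igraph(g)
  avg_degree <- mean(igraph::degree(ig, mode = "all"))

  d <- igraph::distances(ig, mode = "out", weights = NA)
  finite <- is.finite(d) & row(d) != col(d)
  avg_sp <- if (any(finite)) mean(d[finite]) else 0

  # closeness from incoming geodesics, reachable-fraction normalized
  closeness_i <- vapply(seq_len(n), function(i) {
    din <- d[, i]
    reach <- is.finite(din) & seq_len(n) != i
    r <- sum(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(din[reach]))
  }, numeric(1))
  avg_closeness <- mean(closeness_i)

  avg_betweenness <- if (n > 2) {
    mean(igraph::betweenness(ig, directed = TRUE, weights = NA)) /
      ((n - 1) * (n - 2))
  } else 0

  if (g$weighted) {
    avg_wdegree <- mean(igraph::strength(ig, mode = "all"))
    und <- igraph::as_undirected(igraph::simplify(ig), mode = "collapse")
    cc <- igraph::transitivity(und, type = "local", isolates = "zero")
    avg_clustering <- if (length(cc) == 0) 0 else mean(cc)
    out <- c(n_nodes = n, n_edges = nrow(g$edges), avg_degree = avg_degree,
             avg_weighted_degree = avg_wdegree,
             avg_clustering = avg_clustering, avg_shortest_path = avg_sp,
             avg_closeness = avg_closeness,
             avg_betweenness = avg_betweenness)
  } else {
    out <- c(n_nodes = n, n_edges = nrow(g$edges), avg_degree = avg_degree,
             avg_shortest_path = avg_sp, avg_closeness = avg_closeness,
             avg_betweenness = avg_betweenness)
  }
  structure(out, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Feature-based graph similarity
#'
#' Both feature vectors are normalized to unit length; the similarity is one
#' minus their Euclidean distance. Identical (or proportional) vectors score
#' exactly 1; the theoretical minimum for non-negative features is
#' `1 - sqrt(2)` (about -0.414) — the score is deliberately not clamped at
#' zero.
#'
#' @param f1,f2 [feature_vector()]s of equal length (same graph family).
#' @return A similarity score `<= 1`.
#' @export
feature_similarity <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop("feature vectors of different families (lengths ", length(f1),
         " and ", length(f2), ") are not comparable")
  }
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0 || n2 == 0) stop("cannot normalize a zero feature vector")
  1 - sqrt(sum((f1 / n1 - f2 / n2)^2))
}
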