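# Shared fixtures and independent oracles for the test suite.

# Brute-force typed graph edit distance: enumerates every injective partial
# node mapping and scores it directly from the definition. Independent of the
# branch-and-bound implementation; only feasible for <= 5 nodes.
brute_ged <- function(g1, g2) {
  n1 <- nrow(g1$nodes); n2 <- nrow(g2$nodes)
  key <- function(g) {
    ifelse(g$nodes$type == "EVENT", paste0("E:", g$nodes$label),
           g$nodes$type)
  }
  k1 <- key(g1); k2 <- key(g2)
  adj <- function(g, n) {
    m <- matrix(0L, n, n)
    if (nrow(g$edges)) {
      m[cbind(match(g$edges$from, g$nodes$id),
              match(g$edges$to, g$nodes$id))] <- 1L
    }
    m
  }
  A1 <- adj(g1, n1); A2 <- adj(g2, n2)
  if (n1 == 0) return(n2 + sum(A2))
  best <- Inf
  rec <- function(i, assign) {
    if (i > n1) {
      used <- assign[assign > 0]
      cost <- sum(assign == 0) + (n2 - length(used))
      for (a in seq_len(n1)) {
        if (assign[a] > 0 && k1[a] != k2[assign[a]]) cost <- cost + 1
      }
      for (a in seq_len(n1)) for (b in seq_len(n1)) {
        if (A1[a, b] == 1 &&
            !(assign[a] > 0 && assign[b] > 0 &&
              A2[assign[a], assign[b]] == 1)) {
          cost <- cost + 1
        }
      }
      pre <- integer(n2); pre[assign[assign > 0]] <- which(assign > 0)
      for (u in seq_len(n2)) for (v in seq_len(n2)) {
        if (A2[u, v] == 1 &&
            !(pre[u] > 0 && pre[v] > 0 && A1[pre[u], pre[v]] == 1)) {
          cost <- cost + 1
        }
      }
      best <<- min(best, cost)
      return(invisible(NULL))
    }
    for (v in c(0, setdiff(seq_len(n2), assign[seq_len(i - 1)]))) {
      assign[i] <- v
      rec(i + 1, assign)
    }
  }
  rec(1, integer(n1))
  best
}

# Random typed graph in one of the two graph families
rand_typed_graph <- function(n, family = c("ivm", "petri")) {
  family <- match.arg(family)
  types <- if (family == "ivm") {
    c("EVENT", "XOR_SPLIT", "XOR_JOIN", "AND_SPLIT", "AND_JOIN", "LOOP")
  } else {
    c("PLACE", "TRANSITION", "EVENT")
  }
  labels <- c("Radiology", "Surgery", "Pathology")
  ty <- sample(types, n, replace = TRUE)
  lab <- ifelse(ty == "EVENT", sample(labels, n, replace = TRUE),
                NA_character_)
  nodes <- data.frame(id = paste0("v", seq_len(n)), type = ty, label = lab,
                      stringsAsFactors = FALSE)
  poss <- expand.grid(from = nodes$id, to = nodes$id,
                      stringsAsFactors = FALSE)
  edges <- poss[sample(nrow(poss), sample(0:nrow(poss), 1)), , drop = FALSE]
  typed_graph(nodes, edges)
}

# Worked node-matching examples: three-node operator graphs (split ->
# event -> join) and five-node Petri-derived graphs, identical up to node
# ids, with one event-label substitution in the third of each family.
operator_example_graph <- function(ids, event_label) {
  typed_graph(
    data.frame(id = ids, type = c("XOR_SPLIT", "EVENT", "XOR_JOIN"),
               label = c(NA, event_label, NA), stringsAsFactors = FALSE),
    data.frame(from = ids[1:2], to = ids[2:3], stringsAsFactors = FALSE)
  )
}

petri_example_graph <- function(ids, event_label) {
  typed_graph(
    data.frame(id = ids,
               type = c("PLACE", "EVENT", "PLACE", "TRANSITION", "PLACE"),
               label = c(NA, event_label, NA, NA, NA),
               stringsAsFactors = FALSE),
    data.frame(from = ids[1:4], to = ids[2:5], stringsAsFactors = FALSE)
  )
}

# Rank-then-Pearson Spearman oracle, written from the definition
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

set_key <- function(lang) {
  sort(vapply(lang, paste, character(1), collapse = "|"))
}
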