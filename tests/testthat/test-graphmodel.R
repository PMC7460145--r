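test_that("petri_to_graph maps places, transitions and events bijectively", {
  net <- tree_to_petri(pt_seq("A", "B"))
  g <- petri_to_graph(net)
  expect_equal(n_nodes(g), length(net$places) + nrow(net$transitions))
  expect_equal(n_edges(g), nrow(net$arcs))
  expect_equal(sum(g$nodes$type == "PLACE"), 3)
  expect_equal(sum(g$nodes$type == "EVENT"), 2)
  expect_setequal(g$nodes$label[g$nodes$type == "EVENT"], c("A", "B"))
  expect_false(g$weighted)

  # silent transitions become unlabeled TRANSITION nodes
  net2 <- tree_to_petri(pt_and("A", "B"))
  g2 <- petri_to_graph(net2)
  expect_equal(sum(g2$nodes$type == "TRANSITION"), 2)  # fork and join
  expect_true(all(is.na(g2$nodes$label[g2$nodes$type == "TRANSITION"])))
})

test_that("ivm_to_graph renders operators, weights and loop cycles", {
  # plain sequence: events wired directly, no operator nodes
  slog <- log_from_traces(rep(list(c("A", "B")), 10))
  sg <- ivm_to_graph(annotate_frequencies(pt_seq("A", "B"), slog))
  expect_equal(sort(sg$nodes$type), c("EVENT", "EVENT"))
  expect_equal(sg$edges$weight, 10)
  expect_true(sg$weighted)

  # exclusive choice: split/join with conserved branch weights
  xlog <- log_from_traces(c(rep(list("A"), 7), rep(list("B"), 3)))
  xg <- ivm_to_graph(annotate_frequencies(pt_xor("A", "B"), xlog))
  expect_setequal(xg$nodes$type,
                  c("XOR_SPLIT", "XOR_JOIN", "EVENT"))
  split_id <- xg$nodes$id[xg$nodes$type == "XOR_SPLIT"]
  join_id <- xg$nodes$id[xg$nodes$type == "XOR_JOIN"]
  expect_setequal(xg$edges$weight[xg$edges$from == split_id], c(7, 3))
  expect_equal(sum(xg$edges$weight[xg$edges$from == split_id]), 10)
  expect_equal(sum(xg$edges$weight[xg$edges$to == join_id]), 10)

  # loop: single LOOP node, graph cyclic; loop-free graph acyclic
  llog <- log_from_traces(list(c("A"), c("A", "B", "A"),
                               c("A", "B", "A", "B", "A")))
  lg <- ivm_to_graph(annotate_frequencies(pt_loop("A", "B", cont = 0.3),
                                          llog))
  expect_equal(sum(lg$nodes$type == "LOOP"), 1)
  ig <- graph_to_igraph(lg)
  expect_false(igraph::is_dag(ig))
  expect_true(igraph::is_dag(graph_to_igraph(sg)))

  # unannotated tree is refused
  expect_error(ivm_to_graph(pt_seq("A", "B")), "annotate_frequencies")
})

test_that("weight flow is conserved at every split and join node", {
  log <- sample_log(generator_spec(preset_tree("icu"), n_cases = 150,
                                   seed = 7, name = "icu"))
  tree <- discover_tree(log)
  g <- ivm_to_graph(annotate_frequencies(tree, log))
  for (i in seq_len(nrow(g$nodes))) {
    ty <- g$nodes$type[i]
    if (!ty %in% c("AND_SPLIT", "AND_JOIN", "XOR_SPLIT", "XOR_JOIN")) next
    id <- g$nodes$id[i]
    w_in <- sum(g$edges$weight[g$edges$to == id])
    w_out <- sum(g$edges$weight[g$edges$from == id])
    if (w_in > 0 && w_out > 0) expect_equal(w_in, w_out, info = ty)
  }
})

test_that("conversions are deterministic up to node ids", {
  log <- sample_log(generator_spec(preset_tree("breast"), n_cases = 60,
                                   seed = 9, name = "b"))
  g1 <- ivm_to_graph(annotate_frequencies(discover_tree(log), log))
  g2 <- ivm_to_graph(annotate_frequencies(discover_tree(log), log))
  expect_equal(g1$nodes, g2$nodes)
  expect_equal(g1$edges, g2$edges)
  # renaming node ids leaves the similarity layer unchanged
  ren <- g2
  map <- stats::setNames(paste0("z", seq_len(nrow(ren$nodes))),
                         ren$nodes$id)
  ren$nodes$id <- unname(map[ren$nodes$id])
  ren$edges$from <- unname(map[ren$edges$from])
  ren$edges$to <- unname(map[ren$edges$to])
  expect_equal(ged(g1, ren, budget = 10)$distance, 0)
  expect_equal(feature_vector(ren), feature_vector(g1))
})

test_that("typed graph validity rules hold", {
  nodes <- data.frame(id = c("a", "b"), type = c("EVENT", "XOR_SPLIT"),
                      label = c("A", NA))
  edges <- data.frame(from = "a", to = "b")
  expect_silent(typed_graph(nodes, edges))
  bad <- nodes; bad$label <- c(NA, NA)
  expect_error(typed_graph(bad, edges), "EVENT nodes")
  bad2 <- nodes; bad2$label <- c("A", "oops")
  expect_error(typed_graph(bad2, edges), "only EVENT")
  expect_error(typed_graph(nodes, data.frame(from = "a", to = "zz")),
               "existing node ids")
  expect_error(typed_graph(nodes, edges, weighted = TRUE), "weight")
})

test_that("graphml and dot exports carry types, labels and weights", {
  log <- log_from_traces(c(rep(list("A"), 7), rep(list("B"), 3)))
  g <- ivm_to_graph(annotate_frequencies(pt_xor("A", "B"), log))
  f <- tempfile(fileext = ".graphml")
  write_graphml(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(back)$type, c("XOR_SPLIT", "EVENT", "XOR_JOIN"))
  expect_setequal(igraph::E(back)$weight, c(7, 3))
  dot <- graph_dot(g)
  expect_match(dot, "digraph")
  expect_match(dot, "label=\"A\"")
})
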