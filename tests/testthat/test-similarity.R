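test_that("node matching is type-aware and id-blind", {
  ev <- function(lab) list(type = "EVENT", label = lab)
  expect_true(node_match(ev("Radiology"), ev("Radiology")))
  expect_false(node_match(ev("Radiology"), ev("Surgery")))
  expect_true(node_match(list(type = "XOR_SPLIT", label = NA),
                         list(type = "XOR_SPLIT", label = NA)))
  expect_false(node_match(list(type = "XOR_SPLIT", label = NA),
                          list(type = "AND_SPLIT", label = NA)))
  expect_false(node_match(list(type = "PLACE", label = NA),
                          list(type = "TRANSITION", label = NA)))
  # reflexive and symmetric on random nodes
  set.seed(1)
  for (i in 1:20) {
    g <- rand_typed_graph(2, sample(c("ivm", "petri"), 1))
    a <- as.list(g$nodes[1, ]); b <- as.list(g$nodes[2, ])
    expect_true(node_match(a, a))
    expect_equal(node_match(a, b), node_match(b, a))
  }
})

test_that("ged reproduces the worked node-matching examples", {
  ga1 <- operator_example_graph(c("1", "2", "3"), "Radiology")
  ga2 <- operator_example_graph(c("9", "4", "7"), "Radiology")
  ga3 <- operator_example_graph(c("5", "6", "8"), "Surgery")
  expect_equal(ged(ga1, ga2, budget = 5)$distance, 0)
  expect_equal(ged(ga2, ga3, budget = 5)$distance, 1)

  gb1 <- petri_example_graph(paste0("a", 1:5), "Radiology")
  gb2 <- petri_example_graph(paste0("b", 1:5), "Radiology")
  gb3 <- petri_example_graph(paste0("c", 1:5), "Surgery")
  expect_equal(ged(gb1, gb2, budget = 5)$distance, 0)
  expect_equal(ged(gb2, gb3, budget = 5)$distance, 1)
})

test_that("ged equals brute force on random small graphs and is metric-like", {
  set.seed(2024)
  for (i in 1:25) {
    fam <- sample(c("ivm", "petri"), 1)
    g1 <- rand_typed_graph(sample(2:5, 1), fam)
    g2 <- rand_typed_graph(sample(2:5, 1), fam)
    r12 <- ged(g1, g2, budget = 10)
    expect_true(r12$converged)
    expect_equal(r12$distance, brute_ged(g1, g2))
    # symmetry and identity
    expect_equal(ged(g2, g1, budget = 10)$distance, r12$distance)
    expect_equal(ged(g1, g1, budget = 10)$distance, 0)
  }
})

test_that("ged handles empty graphs by pure insertion", {
  g <- operator_example_graph(c("1", "2", "3"), "Radiology")
  e <- typed_graph(data.frame(id = character(0), type = character(0),
                              label = character(0)),
                   data.frame(from = character(0), to = character(0)))
  expect_equal(ged(e, g, budget = 5)$distance, n_nodes(g) + n_edges(g))
  expect_equal(ged(g, e, budget = 5)$distance, n_nodes(g) + n_edges(g))
})

test_that("feature vectors follow the documented conventions", {
  # directed path A -> B -> C
  g <- typed_graph(
    data.frame(id = c("a", "b", "c"), type = "EVENT",
               label = c("A", "B", "C")),
    data.frame(from = c("a", "b"), to = c("b", "c"))
  )
  fv <- feature_vector(g)
  expect_named(fv, c("n_nodes", "n_edges", "avg_degree",
                     "avg_shortest_path", "avg_closeness",
                     "avg_betweenness"))
  expect_equal(unname(fv["n_nodes"]), 3)
  expect_equal(unname(fv["n_edges"]), 2)
  expect_equal(unname(fv["avg_degree"]), 4 / 3)
  # ordered reachable pairs: (a,b)=1, (a,c)=2, (b,c)=1
  expect_equal(unname(fv["avg_shortest_path"]), 4 / 3)

  # weighted family has 8 components including weighted degree/clustering
  log <- log_from_traces(c(rep(list("A"), 7), rep(list("B"), 3)))
  wg <- ivm_to_graph(annotate_frequencies(pt_xor("A", "B"), log))
  wfv <- feature_vector(wg)
  expect_length(wfv, 8)
  expect_true(all(is.finite(wfv)) && all(wfv >= 0))

  # single node: path and centrality components are zero
  g1 <- typed_graph(data.frame(id = "a", type = "EVENT", label = "A"),
                    data.frame(from = character(0), to = character(0)))
  fv1 <- feature_vector(g1)
  expect_equal(unname(fv1[c("avg_shortest_path", "avg_closeness",
                            "avg_betweenness")]), c(0, 0, 0))
})

test_that("feature similarity is scale-invariant, symmetric and bounded", {
  f1 <- c(3, 4, 0, 1); f2 <- c(6, 8, 0, 2); f3 <- c(1, 0, 0, 0)
  f4 <- c(0, 1, 0, 0)
  expect_equal(feature_similarity(f1, f1), 1)
  expect_equal(feature_similarity(f1, f2), 1)  # proportional vectors
  expect_equal(feature_similarity(f3, f4), 1 - sqrt(2))
  expect_equal(feature_similarity(f1, f3), feature_similarity(f3, f1))
  expect_error(feature_similarity(f1, c(1, 2)), "not comparable")
  expect_error(feature_similarity(f1, c(0, 0, 0, 0)), "zero")
  set.seed(5)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    s <- feature_similarity(a, b)
    expect_lte(s, 1 + 1e-12)
    expect_gte(s, 1 - sqrt(2) - 1e-12)
    expect_equal(feature_similarity(a, 3.7 * b), s)
  }
})

test_that("ged budget behaves as an anytime bound", {
  # large enough graphs that a tiny budget cannot finish the search
  set.seed(99)
  g1 <- rand_typed_graph(14, "ivm")
  g2 <- rand_typed_graph(14, "ivm")
  quick <- ged(g1, g2, budget = 0.05)
  slow <- ged(g1, g2, budget = 5)
  expect_lte(slow$distance, quick$distance)
  expect_error(ged(g1, g2, budget = 0), "positive")
})
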