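test_that("basic cuts are recovered from clean logs", {
  seq_log <- log_from_traces(rep(list(c("A", "B")), 10))
  expect_equal(format(discover_tree(seq_log)), "SEQ(A,B)")

  and_log <- log_from_traces(c(rep(list(c("A", "B")), 5),
                               rep(list(c("B", "A")), 5)))
  expect_equal(format(discover_tree(and_log)), "AND(A,B)")

  xor_log <- log_from_traces(c(rep(list("A"), 5), rep(list("B"), 5)))
  expect_equal(format(discover_tree(xor_log)), "XOR(A,B)")

  empty <- split_population(
    log_from_traces(list(p = "A"), case_attrs = list(p = list(age = 1))),
    attr_filter("age", ">", 99))
  expect_error(discover_tree(empty), "empty")
})

test_that("discovered models replay their own log perfectly at threshold 1", {
  trees <- list(
    preset_tree("breast"),
    preset_tree("icu"),
    pt_seq("A", pt_loop("B", "C", cont = 0.4), pt_xor("D", pt_tau()))
  )
  for (k in seq_along(trees)) {
    log <- sample_log(generator_spec(trees[[k]], n_cases = 80,
                                     seed = 100 + k, name = "pop"))
    net <- tree_to_petri(discover_tree(log, noise_threshold = 1))
    rep <- token_replay(log, net)
    expect_equal(fitness(rep), 1)
    expect_true(all(rep$per_variant$reached_final))
  }
})

test_that("noise filtering prunes rare directly-follows edges", {
  # 95 straight A,B,C plus 5 rare A,C skips: at 90% filtering the A->C
  # edge (freq 5 < 0.1 * 95) is dropped and the model stays a sequence
  log <- log_from_traces(c(rep(list(c("A", "B", "C")), 95),
                           rep(list(c("A", "C")), 5)))
  noisy <- discover_tree(log, noise_threshold = 0.9)
  expect_equal(format(noisy), "SEQ(A,B,C)")
  # unfiltered discovery must keep the skip behaviour replayable
  full <- tree_to_petri(discover_tree(log, noise_threshold = 1))
  expect_false(is.null(replay_trace_exact(full, c("A", "C"))))
})

test_that("flower fallback accepts arbitrary orderings", {
  # no seq/xor/and/loop cut: all four orderings of two activities plus
  # repetitions force the fallback
  log <- log_from_traces(list(c("A", "B", "A"), c("B", "A", "B"),
                              c("A", "A"), c("B", "B")))
  tree <- discover_tree(log)
  net <- tree_to_petri(tree)
  for (t in traces(log)) {
    expect_false(is.null(replay_trace_exact(net, t)))
  }
  expect_false(is.null(replay_trace_exact(net, c("B", "B", "A", "A", "B"))))
})

test_that("directly-follows counts are exact", {
  log <- log_from_traces(list(c("A", "B", "A", "B"), c("A", "B")))
  dfg <- directly_follows(log)
  ab <- dfg$edges$n[dfg$edges$from == "A" & dfg$edges$to == "B"]
  ba <- dfg$edges$n[dfg$edges$from == "B" & dfg$edges$to == "A"]
  expect_equal(ab, 3L)
  expect_equal(ba, 1L)
  expect_equal(unname(dfg$starts["A"]), 2L)
  expect_equal(unname(dfg$ends["B"]), 2L)
})

test_that("tree_to_petri builds the documented shapes and languages", {
  leaf_net <- tree_to_petri(pt_leaf("A"))
  expect_length(leaf_net$places, 2)
  expect_equal(nrow(leaf_net$transitions), 1)
  expect_equal(leaf_net$transitions$label, "A")

  seq_net <- tree_to_petri(pt_seq("A", "B"))
  expect_length(seq_net$places, 3)
  expect_equal(sum(!is.na(seq_net$transitions$label)), 2)
  expect_equal(nrow(seq_net$arcs), 4)
  rep <- token_replay(log_from_traces(list(c("A", "B"))), seq_net)
  expect_equal(unname(rep$totals["missing"]), 0)
  expect_equal(unname(rep$totals["remaining"]), 0)

  and_net <- tree_to_petri(pt_and("A", "B"))
  for (t in list(c("A", "B"), c("B", "A"))) {
    expect_equal(fitness(token_replay(log_from_traces(list(t)), and_net)), 1)
  }
})

test_that("tree_to_petri preserves the language on small trees", {
  trees <- list(
    pt_seq("A", pt_and("B", pt_xor("C", pt_tau())), "D"),
    pt_xor(pt_seq("A", "B"), pt_seq("B", "A")),
    pt_loop("A", "B", cont = 0.4),
    pt_seq(pt_xor("A", "B"), pt_loop("C", cont = 0.3))
  )
  for (tree in trees) {
    # every tree trace replays on the net
    for (t in tree_language(tree, max_loop = 2)) {
      expect_false(is.null(replay_trace_exact(tree_to_petri(tree), t)),
                   info = paste(format(tree), "->", paste(t, collapse = ",")))
    }
    # every bounded net trace is a tree trace (loops unrolled generously)
    net_lang <- petri_language(tree_to_petri(tree), max_len = 6)
    tree_lang <- tree_language(tree, max_loop = 5)
    expect_true(all(set_key(net_lang) %in% set_key(tree_lang)),
                info = format(tree))
  }
})

test_that("frequency annotation conserves flow and tallies deviations", {
  tree <- pt_seq("A", "B")
  log <- log_from_traces(rep(list(c("A", "B")), 10))
  ann <- annotate_frequencies(tree, log)
  expect_equal(ann$freq, 10)
  expect_equal(vapply(ann$children, `[[`, numeric(1), "freq"), c(10, 10))

  xtree <- pt_xor("A", "B")
  xlog <- log_from_traces(c(rep(list("A"), 7), rep(list("B"), 3)))
  xann <- annotate_frequencies(xtree, xlog)
  expect_equal(xann$freq, 10)
  expect_equal(vapply(xann$children, `[[`, numeric(1), "freq"), c(7, 3))

  # one deviating trace of 10: tallied, excluded from the counts
  dlog <- log_from_traces(c(rep(list(c("A", "B")), 9), list(c("B", "A"))))
  dann <- annotate_frequencies(tree, dlog)
  expect_equal(attr(dann, "deviations"), 1L)
  expect_equal(dann$freq, 9)
})

test_that("pnml round trip preserves the net and its markings", {
  net <- tree_to_petri(pt_seq("A", pt_and("B", pt_xor("C", pt_tau()))))
  f <- tempfile(fileext = ".pnml")
  write_pnml(net, f)
  back <- read_pnml(f)
  expect_setequal(back$places, net$places)
  expect_equal(back$transitions[order(back$transitions$id),
                                c("id", "label")],
               net$transitions[order(net$transitions$id),
                               c("id", "label")],
               ignore_attr = TRUE)
  expect_equal(nrow(back$arcs), nrow(net$arcs))
  expect_equal(back$im, net$im)
  expect_equal(back$fm, net$fm)
  # the reread net still replays the tree's traces
  expect_false(is.null(replay_trace_exact(back, c("A", "B", "C"))))
})
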