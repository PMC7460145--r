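test_that("sample_log realizes its generator spec deterministically", {
  spec <- generator_spec(pt_seq("A", "B"), n_cases = 100, seed = 5,
                         name = "p")
  log <- sample_log(spec)
  expect_equal(n_cases(log), 100)
  expect_true(all(vapply(traces(log), identical, logical(1), c("A", "B"))))
  # strictly increasing timestamps within each trace
  by_case <- split(log$events$timestamp, log$events$case_id)
  expect_true(all(vapply(by_case, function(ts) all(diff(ts) > 0),
                         logical(1))))
  # same seed -> byte-identical XES
  f1 <- tempfile(fileext = ".xes"); f2 <- tempfile(fileext = ".xes")
  write_log(sample_log(spec), f1, "xes")
  write_log(sample_log(spec), f2, "xes")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("xor branch frequencies follow their probabilities", {
  spec <- generator_spec(pt_xor("A", "B", probs = c(0.5, 0.5)),
                         n_cases = 1000, seed = 8, name = "p")
  n_a <- sum(vapply(traces(sample_log(spec)), identical, logical(1), "A"))
  sigma <- sqrt(1000 * 0.25)
  expect_lt(abs(n_a - 500), 3 * sigma)
})

test_that("noise-free samples always replay on the generating tree", {
  for (tree in list(preset_tree("breast"), preset_tree("icu"))) {
    net <- tree_to_petri(tree)
    log <- sample_log(generator_spec(tree, n_cases = 60, seed = 17,
                                     name = "p"))
    tv <- trace_variants(log)
    for (v in tv$variants) {
      expect_false(is.null(replay_trace_exact(net, v)),
                   info = paste(v, collapse = ","))
    }
    expect_equal(fitness(token_replay(log, net)), 1)
  }
})

test_that("deviation injection edits the promised share of traces", {
  spec <- generator_spec(pt_seq("A", "B", "C"), n_cases = 500, seed = 4,
                         name = "p")
  clean <- sample_log(spec)
  expect_identical(traces(inject_deviations(clean, 0, seed = 1)),
                   traces(clean))

  forced <- inject_deviations(log_from_traces(rep(list(c("A", "B")), 20)),
                              rate = 1, kinds = "swap", seed = 2)
  expect_true(all(vapply(traces(forced), identical, logical(1),
                         c("B", "A"))))

  dev <- inject_deviations(clean, 0.2, seed = 3)
  n_dev <- length(attr(dev, "deviated_cases"))
  expect_lt(abs(n_dev - 100), 3 * sqrt(500 * 0.2 * 0.8))

  # skip on a length-1 trace falls back to insert
  short <- inject_deviations(log_from_traces(list(p = "A")), rate = 1,
                             kinds = "skip", seed = 6)
  expect_length(traces(short)$p, 2)
})

test_that("make_populations realizes overlap targets constructively", {
  sp <- list(
    a = generator_spec(pt_seq("A", "B"), n_cases = 100, seed = 1,
                       name = "a"),
    b = generator_spec(pt_seq("A", "C"), n_cases = 100, seed = 2,
                       name = "b"),
    c = generator_spec(pt_seq("B", "C"), n_cases = 100, seed = 3,
                       name = "c")
  )
  pops <- make_populations(sp, data.frame(
    pop1 = c("a", "a"), pop2 = c("b", "c"), jaccard = c(0.5, 0.2)))
  expect_lt(abs(jaccard_overlap(pops$a, pops$b) - 0.5), 0.02)
  expect_lt(abs(jaccard_overlap(pops$a, pops$c) - 0.2), 0.02)
  # shared cases carry identical traces in both populations
  shared <- intersect(case_ids(pops$a), case_ids(pops$b))
  expect_gt(length(shared), 0)
  expect_identical(traces(pops$a)[shared], traces(pops$b)[shared])

  # disjoint by default; duplicated spec gives jaccard 1
  disjoint <- make_populations(sp[1:2])
  expect_equal(jaccard_overlap(disjoint$a, disjoint$b), 0)
  twice <- make_populations(list(x = sp$a, y = sp$a),
                            data.frame(pop1 = "x", pop2 = "y",
                                       jaccard = 1))
  expect_equal(jaccard_overlap(twice$x, twice$y), 1)

  # infeasible targets are rejected before sampling
  expect_error(
    make_populations(sp, data.frame(pop1 = c("a", "a", "b"),
                                    pop2 = c("b", "c", "c"),
                                    jaccard = c(0.9, 0.9, 0.9))),
    "infeasible")
})

test_that("generator specs validate their probabilities", {
  expect_error(pt_xor("A", "B", probs = c(0.6, 0.6)), "sum to 1")
  expect_error(pt_loop("A", cont = 1), "\\[0, 1\\)")
  expect_error(generator_spec(pt_seq("A"), deviation_rate = 1.5), "rate")
})
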