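#' Process-tree constructors
#'
#' A process tree is the operator representation of a discovered model: an
#' ordered tree whose internal nodes are control-flow operators and whose
#' leaves are activities (or the silent step `tau`). Operators:
#'
#' * `pt_seq(...)` — children execute left to right;
#' * `pt_xor(...)` — exactly one child executes; an optional `probs` vector
#'   (summing to 1) gives branch probabilities for simulation;
#' * `pt_and(...)` — all children execute, interleaved in any order;
#' * `pt_loop(do, ...)` — the do-part executes, then with probability `cont`
#'   one redo-part executes and the do-part repeats; a loop always has the
#'   do-part first and at least one redo-part (a silent `pt_tau()` is added
#'   when none is given).
#'
#' Character arguments are promoted to `pt_leaf()` for convenience, so
#' `pt_seq("A", "B")` is `pt_seq(pt_leaf("A"), pt_leaf("B"))`.
#'
#' @param label Activity label for a leaf.
#' @param ... Child subtrees (or activity labels).
#' @param probs For `pt_xor`: branch probabilities, one per child, summing
#'   to 1. Defaults to uniform.
#' @param cont For `pt_loop`: redo (continuation) probability in \[0, 1)
#'   used by the synthetic-log sampler. Must be < 1 so traces terminate.
#' @return A `process_tree` object.
#' @examples
#' pt_seq("radiology", pt_xor("pathology", pt_tau()), "surgery")
#' @name process_tree
NULL

pt_node <- function(kind, children = list(), label = NA_character_,
                    probs = NULL, cont = NULL) {
  children <- lapply(children, function(ch) {
    if (is.character(ch)) pt_leaf(ch) else ch
  })
  if (!all(vapply(children, inherits, logical(1), "process_tree"))) {
    stop("children must be process trees or activity labels")
  }
  structure(list(kind = kind, children = children, label = label,
                 probs = probs, cont = cont, freq = NULL),
            class = "process_tree")
}

#' @rdname process_tree
#' @export
pt_leaf <- function(label) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  pt_node("leaf", label = label)
}

#' @rdname process_tree
#' @export
pt_tau <- function() pt_node("tau")

#' @rdname process_tree
#' @export
pt_seq <- function(...) {
  ch <- list(...)
  if (length(ch) < 1) stop("seq needs at least one child")
  pt_node("seq", ch)
}

#' @rdname process_tree
#' @export
pt_xor <- function(..., probs = NULL) {
  ch <- list(...)
  if (length(ch) < 1) stop("xor needs at least one child")
  if (!is.null(probs)) {
    if (length(probs) != length(ch)) stop("one probability per branch")
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
      stop("xor branch probabilities must be non-negative and sum to 1")
    }
  }
  pt_node("xor", ch, probs = probs)
}

#' @rdname process_tree
#' @export
pt_and <- function(...) {
  ch <- list(...)
  if (length(ch) < 2) stop("and needs at least two children")
  pt_node("and", ch)
}

#' @rdname process_tree
#' @export
pt_loop <- function(do, ..., cont = 0.3) {
  redo <- list(...)
  if (length(redo) == 0) redo <- list(pt_tau())
  if (cont < 0 || cont >= 1) {
    stop("loop continuation probability must lie in [0, 1)")
  }
  pt_node("loop", c(list(do), redo), cont = cont)
}

#' @export
format.process_tree <- function(x, ...) {
  rec <- function(nd) {
    switch(nd$kind,
      leaf = nd$label,
      tau = "tau",
      paste0(toupper(nd$kind), "(",
             paste(vapply(nd$children, rec, character(1)), collapse = ","),
             ")")
    )
  }
  rec(x)
}

#' @export
print.process_tree <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Activities appearing in a process tree
#' @param tree A `process_tree`.
#' @return Sorted character vector of leaf labels.
#' @export
tree_activities <- function(tree) {
  stopifnot(inherits(tree, "process_tree"))
  rec <- function(nd) {
    if (nd$kind == "leaf") return(nd$label)
    if (nd$kind == "tau") return(character(0))
    unlist(lapply(nd$children, rec), use.names = FALSE)
  }
  sort(unique(rec(tree)))
}

interleave <- function(a, b) {
  # all order-preserving interleavings of two sequences
  if (length(a) == 0) return(list(b))
  if (length(b) == 0) return(list(a))
  c(lapply(interleave(a[-1], b), function(t) c(a[1], t)),
    lapply(interleave(a, b[-1]), function(t) c(b[1], t)))
}

#' Enumerate the language of a process tree
#'
#' Brute-force enumeration of all traces a tree can produce, with loops
#' unrolled up to `max_loop` redo executions. Only practical for small trees;
#' intended for verifying that a Petri-net conversion preserves the modeled
#' behaviour.
#'
#' @param tree A `process_tree`.
#' @param max_loop Maximum number of redo executions unrolled per loop.
#' @return List of unique character vectors (a zero-length vector is the
#'   empty trace).
#' @export
tree_language <- function(tree, max_loop = 2) {
  stopifnot(inherits(tree, "process_tree"))
  rec <- function(nd) {
    switch(nd$kind,
      leaf = list(nd$label),
      tau = list(character(0)),
      xor = unlist(lapply(nd$children, rec), recursive = FALSE),
      seq = Reduce(function(acc, ch) {
        nxt <- rec(ch)
        unlist(lapply(acc, function(a) lapply(nxt, function(b) c(a, b))),
               recursive = FALSE)
      }, nd$children, list(character(0))),
      and = Reduce(function(acc, ch) {
        nxt <- rec(ch)
        out <- list()
        for (a in acc) for (b in nxt) out <- c(out, interleave(a, b))
        out
      }, nd$children, list(character(0))),
      loop = {
        do_l <- rec(nd$children[[1]])
        redo_l <- unlist(lapply(nd$children[-1], rec), recursive = FALSE)
        acc <- do_l
        out <- acc
        if (max_loop > 0) {
          for (k in seq_len(max_loop)) {
            acc <- unlist(lapply(acc, function(a) {
              unlist(lapply(redo_l, function(r) {
                lapply(do_l, function(d) c(a, r, d))
              }), recursive = FALSE)
            }), recursive = FALSE)
            out <- c(out, acc)
          }
        }
        out
      }
    )
  }
  lang <- rec(tree)
  lang[!duplicated(vapply(lang, paste, character(1), collapse = "\r"))]
}
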