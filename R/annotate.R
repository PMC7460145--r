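#' Annotate a process tree with replay frequencies
#'
#' Replays every trace of the log on the tree (via its Petri-net form, whose
#' transitions are tagged with the tree node they implement) and records, on
#' each tree node, how often control traversed it. Traces the model cannot
#' replay are deviations: they are tallied and excluded from the counts, so
#' the annotated frequencies conserve flow exactly (the counts of an
#' exclusive choice's branches sum to the count of the choice itself).
#'
#' @param tree A [process_tree].
#' @param log An [event_log()].
#' @return The tree with a `freq` field on every node, plus attributes
#'   `deviations` (number of non-replaying traces), `n_traces` (number of
#'   replayed traces) and `annotated = TRUE`.
#' @examples
#' tree <- pt_xor("A", "B")
#' log <- log_from_traces(c(rep(list("A"), 7), rep(list("B"), 3)))
#' ann <- annotate_frequencies(tree, log)
#' ann$freq               # 10
#' ann$children[[1]]$freq # 7
#' @export
annotate_frequencies <- function(tree, log) {
  stopifnot(inherits(tree, "process_tree"), inherits(log, "event_log"))
  net <- tree_to_petri(tree)
  tv <- trace_variants(log)
  fires <- stats::setNames(numeric(nrow(net$transitions)),
                           net$transitions$id)
  deviations <- 0L
  fitted <- 0L
  for (i in seq_along(tv$variants)) {
    seq_ <- replay_trace_exact(net, tv$variants[[i]])
    if (is.null(seq_)) {
      deviations <- deviations + tv$counts[i]
    } else {
      fitted <- fitted + tv$counts[i]
      tab <- table(seq_)
      fires[names(tab)] <- fires[names(tab)] + as.integer(tab) * tv$counts[i]
    }
  }
  by_node <- stats::setNames(fires, net$transitions$node)
  count_of <- function(path) {
    hit <- names(by_node) == path
    if (!any(hit)) 0 else sum(by_node[hit])
  }
  assign_freq <- function(nd, path) {
    nd$children <- lapply(seq_along(nd$children), function(i) {
      assign_freq(nd$children[[i]], paste0(path, ".", i))
    })
    nd$freq <- switch(nd$kind,
      leaf = count_of(path),
      tau = count_of(path),
      seq = nd$children[[1]]$freq,
      xor = sum(vapply(nd$children, `[[`, numeric(1), "freq")),
      and = count_of(paste0(path, ".fork")),
      loop = count_of(paste0(path, ".enter"))
    )
    nd
  }
  out <- assign_freq(tree, "r")
  attr(out, "annotated") <- TRUE
  attr(out, "deviations") <- deviations
  attr(out, "n_traces") <- fitted
  out
}

#' Is a process tree frequency-annotated?
#' @param tree A [process_tree].
#' @return Logical.
#' @export
is_annotated <- function(tree) {
  isTRUE(attr(tree, "annotated")) && !is.null(tree$freq)
}
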