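#' Spearman rank correlation with a t-approximated p-value
#'
#' The rank-correlation coefficient used to validate similarity measures
#' against human visual judgment: the Pearson correlation of the two
#' sequences' ranks, with ties receiving average ranks. The two-sided p-value
#' uses the t-approximation with `n - 2` degrees of freedom (an exact
#' permutation p-value is available behind `exact = TRUE`, feasible for the
#' small n typical of comparison tables).
#'
#' @param x,y Numeric sequences of equal length, at least 3.
#' @param exact Compute the p-value by full permutation enumeration instead
#'   of the t-approximation (only for `length(x) <= 8`).
#' @return A list of class `correlation_result` with `rho`, `p_value`, `n`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation is undefined for a constant sequence")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p-value only supported for n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p_value, n = n),
            class = "correlation_result")
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (p = %.4f, n = %d)", x$rho, x$p_value,
              x$n))
  if (!is.null(x$measure1)) {
    cat(sprintf("  [%s vs %s]", x$measure1, x$measure2))
  }
  cat("\n")
  invisible(x)
}

#' Compare two populations end to end
#'
#' The full pairwise comparison: discovers a model for each population,
#' converts both into typed graphs, and fills one comparison row with the
#' graph edit distance, the feature similarity, the four directional
#' cross-conformance values and their averages, plus externally supplied
#' visual-judgment scores (mean and sd of human ratings on a 0-4 Likert
#' scale, 0 = identical, 4 = extremely different). The human rating is an
#' input — it is never computed.
#'
#' @param logA,logB [event_log()]s of the two populations.
#' @param visual_mean,visual_sd Optional visual-judgment summary for the
#'   pair.
#' @param noise_threshold Discovery noise threshold.
#' @param ged_budget Time budget (seconds) for the graph edit distance.
#' @param graph_type `"ivm"` compares the weighted operator-model graphs,
#'   `"petri"` the unweighted Petri-net-derived graphs.
#' @return A one-row tibble (a comparison row) with columns `group1`,
#'   `group2`, `visual_mean`, `visual_sd`, `F12`, `P12`, `F21`, `P21`,
#'   `F_avg`, `P_avg`, `GED`, `FS`, `ged_converged`, `deviationsA`,
#'   `deviationsB`.
#' @export
compare_pair <- function(logA, logB, visual_mean = NA_real_,
                         visual_sd = NA_real_, noise_threshold = 1,
                         ged_budget = 60, graph_type = c("ivm", "petri")) {
  stopifnot(inherits(logA, "event_log"), inherits(logB, "event_log"))
  graph_type <- match.arg(graph_type)
  if (!is.na(visual_mean) && (visual_mean < 0 || visual_mean > 4)) {
    stop("visual_mean must lie on the 0-4 Likert scale")
  }
  treeA <- discover_tree(logA, noise_threshold)
  treeB <- discover_tree(logB, noise_threshold)
  netA <- tree_to_petri(treeA)
  netB <- tree_to_petri(treeB)
  annA <- annotate_frequencies(treeA, logA)
  annB <- annotate_frequencies(treeB, logB)
  if (graph_type == "ivm") {
    gA <- ivm_to_graph(annA)
    gB <- ivm_to_graph(annB)
  } else {
    gA <- petri_to_graph(netA)
    gB <- petri_to_graph(netB)
  }
  gres <- ged(gA, gB, budget = ged_budget)
  fs <- feature_similarity(feature_vector(gA), feature_vector(gB))
  cc <- cross_conformance(logA, logB, netA = netA, netB = netB)
  tibble::tibble(
    group1 = logA$name, group2 = logB$name,
    visual_mean = visual_mean, visual_sd = visual_sd,
    F12 = cc$F12, P12 = cc$P12, F21 = cc$F21, P21 = cc$P21,
    F_avg = cc$F_avg, P_avg = cc$P_avg,
    GED = gres$distance, FS = fs,
    ged_converged = gres$converged,
    deviationsA = attr(annA, "deviations"),
    deviationsB = attr(annB, "deviations")
  )
}

measure_column <- function(rows, measure) {
  col <- switch(measure, visual = "visual_mean", measure)
  if (!col %in% names(rows)) {
    stop("measure '", measure, "' not present in the comparison rows; ",
         "available: ", paste(names(rows), collapse = ", "))
  }
  v <- rows[[col]]
  if (anyNA(v)) {
    stop("measure '", measure, "' is missing for row(s) ",
         paste(which(is.na(v)), collapse = ", "))
  }
  v
}

#' Correlation matrix of similarity measures over comparison rows
#'
#' For every unordered pair of the named measures, the Spearman rank
#' correlation across the comparison rows. This is the analysis that asks
#' which automatic measure tracks human visual judgment.
#'
#' @param rows A data frame of comparison rows ([compare_pair()] output or a
#'   transcribed comparison table; `visual` refers to the `visual_mean`
#'   column).
#' @param measures Character vector of measure names.
#' @param exact Passed to [spearman_cor()].
#' @return A tibble with one row per measure pair: `measure1`, `measure2`,
#'   `rho`, `p_value`, `n`.
#' @examples
#' tab <- comparison_table("mimic")
#' correlation_matrix(tab, measures = c("visual", "F_avg", "FS"))
#' @export
correlation_matrix <- function(rows,
                               measures = c("visual", "F_avg", "P_avg",
                                            "GED", "FS"),
                               exact = FALSE) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) < 3) stop("at least 3 comparison rows are required")
  cols <- lapply(measures, measure_column, rows = rows)
  names(cols) <- measures
  out <- list()
  for (i in seq_along(measures)) {
    for (j in seq_along(measures)) {
      if (i >= j) next
      cr <- spearman_cor(cols[[i]], cols[[j]], exact = exact)
      out[[length(out) + 1]] <- tibble::tibble(
        measure1 = measures[i], measure2 = measures[j],
        rho = cr$rho, p_value = cr$p_value, n = cr$n)
    }
  }
  do.call(rbind, out)
}

#' Bundled reference comparison tables
#'
#' Two pairwise model-comparison tables shipped with the package, each with
#' six population pairs scored by all instruments: `"mimic"` compares
#' cancer-type cohorts from the MIMIC-III ICU database (Petri-net graphs),
#' `"zgt"` compares breast-cancer screening cohorts from a Dutch hospital
#' (operator-model graphs). Columns follow the comparison-row schema: human
#' visual rating (mean and sd on the 0-4 Likert scale), directional fitness
#' and precision, their averages, GED and FS. They are the standard input for
#' [correlation_matrix()].
#'
#' @param dataset `"mimic"` or `"zgt"`.
#' @return A tibble of comparison rows.
#' @export
comparison_table <- function(dataset = c("mimic", "zgt")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0("comparison_", dataset, ".csv"),
                      package = "pmcompare", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read comparison rows from a CSV file
#'
#' @param path CSV with the comparison-row columns (at least the measures to
#'   be correlated).
#' @return A tibble of comparison rows.
#' @export
read_comparison_rows <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
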