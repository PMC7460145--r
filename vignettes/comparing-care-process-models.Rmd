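---
title: "Comparing care-process models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing care-process models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcompare)
```

## The problem

Patient populations — screening versus referred patients, age bands,
diagnosis-code groups — leave different footprints in a hospital's event
log. Discovering a process model per population is routine; judging whether
two discovered models describe *similar care* is not. Humans can rate model
pairs on a Likert scale (0 identical … 4 extremely different), but that does
not scale to the dozens of population pairs a single study design produces.
`pmcompare` implements automatic instruments for the pairwise comparison —
two graph-based similarities and cross-log conformance — and the
rank-correlation analysis that asks which instrument tracks the human
judgment. This vignette records the models, parameter conventions, numerical
choices and limitations; the package reference documents the individual
functions.

## Event logs and populations

An event log is a set of traces, one per case (patient), each a
chronologically ordered sequence of timestamped activities. Ordering is by
timestamp, then by an optional non-negative `seq_index` that disambiguates
several events on the same calendar day (clinical systems often record only
dates plus a within-day sequence number), then by stable input order — the
last resort triggers a warning because it is only as meaningful as the
export order of the source system.

Case attributes (age, screening flag, diagnosis codes, severity scores)
attach to the case, not to events: one patient is one case. Attributes may
be set-valued, so a patient carrying two diagnosis codes genuinely belongs
to two code-defined populations; `split_population()` with `attr_filter()`
predicates (equality, comparison, membership, closed numeric range —
thresholds inclusive, so "age ≥ 50" keeps the 50-year-old) realizes exactly
this overlap, which `jaccard_overlap()` then quantifies as intersection over
union of the patient-id sets.

Logs are read and written as IEEE-1849-style XES (activity in
`concept:name`, timestamp in `time:timestamp`, case attributes on the
trace; repeated keys collect into set-valued attributes) and as RFC-4180
UTF-8 CSV with an explicit column map — no header sniffing, so the same
file parses identically everywhere. Traces end at their last recorded
event: clinical pathways rarely have a well-defined discharge event at this
granularity, so no artificial end event is synthesized.

## Discovery

`discover_tree()` is an inductive-miner-family algorithm: it recursively
partitions the directly-follows graph (DFG) of the log with cut detection
in the fixed order sequence → exclusive choice → parallel → loop, with
lexicographic tie-breaks, so discovery is a pure function of the log. When
no cut applies, the recursion falls back to a flower model — a loop over
the exclusive choice of the remaining activities — which explains any
ordering at the price of saying nothing. At `noise_threshold = 1` no
behaviour is filtered and every input trace replays on the result (the
classic inductive-miner guarantee, asserted in the test suite).

**Noise filtering.** Below threshold 1, a directly-follows edge survives
only if its frequency is at least `(1 − threshold)` times the strongest
outgoing connection *of the same activity*. Two refinements proved
necessary for this relative rule to behave:

* trace ends count as an edge to a virtual END node. A terminal activity
  has no legitimate outgoing edges, so without the END convention the
  strongest "outgoing edge" of, say, *surgery* is itself a noise edge and
  the filter never removes anything downstream of it — at 10% trace-level
  noise this reliably collapsed discovery to the flower fallback;
* rare trace starts (relative to the strongest start), rare empty
  projections and rare single-activity repeats are filtered at the same
  relative floor, mirroring how the edge filter treats rare connections.

The threshold semantics of interactive mining tools are not published
precisely, so these conventions are the package's own, fixed and
documented; discovered model shapes from other tools are not expected to be
reproduced bit-for-bit.

**Two representations.** `tree_to_petri()` compiles the operator tree
compositionally into a workflow net (single source and sink place; sequence
children share places, choices share entry/exit places, parallel children
get silent fork/join transitions, loops silent enter/exit transitions with
redo parts closing the cycle). The construction tags every transition with
the tree node it implements, which is what lets `annotate_frequencies()`
replay a log (exactly, via a search over silent firings) and attribute
traversal counts back to tree nodes — flow is conserved at every choice by
construction, and non-replaying traces are tallied as deviations rather
than distorting the counts. Language equality of tree and net is checked in
the tests by bounded brute-force enumeration on small trees.

## Typed graphs

Both representations convert to the common comparison substrate, a
directed typed graph. From a Petri net: one `PLACE` node per place, one
`EVENT` node (labeled) per labeled transition, one `TRANSITION` node per
silent transition, one edge per arc — counts match exactly, and the graph
is unweighted. From an annotated operator tree: leaves become labeled
`EVENT` nodes; choice and parallel operators become split and join nodes;
sequences introduce no operator nodes; a loop becomes a single `LOOP` node
whose back edge closes the cycle (the split/join pair encoding was
rejected as less parsimonious); silent branches become a direct
split-to-join edge; every edge carries the replayed frequency, conserved
at every split/join. Self-loop edges are retained in the data structure
even where a rendering might hide them. Node identifiers are opaque
throughout — the similarity layer is invariant to renaming, which the
tests assert.

## Graph edit distance

`ged()` computes the minimum number of unit-cost edit operations (node and
edge insertion, deletion, substitution) transforming one typed graph into
the other. Substituting a node is free exactly when `node_match()` holds:
same type, and for `EVENT` nodes the same activity label — never the node
id. An edge is preserved for free only when both endpoints map and the
direction agrees; edge weights are ignored (unit costs and weight-blind
matching are the only cost model consistent with the worked examples the
measure is validated against, and human raters are likewise instructed to
ignore edge numbers).

The computation is NP-hard, so the implementation (C++, branch-and-bound
over node assignments with an admissible class-count lower bound and
best-first child ordering) is *anytime*: within a time budget it reports
the best distance found, an upper bound that never increases with more
budget, exact when the search completed (`converged = TRUE`). Both operand
orders are searched and the minimum reported, making the approximation
symmetric. The default budget is 60 s; one hour mirrors the regime in
which the measure was validated on real cohort models. On every random
graph pair of ≤ 5 nodes the suite checks equality with an exhaustive
enumeration oracle.

## Feature similarity

`feature_vector()` summarizes a graph as (nodes, edges, mean degree, mean
weighted degree, mean clustering coefficient, mean shortest path, mean
closeness, mean betweenness); unweighted Petri-net graphs drop the weighted
degree (it equals the degree) and the clustering coefficient (identically
zero on such graphs), giving six components. The named statistics admit
variants, so the conventions are fixed here: degree is in+out; weighted
degree sums in- and out-weights; clustering is the mean local coefficient
of the undirected projection with isolates contributing zero; the mean
shortest path runs over ordered *reachable* pairs only (the graphs need not
be strongly connected); closeness uses incoming geodesics with the
reachable-fraction normalization; betweenness is directed, normalized by
`(n−1)(n−2)`; all path-based components of a single-node graph are zero.
A feature vector produced by another toolchain need not match
component-for-component (a reported mean degree can even disagree with
`2E/N` for the reported node and edge counts, depending on loop and
direction handling), so no attempt is made to match any particular
external vector — the conventions above are the contract.

`feature_similarity()` normalizes both vectors to unit length and returns
one minus their Euclidean distance: exactly 1 for proportional vectors,
bounded below by `1 − √2` for non-negative features, deliberately not
clamped at zero. In practice FS crowds the interval just below 1 even for
visibly different models — one of the findings the correlation analysis
makes quantitative.

## Cross-log conformance

`token_replay()` is standard token-based replay: fire the trace's
transitions from the initial marking; when the needed transition is
disabled, first search (breadth-first, depth-capped at 10, lexicographic
tie-breaks) for the shortest silent sequence that enables it, otherwise
insert the missing input tokens and count them; at the end consume the
final marking and count leftovers as remaining. Produced/consumed totals
include the initial and final marking. Activities absent from the model's
alphabet are log-only moves (one missing, one consumed token) — never a
crash. Fitness is `½(1 − Σm/Σc) + ½(1 − Σr/Σp)`, which is 1 iff nothing
was missing or remaining. Replay runs per trace variant and weights by
frequency, so logs with thousands of cases cost what their distinct
pathways cost.

`precision()` is escaping-edges precision: at every observed trace-prefix
state (weighted by visits), compare the activities the model enables
(through a silent-transition closure) with the activities observed next;
precision is one minus the weighted share of enabled-but-never-observed
activities. The model that allows exactly the log scores 1; a flower model
scores strictly lower on any non-trivial log while its fitness stays 1 —
the two measures are deliberately complementary.

`cross_conformance()` applies both in both directions (log 1 on model 2
and vice versa) and averages: the F12/P12/F21/P21/F̄/P̄ columns of a
comparison row. The alignment-based replay of interactive toolchains is a
different (and unspecified) variant, so absolute fitness/precision values
from such tools are not reproduction targets; the backend here is fully
specified, deterministic and desk-checkable, and the conformance stage is
a plain function boundary that an alignment engine could replace.

## Validation by rank correlation

`compare_pair()` assembles one comparison row per population pair; human
visual ratings (mean, sd) enter as data — the user study is never
simulated. `correlation_matrix()` computes Spearman's ρ (Pearson on
average ranks) for every unordered measure pair, with a two-sided p-value
from the t-approximation with n−2 degrees of freedom; with only a handful
of rows an exact permutation p-value is available (`exact = TRUE`), but
p-value methodology differs between tools, so only ρ values are treated as
reproducible quantities. The package ships two reference comparison tables
(`comparison_table("mimic")`, six ICU cancer-type cohort pairs;
`comparison_table("zgt")`, six breast-cancer cohort pairs) whose
correlation structure — FS and average fitness tracking visual judgment on
the former; average precision and GED on the latter — the acceptance tests
reproduce to two decimals. That the reproduction succeeds with average
ranks is itself evidence for the tie convention, which is why it is the
default.

## The synthetic generator

`generator_spec()` + `sample_log()` emulate the study setting without
hospital data: traces are random walks through a process tree (choice
branches by probability, parallel branches by uniformly random
interleaving, loops by geometric continuation with probability < 1 so
termination is almost sure), with strictly increasing timestamps
(exponential inter-event gaps, mean 3 days by default, rounded up to whole
seconds). Defaults follow the study conditions: 4–8 activity types (the
`preset_tree()` pathways: a 4-activity breast-cancer-like tree and an
8-activity ICU-procedure-like tree — labels only, no clinical claims),
hundreds of cases per population (default 300), deviation rate 0 unless
asked. `inject_deviations()` edits each trace with probability `rate` by
one uniformly chosen insert/skip/swap — the simplest operationalization of
"patients whose behaviour departs from the common pathway"; a skip on a
length-1 trace falls back to insert. `make_populations()` realizes pairwise
Jaccard targets constructively (shared cases are copied with identical ids
and traces), with feasibility checked before sampling; shared sets for
different pairs are kept disjoint, so the per-population share totals must
fit within its case count.

What the generator does *not* emulate: realistic clinical timing, resource
and cost annotations, attribute-correlated pathway differences, free-text
provenance, or the heavy-tailed variant distributions of real logs. Tests
passing on synthetic populations therefore demonstrate correctness of the
instruments under controlled conditions, not performance claims on real
hospital data.

## Problem sizes and test design

The suite verifies each instrument against an independent oracle at small
scale — exhaustive edit-path enumeration for GED (≤ 5 nodes, 50 random
pairs), bounded language enumeration for the tree/net equivalence,
rank-then-Pearson recomputation for Spearman (100 random tied/untied
sequences) — and the pipeline properties at moderate scale: populations of
150–400 cases, deviation rates up to 0.4 for the fitness-degradation
property, and the recovery property (populations from the same generator
beat populations from a structurally different one on GED, FS and F̄
simultaneously) over 10 seeds at 400 cases, 5% deviations and discovery
noise threshold 0.9. GED budgets in tests are 1–10 s, which the
branch-and-bound either exhausts (large random graphs, upper-bound
semantics asserted) or converges within (everything else).

## Known limitations

* Discovery is a deterministic baseline of the inductive-miner family; it
  has no fall-throughs between the four cuts and the flower model, and its
  noise filter, while documented, is one of several defensible readings of
  "90% noise filtering".
* Token-replay fitness and escaping-edges precision are not the
  alignment-based metrics of interactive process-mining suites; numbers
  are comparable within this package, not across tools.
* GED at realistic model sizes is an upper bound, not the exact distance;
  pairs of structurally identical large graphs can report small positive
  distances if the budget elapses before the zero-cost mapping is proven
  optimal (`converged` tells).
* FS compresses near 1 and is best read jointly with the other measures.
* Populations are attribute-defined; text-mining inclusion heuristics
  (e.g., keyword-based "new patient" rules) are out of scope.
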