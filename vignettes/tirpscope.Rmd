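---
title: "Mining and associatively exploring time-interval patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and associatively exploring time-interval patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirpscope)
```

## The model

tirpscope works with three layers of structure.

**Symbolic time intervals.** An STI is a triple `(symbol, start, end)`
with `start <= end`; time is abstract numeric, so months, days or seconds
are carried by the data, never by the code. Zero-duration STIs are legal
and represent instantaneous events (a fall, an administration): event-log
data needs them, and all relation predicates apply to them unchanged.
Within a transaction, STIs are kept in the lexicographic order
`(start, end, symbol)`. That ordering is load-bearing: because any pair
of STIs is always considered in this order, the seven non-inverse Allen
relations — before `b`, meets `m`, overlaps `o`, starts `s`, contains
`c`, finished-by `f`, equals `e` — are a complete, mutually exclusive
vocabulary for interval pairs, and the six inverse relations never
arise. `equals` completes the set: with both intervals orderable either
way, identical intervals fit none of the other six.

**Patterns.** A TIRP of size k is a symbol sequence plus the
upper-triangular matrix of pairwise relations, stored flat in column
order (`r(1,2), r(1,3), r(2,3), ...`) so that a child pattern's vector is
its parent's vector plus one appended column. An instance of a TIRP in a
transaction is a lexicographically ordered selection of STIs matching the
symbols positionally and the matrix exactly. Metrics follow two-level
averaging throughout: per supporting transaction first (HS = instance
count, MD = mean instance duration), then unweighted across supporting
transactions (MHS, MMD). An instance's duration is its latest STI end
minus its earliest STI start. "Latest end" rather than "the last STI's
end" is a deliberate choice: under `contains`, the lexicographically last
STI can end before an earlier one, and a duration should not shrink
because of tie-breaking in the sort order.

**The enumeration tree and its indices.** The tree's level k holds every
frequent size-k pattern; each child appends one STI to its parent, so a
pattern's prefix path is unique. The pair index inverts this structure:
for every node and every consecutive position pair `(i, i+1)` one entry
`(node, i, r(i, i+1))` goes into the forward bucket keyed
`(symbol_i, symbol_{i+1})` and the backward bucket keyed in reverse.
"One after the other" is read strictly as *consecutive positions*: the
exploration engine's panels only ever offer immediate neighbors of the
fixed sequence, and indexing non-adjacent pairs would inflate the buckets
without serving any query the engine issues. The two maps hold identical
entry sets; only the key order differs, which is what makes backward
queries as cheap as forward ones.

## Lookup semantics

A query fixes a sequence: symbols plus the *complete* relation
sub-matrix among them. A TIRP matches at position p when its symbols at
`p..p+m-1` equal the sequence's and its sub-matrix over those positions
equals the sequence's relations; matching is strict on relations by
default (a symbols-only mode exists behind `match_relations = FALSE`,
since two patterns over the same symbols with different relations are
different clinical statements). Forward extensions require a match with
at least one position after it; backward extensions one before. For a
single-symbol sequence the candidate set comes straight from the buckets
keyed by that symbol; for longer sequences candidates are drawn from the
rarest of the consecutive-pair buckets (filtered by the fixed relation)
and verified by the matcher. A TIRP matching at several positions yields
one row per (node, extending position). Rows are ordered by VS
descending, then symbol, then node id — the ordering is a display
convention, chosen once and kept deterministic so that row numbers are
stable across runs.

The session engine adds state: the fixed sequence, a center position,
and the selected node whose metrics the center block reports (size label
`X/Y` = center position within that node / node size). Selections extend
the sequence at a boundary and recompute the *opposite* panel; the
same-side panel is retained with the chosen row marked. After a shift,
a side that has a fixed neighbor collapses to that single marked row,
while a boundary side shows the extensions of the whole fixed sequence —
the two behaviors coexist because a selection narrows the view (the
user just committed to a row) whereas a shift re-centers it. Shifts
never alter the fixed sequence or the selected node. Undo pops the
previous state exactly, so undo-then-reselect is an identity.

The positional query (`positional_query()`) is the baseline this
design is measured against: filter patterns by first symbol, final
symbol, and/or an *interior* symbol (a strictly interior position,
2..k−1 — a size-2 pattern has no interior, so an intermediate-only query
over pairs returns nothing). Because "interior" may be anywhere inside,
the query over-returns relative to an immediate-neighbor exploration;
the test suite formalises this as a superset relation for backward rows
whose match ends the pattern.

## Mining

The miner is correctness-first and instance-driven. Level 1 keeps every
symbol supported by at least the threshold count. A size-k node is
extended by walking each supporting instance and each STI
lexicographically after the instance's last STI, reading the new
relation column off the actual intervals; candidates with any pair
beyond the maximal gap are discarded, the rest are grouped by
(symbol, relation column) and thresholded on distinct transactions.
Because relations are read off realised instances, every emitted child
is realisable by construction — there is no transitivity table to get
wrong — and every frequent pattern appears exactly once under its unique
prefix. The price is speed on large databases, which is out of scope;
the index and exploration layers, not the miner, are built to handle
trees with tens of thousands of nodes.

Tunable parameters, with defaults and rationale:

| parameter | meaning (units) | default | notes |
|---|---|---|---|
| `min_vs` | support threshold | — | `< 1` read as a fraction, converted once with ceiling; ties (count = threshold) are frequent |
| `max_gap` | maximal `before` gap (time units) | — | applies to *every* pair whose relation would be `b`, not only adjacent ones; a too-distant pair invalidates the whole instance |
| `epsilon` | endpoint equality tolerance (time units) | 0 | exact timestamps need none; measured timestamps may |
| `max_size` | cap on pattern size | `Inf` | used to bound desk-scale experiments |
| `keep_instances` | retain instance tables | `TRUE` | needed by timeline layouts; supporting ids are always kept for demographic breakdowns |

## Temporal abstraction

State abstraction assigns each sample a bin label from ascending cutoffs
(expert-given or equal-width via `ewd_cutoffs()`); bins are left-closed
with a right-closed top bin, so a value exactly on a cutoff takes the
label above it — some boundary rule must be fixed, and this one keeps
`findInterval()` semantics. Gradient abstraction labels each
consecutive-sample segment Increasing/Stable/Decreasing by comparing the
slope against a threshold `theta` (default 0: any nonzero slope is a
trend; experts override per variable). Segment semantics — labels attach
to inter-sample segments, not samples — were chosen because a derivative
is a property of an interval, not a point. Runs of identical labels merge
into one STI spanning the first to the last observed bound; a
`max_sample_gap` (default `Inf`) breaks runs across recording gaps,
which irregular event-logged data requires. Point-sample state runs keep
observed timestamps as endpoints (a singleton run is a zero-duration
STI); an `extend_to_next` mode holds each state until the next sample
instead, for data where observations are known to persist. The default
does not invent unobserved duration.

## Numerical and degenerate-input conventions

- Endpoint comparisons use a three-way comparator with tolerance
  `epsilon`; the relation decision tree checks start equality, then end
  equality, then the end-vs-start gap, which reproduces the ordered
  predicate semantics (equals before starts before finished-by before
  meets) for exact arithmetic. With `epsilon > 0` one corner becomes
  reachable that exact arithmetic forbids (starts tolerance-equal while
  the first interval ends later); it is mapped to `contains` as the
  nearest superset relation.
- An empty database mines to an empty tree; a threshold above the
  transaction count warns and returns an empty tree; metrics on an
  unsupported pattern are an error, not NaN.
- Writers are canonical (fixed key order, floats at 6 significant
  digits), so equal objects serialize byte-identically and round-trips
  are exact; readers validate and reject rather than coerce.
- All randomness (synthetic databases, random trees) is seedable and
  fully reproducible.

## The synthetic generator

`generate_sti_db()` emulates the structural features of the data this
kind of tool is used on: each of `n` transactions receives a concrete
template realisation with probability π, rigidly shifted in time, plus
Poisson background noise from a separate symbol pool. A rigid shift
preserves every pairwise relation exactly; per-STI jitter is deliberately
not offered because naive jitter flips knife-edge relations (meets,
starts) into neighbors and would silently change the planted ground
truth. Defaults — n = 200, π = 0.6, Poisson mean 3 noise STIs from a
pool of 8, a 3-STI before-chain template with gaps well inside a 20-unit
maximal gap — are the planted-recovery study conditions used by the test
suite and the acceptance script. With template and noise pools disjoint,
the planted pattern's support equals the planted transaction count, so
recovery and binomial fluctuation bounds are checkable exactly.

What the generator does **not** emulate: realistic symbol co-occurrence,
autocorrelated measurement series, per-variable sampling cadences, or
the distributional quirks of real clinical data. Passing tests therefore
demonstrate algorithmic correctness (the miner finds exactly what is
there; the index returns exactly what a full scan returns), not
robustness to real-data messiness.

`random_tirp_tree()` serves a different purpose: structurally valid but
semantically arbitrary trees (random symbols, random relation columns,
anti-monotone synthetic support) for fuzzing the index and lookup code
at sizes the miner need not reach.

## Problem sizes used by the test suite

The suite checks the miner against an exhaustive subset-enumeration
oracle on 50 seeded databases of 5 transactions with up to 10 STIs each
over a 5-symbol alphabet (size capped at 4 for both sides), and the
indexed lookups against full-tree scans over 100 seeded random trees of
30–200 nodes (alphabet up to 20, sizes up to 6), for every size-1..3
consecutive window occurring in them. Planted-pattern recovery runs 20
seeds at n = 200, π = 0.6, mining at a 40% support threshold. Index-size
conformance is checked on trees of 100, 1,000 and 10,000 nodes. These
sizes were chosen as the smallest at which the properties are
non-trivial while keeping the whole suite comfortably interactive.

## Known limitations

- The miner enumerates instances exhaustively; combinatorial databases
  (many equal symbols overlapping in one transaction) make HS — and the
  miner — expensive. This is inherent to exact HS counting.
- Disjunctive or coarser relation sets, closed/maximal pattern mining,
  and population-comparison views are out of scope.
- The exploration engine exposes immediate neighbors only; reaching a
  pattern whose extra STIs are all non-adjacent to the fixed sequence
  requires the positional query.
- The timeline layout averages instance offsets; overlapping relations
  are reported numerically and drawn to the averaged scale, which can
  visually understate rare long instances.
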