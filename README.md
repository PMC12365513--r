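# tirpscope

Associative exploration of frequent time-interval patterns mined from
clinical (or any other multivariate) temporal data.

## The problem

Temporal abstraction turns raw time-point series — lab values, activity
logs, event records — into **symbolic time intervals** (STIs): triples
`(symbol, start, end)` such as `Glucose.High` from month 3 to month 7, or
a zero-duration `Fall.Event`. A **time-interval-related pattern** (TIRP)
is a lexicographically ordered sequence of k STI symbols together with
the conjunction of Allen temporal relations among every pair, stored as
an upper-triangular matrix (the non-inverse half of Allen's relations
suffices: before `b`, meets `m`, overlaps `o`, starts `s`, contains `c`,
finished-by `f`, equals `e`). Mining a database of transactions (one STI
series per patient or resident) yields an **enumeration tree**: level k
holds every frequent size-k TIRP, each child extending its parent by one
later STI. Each pattern P carries

- **VS** — vertical support, the number of transactions in which P occurs
  at least once (relative VS divides by the database size);
- **HS / MHS** — horizontal support, the instance count of P inside one
  transaction, and its mean over supporting transactions;
- **MD / MMD** — the per-transaction mean of instance durations (latest
  STI end minus earliest STI start), and its mean over supporting
  transactions.

Such trees routinely hold thousands of patterns, and the tree shape only
supports root-to-leaf browsing: a pattern that contains your sequence of
interest *with additional STIs beforehand* lives in a different branch
entirely. tirpscope builds **bidirectional pair indices** over the tree —
two nested maps keyed by ordered symbol pairs, listing every TIRP in
which the pair occurs at consecutive positions, with the relation between
them — and uses them to answer, in either time direction: *given this
fixed sequence of STIs, which patterns extend it earlier or later, and
with what metrics?* Index construction is a single pass over the nodes
(work proportional to the total pair count, at most N·(Lmax−1)); bucket
space is bounded by the squared alphabet size times N.

On top of the index sits a session engine mirroring how an analyst
explores: focus an STI, inspect the earlier/later panels, select a row
(which fixes a longer sequence), shift the center along the fixed
sequence, undo. Panels carry, per row, the extending symbol, the relation
R between the center STI and the extending STI, and the TIRP's metrics
with a size label `X/Y` (`Y` the TIRP's size, `X` the extending STI's
position). The package also computes plot-ready summaries (mean-
presentation timelines, bubble-chart points, demographic breakdowns), a
positional first/intermediate/last pattern query for comparison, CSV/JSON
readers and writers, a correctness-first miner, temporal abstraction
(equal-width or expert cutoffs; gradient abstraction), and a
planted-pattern synthetic data generator — so the whole pipeline is
testable without access to private clinical data.

## Worked example

`toy_falls_tree()` ships an 18-node demonstration tree over five
care-home symbols (100 notional transactions):

```r
library(tirpscope)
tree <- toy_falls_tree()
idx  <- build_tirp_index(tree)

session <- start_session(tree, idx, "Fall.Event")
glance(session)
#>   center_symbol selected_node    vs relative_vs   mhs   mmd size_label
#> 1 Fall.Event    P1               90         0.9   1.5     0 1/1
```

The center block shows P1, the size-1 pattern of the focus STI, present
in 90% of transactions. The earlier panel lists every pattern that
extends the focus backward in time:

```r
session$panels$earlier
#>   symbol              relation node  size_label    vs   mhs   mmd
#> 1 Fluids.Low          b        P7    1/2           55   1.4     6
#> 2 Happiness.Decreased o        P9    1/2           45   1.2     8
#> 3 Fluids.Low          b        P16   2/3           30   1.2    10
#> ...
#> 9 Happiness.Decreased o        P17   1/4           15   1.0    16
```

Row P17 reads: in the 4-sized pattern P17, `Happiness.Decreased` is the
first STI (size label 1/4) and **o**verlaps the fall event. Selecting
`Happiness.Decreased` as a *later* STI via P13 fixes the sequence
`<Fall.Event, Happiness.Decreased>`:

```r
session <- select_extension(session, "later", which(session$panels$later$node == "P13"))
glance(session)
#>   center_symbol selected_node    vs relative_vs   mhs   mmd size_label
#> 1 Fall.Event    P13              22        0.22   1.1    10 2/3

session$panels$earlier
#>   symbol     relation node  size_label
#> 1 Fluids.Low b        P13   1/3
```

The center STI is now the 2nd of P13's 3 STIs (`2/3`), and exactly one
pattern precedes the fixed pair — P13 itself, contributing the earlier
`Fluids.Low`. `shift_forward()` then moves the center onto
`Happiness.Decreased` without changing the fixed sequence; its later
panel is empty because no frequent pattern continues the pair.

The same operations run from the shell via the thin CLI:

```sh
Rscript exec/tirpscope simulate --n 200 --pi 0.6 --seed 7 --out db.csv
Rscript exec/tirpscope mine --sti-db db.csv --min-vs 0.4 --max-gap 20 --out tree.json
Rscript exec/tirpscope query --tree tree.json --seq "Glucose.High,Exercise.Low" --rels b --direction forward
```

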