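---
title: "Models and methods behind shattersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shattersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shattersim)
```

# The question

Chromothripsis — the hypothesized one-step shattering and random reassembly
of a chromosome — is operationally detected through a *footprint*: a
chromosome with many breakpoints (50 or more) dominated by at most two or
three copy-number states.  The footprint argument rests on simulations of
the alternative, *progressive* rearrangement: if step-by-step accumulation
of inversions, deletions and tandem duplications cannot produce the
pattern, observing it supports a one-off catastrophe.  shattersim
implements that simulation, the multiple possible definitions of
"breakpoint count" and "copy-number state count" on which the argument
turns, and a reconstruction algorithm that produces an explicit progressive
event series explaining any observed breakpoint set.  Together these let a
user probe how much the footprint criteria actually discriminate.

# The segmented-chromosome model

A chromosome of length $L$ bases is partitioned at breakpoint coordinates
$p_1 < \dots < p_{n-1}$ into $n$ segments; segment $i$ spans
$(p_{i-1}, p_i]$ with $p_0$ the chromosome start and $p_n = L$.  Each
segment end carries a label: the *head* is the 5′ (lower-coordinate) end,
labelled $p_{i-1}$ (position 1 for segment 1), and the *tail* the 3′ end,
labelled $p_i$.  With this labelling a junction's two
(position, terminus) labels are exactly what a breakpoint table reports.
Segment lengths sum to $L$ (segment 1 includes its first base).

A derivative chromosome is an ordered sequence of signed segment copies.
Three operators act on copy-index spans:

* **inversion** — reverse the span and flip orientations.  The copy-number
  profile is *exactly* preserved; this invariant is enforced by tests over
  randomized arrangements, since a subtle indexing fault here is known to
  make some inversions behave like duplications and silently inflate state
  counts.
* **deletion** — remove the span;
* **tandem duplication** — insert a verbatim copy of the span right after
  it.

# Counting conventions

*Breakpoints.* `adjacency` counts every abnormal junction along the
derivative with multiplicity; `pes` counts distinct junctions (a duplicated
junction sequences as one); `microarray` counts changes of value in the
collapsed copy-number profile.  The three disagree on real inputs: the
worked example in the README scores 8 / 7 / 6.  `pes` can never exceed
`adjacency`; `microarray` is ordered against neither.

*Copy states.* `strict` counts distinct copy-number values.  `relaxed`
counts the minimal number of states whose combined reference coverage
reaches a fraction of $L$ (default 0.95; the small worked example uses
0.90).  Zero-copy regions contribute their reference length — deletion is a
state of the reference coordinate system, and without this convention the
documented example (4 states covering 90 of 100 bases) is not reproducible.
Ties between equally covering states cannot change the count, only which
states are picked, so no tie-break rule is needed.

# The progressive simulator

Starting from the intact chromosome, observed breakpoints are drawn one at
a time *without replacement*, with probability proportional to a
per-operation-class weight (uniform by default; `c(2, 1, 1)` makes
inversion-class breakpoints twice as likely per draw, renormalized over the
remaining pool).  The drawn breakpoint's realizations on the *current*
arrangement are enumerated exactly — a junction $\{A, B\}$ can be created
by a deletion joining flanks, a tandem duplication joining span end to span
start, or an inversion at either edge of the inverted span (which then also
creates a by-product junction).  One realization is applied (uniformly at
random by default; `nearest`/`furthest` span strategies are available
because worked derivations sometimes pick the furthest candidate copy), and
the configured breakpoint and state counts are recorded.  Breakpoints with
no realization are discarded and reported, which guarantees termination.
Counts are always recomputed from the arrangement, never incremented, so
later events destroying earlier junctions are handled correctly, and
realized-then-destroyed breakpoints are reported explicitly.

The event loop is implemented in C++ (via Rcpp) and draws from R's RNG, so
a seed makes whole sweeps reproducible.  `simulate_free` runs the same loop
without an observed set — events with uniformly random valid spans — which
is how one demonstrates that inversions and deletions alone can write
hundreds of breakpoints while the profile never leaves states $\{0, 1\}$.

`sweep_replicates` aggregates running snapshots across replicates into
breakpoint-count bins (median state count and the central 99% interval per
bin).  Running counts are used so one replicate populates many bins;
`endpoints_only` restricts to final states.

# The breakpoint graph and reconstruction

The graph has $2n$ nodes (one per segment end), one segment edge per
segment, and one breakpoint edge per observed junction.  Every node has at
most one breakpoint edge; inputs violating this (shared end labels,
fold-back junctions) are rejected by validation.  Components are then
exactly: *paths* (stretches of the derivative), *isolated segments*
(deleted material), and *cycles* (duplicated material).  Partial paths are
chained into one start-to-end traversal by adding new breakpoint edges
between free termini (seeded-random join order); added edges are reported
as new, unobserved breakpoints.  Reading the path out — entering a segment
at its head yields $+$id, at its tail $-$id — gives the derivative as a
signed permutation.

**Sorting by reversals.** The inversion series comes from a native
Hannenhalli–Pevzner sorter.  The exact distance is
$d = (m + 1) - c + h + f$ over the doubled breakpoint graph ($c$ cycles,
$h$ hurdles, $f$ fortress indicator); hurdles are unoriented components
minimal in circular containment order (on the line: minimal ones, plus the
greatest if it contains all others), a hurdle is *super* if its removal
promotes another component to hurdle, and a fortress is an odd number of
hurdles, all super.  The sorter applies maximal-score oriented reversals
while any oriented pair exists and explicit hurdle cut/merge reversals
otherwise; *every* chosen reversal is verified to reduce the exact distance
by one, with a brute-force scan over all reversals as a safety net.  The
emitted sequence therefore always has length exactly $d$, which is checked
exhaustively against an independent breadth-first-search oracle for all
signed permutations up to size 5 and on 10,000 random targets each at sizes
6 and 7.

**Scenario assembly.** The sort target is the chained path followed by one
copy of each cycle's read-out appended at the chromosome end.  Appending
there can never disturb an observed junction (chromosome ends are not
junctions), and it gives every non-deleted segment an explicit target
position, so no stray copies end up between path junctions after sorting.
Deletion events for isolated components are placed at seeded-random
positions among the inversions, with spans resolved against the arrangement
at insertion time.  Duplications come last — each cycle's closing junction
is realized by duplicating its read-out block, which preserves all existing
junctions — followed by a repair pass for any observed junction still
missing: candidate events are tried in the order tandem duplication (never
destructive), inversion, deletion (never removing the last copy of a
segment another missing junction needs), each required to keep every
currently-present observed junction; if no single event suffices, a
depth-limited search finds up to two non-damaging preparatory inversions
(flips of the label-carrying copies or of the block between them) before a
finishing event.  `verify_scenario` replays the event list from the intact
chromosome and reports the explained fraction, new-breakpoint count and
event tallies.  Minimality is claimed only for the inversion series, never
for the total event count across the three operation types.

# Synthetic data: what it emulates and what it does not

`generate_history` samples a ground-truth event series on a lattice
chromosome (equal `unit`-length segments, mirroring the equal-block
didactic model) and emits the final arrangement plus its distinct junction
set.  Histories are resampled (bounded retries) when the final breakpoint
set is not representable by the single-path graph model: junction end
labels shared by two junctions, fold-back junctions, or junctions at the
chromosome-end labels (a derivative that lost a reference telomere cannot
be read as one start-to-end path).  These exclusions define the model's
domain; they are restrictions of the *generator*, not silent behaviors of
the analysis functions, which reject such inputs with explicit errors.

`snu_c1_like` builds a chromosome-scale breakpoint set — 239 junctions by
default, the size of the classic paired-end-sequencing exemplar — on a
100 Mb chromosome with a 10 kb lattice.  The orientation-class mix is
near-balanced across the four classes (60/60/60/59), since the exemplar's
true mix is not published.  Junction partners are drawn with gaps of 1 to
1000 lattice units (up to 10 Mb, 10% of the chromosome).  This bound was
chosen after examining the simulation's dynamical regimes: with very short
gaps almost all rearranged material is a negligible fraction of the
chromosome and relaxed state counts are trivially small, while with
unbounded gaps single deletions can erase a third of the chromosome and
the arrangement either collapses or balloons.  In the bounded-broad regime
the simulator reproduces the qualitative behavior reported for the real
exemplar: distinct-junction counts cannot quickly exceed ~100, and state
counts climb with breakpoint counts.  Sequencing noise, false breakpoint
calls and array segmentation error are deliberately out of scope, so
passing tests say nothing about robustness to miscalled junctions.

# Problem sizes and statistical checks

The shipped tests run the free-simulation regime at 100 replicates × 300
events on 500 segments; the footprint experiment at 1,000 replicates per
arm for the trend and fraction estimates, plus 30 paired seed blocks of
1,000 replicates per arm for the one-sided sign test that the
inversion-biased fraction exceeds the uniform one (the effect is a few
percentage points against a block standard deviation of about one point,
which sets the block count and size); reconstruction round trips at 200
random histories up to 100 segments; and reversal-sort validation
exhaustively to size 5 and by 10,000-target samples at sizes 6 and 7.
The acceptance script reruns the same computations at reduced replicate
counts and reports percentages.

# Known limitations

* Haploid, single-chromosome model: no translocations, no two-path
  (diploid) decomposition, no breakage–fusion–bridge mechanics.
* The scenario builder guarantees a *valid* explanation, minimal only in
  its inversion count; joint minimization across operation types is open.
* Fold-back (hairpin) junctions and telomere-disrupting derivatives are
  outside the path model and rejected rather than modelled.
* The footprint experiments characterize the synthetic breakpoint
  geometry described above; real breakpoint sets with different clustering
  or class mixes will shift the absolute fractions, though not the
  qualitative separation of the counting conventions.
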