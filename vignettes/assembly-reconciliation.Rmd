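---
title: "Assembly reconciliation with asmrec: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly reconciliation with asmrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmrec)
```

## The problem

De novo assemblers make different trade-offs, so two drafts of the same
genome are usually complementary: where one breaks a contig, the other is
often intact. Assembly reconciliation merges several drafts into one
assembly that is more contiguous without introducing new joins the data do
not support. `asmrec` implements a reconciliation pipeline built on three
ideas:

1. **Rank the inputs** with an overall score computed from read alignments,
   so the user does not have to know which draft is best.
2. **Classify contigs** as True (T) or Uncertain (U) from fragment
   coverage, mate-pair support and GC content, breaking contigs at joints
   the evidence rejects outright and remembering suspicious positions for
   later.
3. **Fuse consensus blocks** — high-identity segments shared by two
   assemblies — through an adjacency graph whose algebra identifies exactly
   which fusions are safe, using the U/T classification to resolve
   repeat-induced conflicts by splitting rather than guessing.

## Ranking model

Alignments are preprocessed first: one best hit per read end (MAPQ,
deterministic tie-breaks), proper pairs kept only when their outer distance
lies within `mu_is ± 3*sigma_is` of a fitted normal insert-size model, and
alignments whose mean base quality falls more than three standard deviations
below the batch mean removed.

Each contig position is then scored: aligned match runs vote `+1` when the
read's MAPQ is at least the file-wide mean (`=`/`X` operators bypass the
heuristic), and `-1` for low-MAPQ matches, mismatches, deletions and
insertions (an insertion is charged to the reference position preceding it).
Votes are summed per position and clamped to sign, so `q_j ∈ {-1, 0, +1}`.
Separately, each read's mean depth over its span, `rc_i`, is flagged `+1`
when it deviates from the contig mean by more than two standard deviations,
else `-1`. The assembly score is

$$\mathrm{score} = \frac{\sum_c \sum_j q_j \;-\; \sum_c \sum_i RC_i}{N},$$

with `N` the number of contigs in the set. Dividing the whole numerator by
`N` keeps scores comparable between drafts of different fragmentation; note
this deliberately rewards contiguity — a draft with fewer contigs and the
same per-base support scores higher. Merging proceeds pairwise in descending
score order.

## Contig classification

Fragment coverage `fc(j)` counts retained, *clip-free* alignments spanning
position `j`. Soft-clipped alignments are excluded on purpose: a read that
had to be clipped disagrees with the contig beyond the clip point, so it
does not witness the join — this is precisely the signal at a misjoin, where
clip-free coverage collapses to zero while clipped coverage merely sags.

Positions with `fc(j) ≤ fc* = alpha * mean(fc)` form candidate regions
(maximal runs; the breakpoint `b_p` is the leftmost minimum). Two rescues
protect genuine low-coverage regions:

* **Mate support.** `M_s` counts alignments in the left flank of `b_p`
  whose mates map to a different contig (`M_p` symmetric on the right), and
  `P_cs = fc(b_p)/(fc(b_p)+M_s)`, `P_cp` likewise (a 0/0 case is defined
  as 1). High rates (`> beta`) mean the mates stay put: the region is just
  shallow, not wrong.
* **GC bias.** `P_GC`, the GC percentage of the region extended by one
  flank on each side, outside `P_g ± 1` percentage point of the whole-set
  GC marks the region as coverage-biased rather than misassembled.

A region is **certainly false** only when all of: `fc ≤ fc*`, `P_cs ≤ beta`
and `P_cp ≤ beta`, and `P_GC` strictly inside the ±1-point band. Contigs are
broken at those breakpoints (fragments below `min_fragment` are dropped and
logged). Rescued regions make the contig **U** and their breakpoints are
kept as error positions; everything else is **T**.

Candidate detection skips the first and last `edge_trim` positions of every
contig. Coverage necessarily ramps at contig termini — and, because a
read's mate must also fit, the ramp extends a full insert length — so the
pipeline default for `edge_trim` is the fitted insert-size mean. Contig
ends are geometry, not evidence.

## The adjacency graph

Consensus blocks between the two assemblies (sets O — higher ranked — and R)
come either from a `show-coords`-style table or from the built-in exact
k-mer matcher. Matches are filtered (`min_block`, `min_identity`),
conflicting overlaps trimmed back longest-first, and survivors numbered;
each block's canonical orientation is its orientation in O. Every contig
becomes a chain of signed blocks; consecutive blocks are adjacent when their
gap is at most `g_max` bases or they overlap end-to-end by at most 1% of the
shorter block. Error positions of U contigs are retained only when they fall
in such an adjacency zone (± one flank); positions deep inside a block are
contradicted by the block itself and dropped.

Block terminals (tail `t`, head `h`) and in-chain conjunctions are the graph
vertices; an edge joins an O vertex and an R vertex sharing a terminal.
Because each terminal occurs at most once per set, the edge set decomposes
uniquely into paths and cycles. Classifying the nine feature combinations
(parity × same set × same adjacency, plus the closed circle) gives:

```{r}
path_taxonomy()
```

Five combinations are infeasible: an odd path always ends in different sets;
ends in different sets cannot share an adjacency; an even open path always
ends in the same set. The feasible types drive the optimization:

* **good** (even, same set, different adjacencies): closing it into a cycle
  fuses two chains into one longer adjacency — the productive move.
* **poor-1 single** (`{1t,1t}`-form): left alone; reconstruction absorbs
  them.
* **poor-1 non-single**: the path traverses conflicting arrangements; any
  U contig it touches with an error position in an adjacency zone is split
  there, and the graph is rebuilt.
* **poor-2** (even, ends in the same adjacency): removed together with its
  chain when both end terminals also occur in good paths (the arrangement is
  then redundant and contradictory); otherwise kept.
* **circle**: agreement between the sets; kept as is.

The algebraic distance `d = N − C − P/2` (cycles `C`, open paths `P`)
measures how far the two sets are from agreeing. `N` is reported both as
the contig count (`d`) and as the block count (`d_blocks`); the latter is
invariant under splitting and is the quantity the merge loop monotonically
decreases. The loop — extract, split/remove poor paths, fuse good paths,
rebuild — runs until an iteration adds no good path and changes nothing,
with an iteration cap equal to the block count (each productive iteration
closes at least one path, and paths are bounded by terminals).

After convergence the chains of both sets are pooled and overlapping chains
merged: a chain whose entire block content already occurs in a longer chain
is absorbed; a chain sharing a two-block prefix or suffix is spliced in with
the last shared block repeated, which is how a repeat copy re-enters the
final adjacency. Sequences are emitted from the higher-ranked set's block
placements (reverse-complemented for negative signs), inter-block spacers
from whichever source contig supplied that adjacency, and blockless contigs
verbatim; every emitted base carries provenance. Sequence outside the first
and last consensus block of a chain's source contigs is not emitted — a
known limitation that trades a little genome fraction for never emitting
unvalidated sequence.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.5 | — | coverage cutoff factor `fc* = alpha * mean(fc)` |
| `beta` | 0.8 | — | mate-support rescue threshold on `P_cs`, `P_cp` |
| `min_block` | 200 | bp | minimum consensus block length |
| `min_identity` | 0.95 | — | minimum block match identity |
| `g_max` | 10 | bp | maximum gap between adjacent blocks |
| `flank` | insert mean | bp | mate-support window, GC window, error-carry zone |
| `min_fragment` | 200 | bp | smallest fragment kept after splitting |
| `edge_trim` | insert mean | bp | contig-end margin excluded from detection |
| `max_iter` | block count | — | merge loop cap |
| `kmer` | 31 | bp | internal matcher k-mer size |

`alpha` trades sensitivity for specificity directly; at 20× or deeper
clip-free coverage, `alpha = 0.5` sits far below the coverage distribution's
bulk, so uniform data yield no candidates while true junctions (which drop
to ~0) are always caught. `beta = 0.8` tolerates four mate-supported reads
per spanning read before rescuing. `g_max` is small because consensus
blocks from the same genome should abut; raising it papers over real
disagreement.

## What the synthetic data emulate — and what they do not

The generator produces genomes with controllable GC and byte-identical
planted repeats, assemblies defined by genome-segment plans (clean cuts or
deliberate chimeric joins) with exhaustive truth tables, and paired reads
with normal insert sizes, two-state quality strings (Q38 body, Q12 tail)
and optional quality-biased substitution errors. Alignments are derived
from the simulation truth (reads placed at their true origin, soft-clipped
at segment boundaries, MAPQ constant), not from a real aligner.

This validates the pipeline's logic — filters, scoring arithmetic, region
detection, the graph algebra, breakpoint localization — under known truth.
It does not exercise: mapping ambiguity in repeats (truth placement is
unique), indel errors or platform-specific error profiles, chimeric reads,
or coverage biases beyond pair geometry. Passing tests therefore show the
method is implemented correctly and recovers planted structure; they do not
by themselves establish error rates on real sequencing data.

Default validation scale is a 100 kb genome at 40× read coverage with
100 bp reads and 300 ± 30 bp inserts — large enough for stable coverage
statistics, small enough that a full replicate runs in seconds on one CPU.

## Numerical and design choices

* Internal coordinates are 0-based half-open; conversions happen only at
  format boundaries (SAM POS, coords tables). Per-position profiles are
  1-based vectors, matching R indexing.
* Ties: best-hit selection breaks MAPQ ties by (contig, start, input
  order); breakpoints take the leftmost coverage minimum; path traversal
  starts from the lexicographically smallest terminal, making fusion order
  deterministic; equal-score assemblies keep input order.
* GC is handled in percent so the rescue band is ±1 percentage point.
* Contigs are split so the left fragment keeps positions `1..b_p`.
* A contig with no consensus blocks passes through reconciliation untouched.
* Chains are canonicalized so the smallest absolute block id appears with
  positive sign, making merged chains comparable across runs.
* `merge_all` does not re-align reads to intermediate results; the U/T
  classification is lifted through emission provenance instead. This keeps
  the tool free of external aligner dependencies; supplying fresh
  alignments per round is possible by calling `merge_pair` directly.
* Poor-2 removal targets the chain owning the path's ends (the redundant
  arrangement); in a tie the lower-ranked set loses.
* Degenerate inputs: empty alignment sets score with a zero coverage term
  and a warning; fewer than two proper pairs disables the insert filter;
  no shared blocks returns the higher-ranked set unchanged with a warning.

## Known limitations

* The ranking score rewards contiguity through its `1/N` normalization; a
  bold misjoin can outrank a cautious split when per-base support is
  otherwise equal. Classification exists to catch exactly those joins, but
  the ranking itself is not misjoin-aware.
* Base-level emission trusts the higher-ranked assembly wherever both cover
  an interval; no per-base consensus is computed.
* The internal matcher finds exact matches only; diverged assemblies (real
  polymorphism, consensus errors) need an external whole-genome aligner's
  coords table.
* Contig tails outside the outermost consensus blocks are dropped from
  merged chains (see above).
* Single-end alignments are exempt from the insert filter and contribute to
  coverage only.
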