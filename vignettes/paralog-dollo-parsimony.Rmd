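---
title: "Reconstructing paralog-count evolution under Dollo parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing paralog-count evolution under Dollo parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollotrace)
```

## The problem

Gene families — microRNA families are the motivating case — are born,
expand by duplication, shrink by deletion, and are sometimes lost
outright along individual lineages. Given a rooted species phylogeny
and, for each family, the number of copies (paralogs) observed in each
extant genome, `dollotrace` answers three questions per family:

* **When did the family arise?** Its origin is dated as the branch
  leading to the last common ancestor (LCA) of all species that carry
  it.
* **How many copies did each ancestor hold?** A most-parsimonious
  assignment of copy numbers to the interior nodes.
* **Where was the family lost?** The branches on which the
  reconstructed copy number drops from positive to zero.

Aggregating these per-family answers over a whole family set gives a
per-branch census of innovation and loss across the tree.

## Model and assumptions

The reconstruction rests on a Dollo assumption: a family arises exactly
once and can never be regained after a loss. For deeply conserved
sequence families this is well justified — it is vanishingly unlikely
that essentially the same sequence arises twice independently — but it
is known to fail for repeat-derived families, which is exactly why the
curation stage caps per-species copy numbers (see below).

Three consequences follow:

1. All computation for a family is confined to the subtree rooted at
   its origin LCA (written `T_m`). Outside it the family simply does
   not exist: those nodes are reported with count 0 and no events are
   charged to them.
2. The LCA is a *conservative* (latest-possible) origin estimate: if
   the family was in fact born earlier and lost in every side branch,
   the LCA will sit below the true origin, never above it. The
   simulator tests assert exactly this descendant-or-self property.
3. Within `T_m`, no node whose subtree contains an observed copy may be
   assigned zero copies.

A further simplification, shared with the cladogram-based scoring: the
method does not model multiple compensating events on a single edge
(e.g. a duplication and a loss cancelling within one branch), and
branch lengths, if present in the input, are ignored.

### The dynamic program

Copy numbers on ancestors are found by a Sankoff-style parsimony
recursion over counts `k = 0..P_m`, where `P_v` is the maximum count
observed among the leaves below `v` (no optimal solution can exceed the
maximum observed count, so the range is safely truncated; a property
test widens the range and asserts nothing changes). Leaves are pinned
to their observed counts. The per-edge cost of changing the count from
`k` (parent) to `j` (child) is, by default, the counting score
`|k − j|` — one unit per copy duplicated or deleted. Asymmetric
per-copy duplication and loss weights, and a per-node multiplier, are
available through `cost_model()`; the defaults are the plain counting
score. The Dollo constraint enters as the boundary condition that
`k = 0` is infeasible at any node with `P_v ≥ 1`. Infeasible entries
are IEEE `Inf`, which propagates exactly through addition and can never
tie with a feasible score.

Scores of the children of a node can be minimised independently (the
minimum of a sum over independent choices is the sum of minima), which
is what makes the recursion linear in the number of edges for fixed
`P_m`; overall work is `O(|T_m| · P_m²)` per family. Multifurcations
need no special treatment: the child sum simply has more terms.

### Backtracing and ties

The set of co-optimal assignments can be wide. The backtrace
is made deterministic by a documented rule: at the family root the
smallest count attaining the minimum score is chosen, and then, going
top-down, each child independently takes the smallest count attaining
its parent-conditioned minimum. This is the most conservative choice
(fewest inferred ancestral paralogs). Because the rule is local, other
equally parsimonious histories exist whenever `n_optima > 1`; the
count of co-optimal assignments is computed alongside the scores and
reported with every reconstruction, so downstream users can tell
unique reconstructions from representative ones.

Loss branches are read off the final assignment: every edge whose
parent holds at least one copy while the child holds none. Under the
default cost these are provably the edges into the maximal all-absent
subtrees below the origin, and a property test asserts that
characterisation independently of the dynamic program.

### Correctness surface

The primary correctness argument is oracle equivalence: an exhaustive
enumerator (`enumerate_family()`, a separate code path that tries
every Dollo-feasible interior assignment) is compared against the
dynamic program on *every* rooted tree shape with up to 7 leaves —
multifurcations included, 143 shapes — crossed with *every* leaf-count
vector with entries up to 3, about 1.6 million reconstructions. Scores,
numbers of co-optimal assignments, and the attained cost of the
returned assignment must all agree. The LCA shortcut (only the first
and last present leaf in preorder matter) is likewise checked against a
path-intersection oracle, exhaustively over all leaf subsets on small
trees and on sampled subsets of a 200-leaf tree.

## The census

`branch_census()` aggregates reconstructions into per-node counts:

* `families_present` — families with at least one copy at the node;
* `gains` — families whose origin is the node (summing to the number of
  families analysed: Dollo means every family originates exactly once);
* `losses` — families lost on the branch entering the node;
* `relative_gain = gains / families_present` at the node. The
  "observed number of families" in this ratio is read as the count at
  the node itself, gains included; the alternative reading (the parent's
  count) is not used, and the choice is deliberate: it keeps the ratio
  in `[0, 1]` and defined at the root.
* `relative_loss = losses / families_present(parent)`. The root has no
  parent branch and its relative loss is `NA`. Zero denominators also
  yield `NA`, not zero — "no families there to lose" is different from
  "no losses".

Copy-level turnover (`paralog_flux()`) tallies, per edge, the copies
gained and lost by the reconstructed counts. The gain edge *into* the
origin is not copy flux — the family's birth is a gain event, not a
duplication — so under the default cost each family's summed flux
equals its parsimony score exactly, an identity the tests assert.

## Curation filters

The filtering stage mirrors how homology-search output must be curated
before counting: a hit is accepted only if its E-value is at most
`1e-10`, its aligned span covers at least 90% of the query precursor,
and the span contains every annotated mature interval of the query
(both arms when both are annotated). All three thresholds are
inclusive at the boundary. Families recovered nowhere are dropped, as
are families with more than 100 copies in any single species — a strict
"more than", so exactly 100 copies is still admissible. The structural
(alignment-based) vetting step that would follow in a full pipeline has
no numeric criterion to implement and is out of scope here; the module
consumes standard 12-column tabular hit files and plain FASTA.

## The simulator

`evolve_family()` generates families under the same model class the
reconstruction assumes, with known ground truth: one copy appears at an
origin node (chosen uniformly at random by default), and on each edge
below it every copy independently duplicates with probability `p_dup`,
after which every copy of the enlarged set is independently lost with
probability `p_loss`. Events within an edge are applied in that fixed
order, so replaying the event log is deterministic; the per-edge
expected multiplication factor is therefore `(1+p_dup)(1−p_loss)`
(not `1 + p_dup − p_loss`; the difference, `p_dup·p_loss`, is
negligible at the default rates but the tests use the exact product
form). Histories that go extinct in every species are redrawn, since
all-zero profiles are inadmissible; the redraw count is reported, and
the resampling slightly biases surviving-family copy numbers upward —
the branching-process test allows for this.

Default rates are `p_dup = p_loss = 0.05` per copy per edge: small
enough that most families keep a single copy over a 30-leaf tree
(matching the empirical observation that most families hold one copy
in most species, with occasional expansions), large enough that
batches of a few hundred families exercise duplications, losses and
whole-subtree extinctions.

What the simulator deliberately does not emulate: sequence evolution
and homology-search failure (false negatives from divergent homologs
or incomplete assemblies), branch-length-dependent rates, and
correlated bursts such as whole-genome duplications. Passing
simulation tests therefore validates the *inference machinery* under
its own model assumptions, not the robustness of conclusions drawn
from real, imperfect scan data.

## Numerical and degenerate-input choices

* Counts are exact integers throughout; scores are doubles (to admit
  fractional cost weights) compared with a `1e-9` tie tolerance in the
  C++ kernels.
* A family observed in a single species has `T_m` equal to that leaf:
  score 0, no edges, no losses.
* All-zero profiles, all-zero count-matrix rows, and empty record
  lists are rejected with the family named.
* Incrementing an *absent* leaf from 0 to 1 can relocate the origin
  and charge several new loss branches at once; the unit-sensitivity
  property of the score holds only for leaves already carrying the
  family, and is tested in that form.
* Interior nodes without input names get deterministic identifiers
  (`N` + preorder rank), so re-running a pipeline reproduces files
  byte-for-byte; annotated newick output writes every node id, which
  is what lets annotations be re-read without a bespoke parser.

## Problem sizes used in the shipped checks

The test suite reconstructs ~1.6 million exhaustive small cases (all
shapes ≤ 7 leaves × all count vectors ≤ 3), checks the LCA on all
subsets of trees up to 12 leaves plus 10⁴ random subsets of a 200-leaf
tree, and runs simulator batches of 300–1000 families on 16–40-leaf
trees. These sizes were chosen to make the exhaustive claims genuinely
exhaustive while keeping a full run of the suite in the minutes range
on a single core; the method itself scales to hundreds of species and
thousands of families without difficulty, since each family costs
`O(edges · P_m²)`.

## Known limitations

* Losses are inferred from absence; incomplete genome assemblies
  masquerade as losses, and nothing in the method can distinguish the
  two. The conservative origin estimate is the flip side of the same
  coin.
* The tie-breaking rule makes reported ancestral counts a *canonical
  representative* of the optimum, not a unique truth; consult
  `n_optima` before interpreting a specific interior count.
* No statistical model: parsimony scores are not likelihoods, and no
  rate heterogeneity across branches or families is estimated.
* Family membership is taken as given (or produced by the simple
  name-based grouping of the filter stage); the package does not
  cluster sequences into families.
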