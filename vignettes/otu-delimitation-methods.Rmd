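---
title: "Methods: threshold-clustering species delimitation and identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-clustering species delimitation and identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otudelim)
```

## The model

`otudelim` estimates species boundaries from barcode sequences in three
coupled steps, each of which is an explicit, testable contract rather
than a black box.

### 1. F-linkage threshold clustering

Given a symmetric matrix of uncorrected p-distances (pairwise deletion:
mismatches over columns where both sequences carry an unambiguous
base), two sequences are *linked* when `d <= t`.  Agglomeration starts
from singletons; a cluster pair (A, B) is mergeable when the linked
fraction of its cross pairs

    f = |{(i, j) in A x B : d(i, j) <= t}| / (|A| |B|)

satisfies `f >= F` and `f > 0`.  The pair with the largest `f` merges
first.  `F` interpolates the cluster shape: `F = 0` demands a single
link (single linkage; provably the connected components of the link
graph, which the tests check against an independent graph-components
oracle), `F = 1` demands all links (complete linkage; every
within-cluster pair satisfies `d <= t`, asserted on outputs).

**Tie-breaking.**  Ties in `f` are resolved by the smaller *maximal*
cross-distance, then the smaller mean cross-distance, then the
lexicographically smallest member ids.  The maximal-cross-distance rule
is deliberate: with it, the `F = 1` schedule coincides with the
complete-linkage dendrogram cut, which makes the number of clusters
non-increasing in `t` at both linkage extremes.  Breaking ties by mean
cross-distance alone looks natural but demonstrably produces occasional
non-monotone cluster counts at `F = 1` (about 2% of random 12-element
matrices in our property checks), because it departs from the
dendrogram order; we consider monotonicity the more valuable contract
and chose the tie-break accordingly.

### 2. Fitting (t, F) against a reference partition

`fit_thresholds()` scans `F` over `{0, 0.5, 1}` (configurable) and `t`
from 0 to the maximal observed distance in steps of 0.0005 — 0.05
percentage points, the resolution at which optimal thresholds are
conventionally reported; a finer step only inflates runtime, a coarser
one blurs the optimal range's endpoints.  Agreement with the reference
is a pair-counting index over *labelled* elements only:

* `rand` — `(a + b) / C(n, 2)`,
* `adjusted_rand` — Hubert–Arabie chance correction,
* `modified_rand` (default) — `2 * Rand - 1`, range `[-1, 1]`, exactly
  1.0 when the restricted partitions coincide.

The MRI definition is a configuration switch rather than a constant of
nature: published uses of the index do not always spell the formula
out, so the package fixes `2 * Rand - 1` as its default and leaves the
other two selectable.  Ignoring unlabelled elements entirely (no
penalty) is the right semantics for database references in which only
a minority of records carries a full species name.

Per `F` the fit reports the maximal agreement and the *set* of optimal
thresholds as min / max / median; the median is the canonical fitted
value (`coef()`).  With a clean divergence gap the optimal set is a
wide plateau and any interior value works; the median is the most
defensible single representative and is robust to the plateau's
edges, which depend on single extreme pairwise distances.

### 3. Species boundaries from phenotype-versus-marker contrast

When no usable reference labels exist, cultured isolates supply one.
The assumption: coded culture phenotype (macromorphology on several
media, physiological assays) drifts faster *within* species than the
DNA marker, while between species the marker accumulates more changes.
On a maximum-parsimony tree from the combined characters, a branch is
marked *within-species* when some phenotype partition has strictly more
DELTRAN changes (`use_lengths`) or strictly higher partitioned Bremer
support (`use_support`) than the marker partition.  Strict inequality
is intentional — equality is no evidence of faster phenotype change.
Marked branches and (by default) branches of total length zero are
contracted; leaves connected by fully contracted paths are conspecific.
Path-contraction, rather than "collapse the marked clade", is what
makes clonal zero-length tips merge with their neighbours without
dragging unrelated leaves along: a single marked terminal joins only
its attachment node, and leaf pairs merge only when *every* edge on
their connecting path is contracted.

## Parsimony machinery

* **Scoring** is generalized (Sankoff) dynamic programming: unit costs
  for unordered characters, linear `|i - j|` costs for ordered
  multistate characters, missing states as zero-cost wildcards, and
  alignment gaps in DNA partitions recoded to missing before scoring.
  Identical site patterns are collapsed to weighted columns.
* **Search** (`bnb_search()`) is exact branch and bound over stepwise
  insertion, seeded with a greedy stepwise-addition bound so pruning is
  effective from the first branch.  All minimal topologies are
  returned in deterministic enumeration order.  The enumeration bound
  is 12 taxa — `(2n - 5)!!` topologies grow past any desk scale at 13
  ((2·13−5)!! ≈ 6.5·10^8) — and the intended use (one representative
  culture per host, a dozen or fewer) sits comfortably below it.
* **DELTRAN** resolves ambiguous ancestral states by retaining the
  parent's state whenever it is among the optimal ones (delaying
  changes toward the tips), remaining ties to the smallest state, in a
  preorder traversal from a root state chosen as the smallest-index
  minimum-cost state.  Tie handling inside DELTRAN is not universally
  standardized across implementations; this package documents its rule
  and keeps it fixed, so branch lengths are reproducible, but exact
  per-branch agreement with other programs' DELTRAN output on tied
  characters is not promised.
* **Partitioned Bremer** for each internal branch is computed from the
  best tree *not* containing that bipartition, found in a single
  multi-target branch-and-bound pass; the partition values are that
  tree's per-partition scores minus the given tree's, so they sum to
  the total Bremer by construction (asserted on every branch in the
  tests) and may legitimately be negative where a partition conflicts
  with the branch.  Among equally good incompatible trees the first in
  enumeration order is used — a deterministic, documented choice.
* **Bootstrap** resamples characters with replacement; a replicate
  supports a clade of the reference tree only when the clade occurs in
  *every* minimal tree of that replicate (strict-consensus convention,
  the conservative choice).  Fixed seeds give bit-identical supports.
* **Midpoint rooting** takes the longest leaf-to-leaf path (ties:
  lexicographically smallest sorted leaf-name pair) and roots at its
  midpoint; an all-zero-length tree is rooted on its first edge with a
  warning.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with the crucial property that the within/between divergence
gap is *guaranteed by construction*, not merely likely: species centres
mutate disjoint species-specific site blocks (at least
`ceil(L * d_between_min / 2)` sites each), members mutate at most
`floor(L * d_within_max / 2)` sites from a separate shared pool, so no
seed can collapse the gap.  Defaults mirror the study conditions the
fitting targets: 6 species x 5 sequences, 600 nt, within-species
p-distance <= 1%, between-species >= 5%, full labelling; host genera
are assigned per species with a specificity probability (0.7 by
default — most species keep one genus, some split over two); deposition
years are uniform over 1995-2012; binary phenotype characters change at
a base rate of 0.04 per species-level branch and at a multiplied rate
(default x8, capped at 0.5; `Inf` means within-species changes only)
per member.

What it does **not** emulate — and what green tests therefore do not
show about real data: indel and alignment error (sequences are
generated gap-free, because the analysis consumes p-distances and
indels would only remove sites), rate variation across lineages,
chimeric or mislabelled database records, non-uniform deposition
effort, and correlated phenotype characters.  The overlap filter and
the GenBank metadata parser are exercised on constructed fixtures
instead.

A small bundle of hand-checkable instances
(`simulate_worked_examples()`) carries the documentation examples: a
three-element distance chain separating single from complete linkage,
tiny character matrices with enumerable parsimony behaviour, a
six-sequence coverage table, and a nine-culture annotated tree whose
marked and zero-length branches yield six species under the boundary
rule.  That tree is a *synthetic reconstruction* of a published study
layout from its verbal description (its branch statistics are chosen to
realise the described marking pattern, and the placement of one
terminal relative to its neighbouring clade follows one consistent
reading of the prose); it demonstrates and tests the rule, it is not
measured data.  The same holds for the shipped coded-phenotype CSV
(`synthetic_coded_phenotype()`): a constructed stand-in with the
documented dimensions (9 cultures; 10 macromorphological characters per
medium on three media; 8 binary physiological characters) and
informative-character counts (16 and 4) fixed by construction.

## Temporal coverage

`coverage_series()` clusters the full set once and filters members by
deposition year — stable cluster identities across years; the
alternative, re-clustering each cumulative subset, is available as
`recluster_per_year = TRUE` since the choice is a genuine modelling
fork (cluster identities versus strictly historical reconstruction).
Clusters whose members lack host annotation contribute zero to
host-per-cluster means, which is why those means can fall below one.
An incompletely sampled final year can be recoded as `year - 0.5` at
metadata-parse time so cumulative curves do not overstate it.  The
default sensitivity grid crosses `F in {0, 0.5, 1}` with thresholds
1-5% in 1-point steps plus any fitted optima.

## Degenerate inputs and edge rules

* A distance pair with zero shared non-gap columns is an error naming
  the pair (its distance is undefined), not a silent `NaN`.
* `F = 0` still requires one link: a threshold below every distance
  yields all singletons at any `F`.
* An alignment must have at least two records; a character matrix of
  all `?` is accepted and simply has zero informative characters.
* Host parsing never invents data: genus is the first token of the
  host qualifier, species is set only when a second token other than
  `sp.`/`spp.` follows, absent qualifiers stay `NA`.
* Cluster labels (`C1, C2, ...`) and species labels (`S1, S2, ...`)
  are assigned in order of each block's lexicographically smallest
  member, so outputs are stable under re-serialization.

## Problem sizes

The shipped checks run at sizes chosen to keep the full suite fast on
one CPU while still exercising every contract: clustering properties on
100 random 20-element matrices; exact-search equivalence against
exhaustive enumeration (via an independent phylogenetics library) on 50
random 5-7-taxon matrices; parameter recovery on 20 seeded replicates
of the 6 x 5 two-level design; boundary-rule recovery on 20 seeded
replicates of a 4-species x 2-sequence design with phenotype evolving
only within species.  These sizes are the package's own test design;
the functions themselves accept anything within the documented bounds.

## Known limitations

* Exact parsimony (search, Bremer) is capped at 12 taxa; no heuristic
  fallback is bundled — use a dedicated phylogenetics package beyond
  that.
* p-distances only; no evolutionary-model correction (the thresholds
  being fitted are themselves defined on uncorrected distances).
* No multiple-alignment construction: the package consumes alignments.
* Identification quality is bounded by the reference: a query
  co-clustered with a mislabelled reference inherits the mislabel.
* The boundary rule presumes phenotype characters drift faster within
  species than the marker; for markers with strong intraspecific
  structure, or phenotypes under stabilizing selection, its premise —
  and hence its output — fails quietly.  Fit diagnostics (a narrow or
  fragmented optimal-threshold set, sub-1 agreement maxima) are the
  practical warning signs.
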