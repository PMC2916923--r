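---
title: "Methods: SSE-descriptor random forests for SCOP pair classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSE-descriptor random forests for SCOP pair classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sseforest)
```

## The model

`sseforest` treats SCOP classification as pairwise supervised learning. A
*pair* of domains with the same number N of secondary structure elements is
labelled by the deepest SCOP level the two domains share — `FA` (same
Family), else `SF`, else `FO`, else `CL`, else `NA` (no shared level) — and
is represented by a flat numeric vector of structural descriptors. A random
forest learns the mapping from descriptors to pair type; applied to a pair
of one unclassified *target* and one classified *template*, the predicted
pair type transfers the template's lineage to the target down to the
predicted level.

The key assumptions are:

* **Equal SSE counts.** Structurally equivalent SSE pairs are matched by
  sequential (N→C) order, which is only defined when the two domains have
  the same number of SSEs. `pair_feature_vector()` enforces this as a
  precondition; comparing domains of unequal N is out of scope.
* **Descriptor similarity tracks classification depth.** The premise is
  that two domains sharing a deep level have similar inter-SSE geometry,
  accessibilities and lengths. The forest does not use coordinates directly,
  only the descriptor summary, so it cannot distinguish structures that
  these descriptors do not separate.
* **Labels come from a curated hierarchy.** `NA` means "shares no level in
  the current release", not "structurally unrelated"; confidently
  contradicted `NA` labels are treated as evidence for hierarchy edits
  (`merger_suggestions()`), not as model errors per se.

## Descriptors and the feature layout

Per SSE (from `sse_geometry()`): summed solvent accessibility (Å²), residue
count, and binary type (0 = α-helix, 1 otherwise). Per SSE pair i < j:
Euclidean distance between the unweighted Cα centroids (Å) and the angle
between the first→last Cα axis vectors, folded to [0, 180]°. The pair vector
(layout version 1, `feature_names()`) stores both domains' raw values
interleaved, then four root-mean-square differences (distance, angle,
accessibility, length blocks), then global sequence identity; hence
M = 2·N(N−1) + 6·N + 5.

Choices made where the design was genuinely open:

* **Accessibility aggregate = sum.** A per-SSE total preserves the length
  signal; the mean is available via `acc_agg = "mean"`.
* **Axis direction is kept N→C and the angle folded to [0, 180]°,** so
  parallel and antiparallel packing are distinguished — a biologically
  meaningful contrast — without needing circular statistics: the RMS of
  plain degree differences is well defined on the folded range.
* **Both domains' raw descriptors are stored alongside the RMS block.**
  Raw values let trees condition on absolute geometry (e.g. all-α vs
  α/β spacing), while the RMS block captures the similarity signal
  directly. The layout is versioned and recorded in trained models so
  serialized artefacts can be validated; no result in this package depends
  on the absolute value of M.
* **Sequence identity** is computed from a Needleman–Wunsch global
  alignment (BLOSUM62, gap opening 10, gap extension 0.5, via Biostrings)
  as identical positions / aligned length including internal gaps. The
  identity filter keeps pairs strictly below 35%, reading "below" as a
  strict inequality.
* **Helix codes.** By default only DSSP `H` runs count toward the 4-residue
  helix rule; `segment_sses(helix_codes = c("H","G","I"))` widens this to
  3₁₀/π helices, since assignment granularity is a corpus-level convention
  rather than a property of the method.
* **Residues without a Cα atom are dropped before segmentation**, and
  alternate locations resolve to the highest-occupancy copy (first wins on
  ties).

## The forest

`train_forest()` implements the ensemble directly, because its probability
semantics — not just its argmax — drive the downstream decision rules:

* T = 10 trees by default, each grown on a bootstrap sample of n pairs
  drawn with replacement.
* At each node, m = max(1, ⌊log₂(M+1)⌋) candidate features are drawn
  uniformly without replacement (`attributes_per_node()`; M = 35 → m = 5).
  The floor and the minimum of 1 are our documented reading of the
  conventional default.
* The split maximises information gain over midpoint thresholds between
  consecutive distinct values (Gini available via `split = "gini"`). Ties
  keep the first candidate in draw order, making training a pure function
  of the seed.
* Trees are unpruned: recursion stops only at pure nodes or when no
  candidate split improves the parent (identical feature rows with mixed
  labels therefore form legitimate impure leaves). No depth cap, no minimum
  leaf size.
* A leaf stores raw class counts. The forest probability of a class is the
  unweighted mean over trees of the leaf ratio; the label is the argmax,
  with ties broken by the fixed class order CL, FO, SF, FA, NA.
* Out-of-bag accuracy is computed and reported in `glance()` but is not
  used by any pipeline decision.

Determinism: all randomness (bootstrap, per-node feature draws) is consumed
inside a `withr::with_seed()` scope, so `(data, trees, seed)` fixes the
model exactly; models round-trip through JSON (`write_forest_json()`)
without changing a single prediction.

## Decision rules

Probabilities are binned as printed in the reference tables: `p < 0.5`,
`p = 0.5`, `0.5 < p < 0.9`, `p ≥ 0.9`. Equality at 0.5 is tested after
rounding p to 10 decimal places because averages of leaf ratios produce
values like 0.4999999999 that are exactly one half in intent.

`classify_target()` aggregates a target's predictions over templates grouped
by template lineage: (i) NA argmaxes propose nothing; (ii) the deepest
argmax level among a lineage's templates is reported for that lineage;
(iii) if at least two templates (configurable, our reading of "multiple")
have shared-level p < 0.8 and next-deeper-level p > 0.2, the suggestion is
promoted one level; (iv) p ≥ 0.5 marks an accepted suggestion and p ≥ 0.9
high confidence. A promoted suggestion reports the deeper level's
probability (the maximum across its supporting templates), which makes the
confidence tier conservative. The depth order is NA < CL < FO < SF < FA.

`triangle_violations()` checks transitivity over predicted pairs: a triple
is flagged when exactly two of its edges carry the same shared level (one
of CL/FO/SF/FA) and the third differs. Two `NA` edges are *not* treated as
a shared level: an `NA` prediction asserts the absence of a relation, and
absence does not propagate to the third edge.

`merger_suggestions()` keeps misclassified pairs with p ≥ 0.9: a prediction
deeper than the recorded level suggests merging the two nodes at the
predicted level ("merge"); a shallower prediction suggests a missing element
at the recorded deeper level ("new_sublevel").

## The synthetic benchmark

`make_hierarchy()` generates the package's test bed: a full factorial
hierarchy whose descriptor similarity decreases with lineage distance, the
mechanism the classifier is supposed to exploit. The defaults — 2 classes ×
2 folds × 2 super-families × 2 families × 5 domains per family, N = 3 SSEs —
give 80 domains and 3160 pairs with every pair type well represented
(roughly 25% CL, 13% FO, 6% SF, 5% FA, 50% NA), large enough that each
class exceeds 30 pairs in a 30% holdout while the whole pipeline runs in
seconds on one core.

The generative model: a base geometry of alternating ideal helices
(rise 1.5 Å/residue, radius 2.3 Å, twist 100°/residue) and strands
(rise 3.3 Å) is perturbed with nested Gaussian noise on SSE origins —
σ = 16, 4, 1, 0.25 Å at the class, fold, super-family and family steps, a
factor of 4 between adjacent levels so that sibling spacing cleanly
separates the levels — with domains perturbing their family prototype at
0.25·σ_family. Direction noise and accessibility-mean noise scale with the
same σ, fold prototypes additionally re-draw SSE lengths, and sequences
mutate a family prototype at 0.8 per position, producing within-family
identities of roughly 0.2–0.35 so the 35% filter and the identity feature
are both exercised. All generators are pure functions of an explicit seed.

What passing the synthetic benchmark does **not** show: real domains are not
ideal helices on Gaussian-jittered scaffolds; real hierarchies are deeply
imbalanced, non-factorial, and contain lineages whose descriptor clouds
overlap. The imbalance stress test (Fold/Super-family pairs thinned to
~2.5% training prevalence via `downsample_prevalence()`) probes one of
these gaps; the published-benchmark regression in
`scripts/acceptance.R` checks the metric arithmetic against real-data
results without re-running the real-data experiment, which would require
the SCOP 1.69/1.73 ASTRAL downloads.

## Numerical choices and degenerate inputs

* `pair_angle()` clamps the dot product to [−1, 1] before `acos`.
* An SSE whose first and last Cα coincide has no axis and is an error, as
  is an SSE with fewer than 3 residues.
* MCC with any zero margin is undefined; `mcc()` returns 0 with a warning.
  One-vs-rest products are computed in double precision (they overflow
  32-bit integers on realistic set sizes).
* The identity filter and all level comparisons use exact string prefixes
  of the sccs lineage, never numeric parsing of its fields.
* Probability sums are guaranteed to 1 within 1e-9 (each tree's leaf ratios
  are an exact distribution; averaging preserves this up to float error).

## Problem sizes

The test suite and the acceptance script use the generator defaults
(80 domains / 3160 pairs, 70/30 stratified split, 10 trees); the full suite
runs in well under a minute and the acceptance script in a few minutes on a
single core. These sizes were chosen as the smallest grid at which every
pair type is populated enough for stable per-class MCC; scaling the counts
up changes runtimes, not the code paths.

## Known limitations

* Targets can only be matched to templates with the same SSE count; no
  substructure matching across unequal N.
* The DSSP reader consumes classic DSSP output files; the package never
  re-implements the hydrogen-bond assignment itself, and the synthetic
  annotation writer (`write_domain_dssp()`) merely reuses DSSP's file
  layout.
* mmCIF coordinates and SCOP domain-boundary inference are unsupported;
  unclassified chains are treated whole.
* `triangle_violations()` enumerates all triples and is intended for
  diagnostic use on moderate prediction sets, not genome-scale sweeps.
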