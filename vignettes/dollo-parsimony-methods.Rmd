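---
title: "Single-gain parsimony for gene-family evolution: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-gain parsimony for gene-family evolution: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollopsin)
```

## The model

A gene family's distribution across terminal clades is explained by a
**single-gain (Dollo) history**: the family originates exactly once, at some
node of the rooted species tree, and may then be lost any number of times,
irreversibly — a lineage that loses the family never regains it. Under this
model the most parsimonious history for an observed presence/absence row is
fully determined:

* the **gain node** is the last common ancestor (LCA) of the terminals that
  retain the family — any higher gain only adds losses, any lower gain cannot
  cover all present terminals;
* the **minimal loss set** consists of the maximal subtrees below the gain
  node whose terminals are all absent; one loss on the subtending branch
  covers every descendant, so counting maximal subtrees is both necessary and
  sufficient.

`reconstruct_family()` implements exactly this; the test suite checks it
against an independent oracle that enumerates every internal-state assignment
with exactly one 0→1 transition and takes the minimum number of 1→0
transitions, over randomized rooted binary trees of 4–7 tips and random
presence rows (500+ cases at a fixed seed). The two must agree everywhere,
and do.

Two evidence-driven refinements extend the plain model:

* **Gain overrides.** When gene-tree placement supports an origin deeper than
  the LCA of the retaining clades, the gain can be pinned to a named ancestor
  (`family_config(gain_override=)`). The packaged configuration pins the
  xenacoelomorph-specific opsins to the Bilateria node: phylogenetically they
  sit close to the r-opsins, so an origin in the bilaterian ancestor followed
  by transformation into (or replacement by) the canonical r-opsin lineage is
  the minimal-step reading. Overrides are validated to be ancestral to the
  observed presences; an inconsistent override is a configuration error, not
  a silent adjustment.
* **Surrogate homology.** If family A is assumed homologous to family B, the
  absence of A in a lineage that retains B is not evidence of loss. Such
  branches are recorded as *suppressed losses* — explicit, logged events that
  replay as absence but do not enter loss totals. This keeps the
  ancestral-repertoire arithmetic honest (the pinned family still counts at
  nodes above the suppression) without inflating the parsimony comparison.
  The packaged configuration applies this to the xenacoelomorph-specific
  opsins with the canonical r-opsins as surrogate.

Gains arising by duplication of another family are bookkept separately
(`duplication_parent`); the packaged configuration marks the noncanonical
r-opsins as a duplication of the canonical lineage. Only losses enter the
between-hypothesis comparison: gain and duplication counts are descriptive.

## The quantities reported

`reconstruct_scenario()` sums per-family events; `ancestral_repertoire(node)`
returns the families whose gain lies at or above `node` with no loss on the
root-to-`node` path, flagging families whose presence at the node is only
virtual (a suppressed branch on the path) as `suppressed` and excluding them
from the headline size. `compare_hypotheses()` tabulates totals per candidate
tree and reports the argmin by losses; ties are reported, never broken.

The **parallel-loss tally** is defined mechanically as the number of families
lost on more than one branch. On the packaged matrix under the main scoring
this gives three multiply-lost families for Xenambulacraria (Anthozoa I three
times; chaopsin and xenopsin twice each) versus one for Nephrozoa (chaopsin);
under the xenopsin-absent scoring it gives two for each hypothesis — the
xenopsin losses collapse to a single deuterostome loss under Xenambulacraria
but split into two (Deuterostomia, Xenacoelomorpha) under Nephrozoa, while
chaopsin's double loss is shared by both trees. We chose the mechanical
definition deliberately: it is the only one that is deterministic, auditable
and symmetric across hypotheses.

## Data representation choices

**Five terminal clades.** The packaged opsin matrix is resolved to Cnidaria,
Xenacoelomorpha, Protostomia, Chordata and Ambulacraria. This is the minimal
granularity at which the loss enumeration is well-defined: coarser (a merged
Deuterostomia) hides the two independent deuterostome losses of xenopsin
under Xenambulacraria; finer (phylum-level) adds within-clade absences that
the clade-level argument does not count. Presence at a terminal means "any
sampled descendant lineage retains the family". Within-Protostomia patterns
(e.g. bathyopsin known only from brachiopods) are below this granularity and
deliberately out of scope.

**`uncertain` as a first-class state.** The xenacoelomorph xenopsin sequences
lack the diagnostic K296 lysine, so that cell is scored `?` in the shipped
TSV and resolved by a policy switch: the main scoring counts uncertain as
present, the alternative as absent. Both scenarios therefore derive from one
source file differing from its companion fixture in exactly one cell (an
asserted invariant), and the policy is an argument everywhere, never
hardcoded.

**Cladograms only.** Branch lengths are ignored; the comparison is purely
topological. Trees must be rooted and binary; unlabeled internal nodes are
auto-named `n<postorder index>` with a warning so every event remains
addressable. Whether Chordata pairs with Xenambulacraria inside Deuterostomia
affects no count at this granularity, but the built-in topology encodes it
anyway for fidelity to the hypothesis as usually drawn.

## Residue homology at K296

The K296 coordinate is carried into an alignment by counting ungapped
reference residues: `map_reference_position()` returns the column of the Nth
ungapped character, which is invariant under inserting all-gap columns
elsewhere (a tested property). Classification at that column is:

* `K` (case-insensitive) → `lysine_present`;
* any other amino acid → `lysine_absent`; ambiguity codes (X, B, Z, …) also
  score `lysine_absent` — the check demands a positive lysine — but carry an
  audit note;
* a gap flanked by sequence on both sides → `undetermined_gap`;
* a gap with no residue at all between the column and one sequence end →
  `undetermined_truncated`.

The truncation rule is the package's own mechanical operationalization of
"incomplete over the site": complete-but-substituted sequences (evidence of
genuine lysine absence) are thereby separated from sequences that simply do
not span the region (no evidence either way). Judgments based on wider
neighborhood context would require a coverage model we deliberately avoid.
The default reference is the embedded 348-residue bovine rhodopsin with
position 296 preset; both are overridable.

## Annotation filtering

Best-hit reduction maximizes bit score with ties broken by lower e-value,
then lexicographic subject id; the ordering is the package's own convention
(scores rarely tie in practice) and every exercised tie-break is logged. The
reciprocal opsin filter keeps a candidate iff at least one of its top-k
(default 3) back-search subjects is a flagged opsin; candidates without
back-hits are removed with reason `"no hits"`. The three-tier pathway
annotation fires strictly in order accession > exact canonical name (with an
explicit deny-list of ambiguous names; no fuzzy matching) > shared cluster
id, where the cluster tier extends in a single non-iterative pass from
configured clusters plus the best-hit clusters of tier-1/2 annotated
proteins. Iterating the cluster extension could chain annotations through
progressively weaker links, so it is not done.

Clade-level aggregation scores a gene present for a group when any member
species carries an annotation; umbrella groups are plain additional
memberships, so umbrella presence dominating subgroup presence is structural,
not special-cased. Presence is boolean throughout — paralog counts are not
modeled.

## Synthetic data: what it emulates, what it does not

The generators exist to make every stage testable offline with known truth:

* `simulate_dollo_matrix()` draws a uniform gain node per family and loses
  each branch below it independently (default study condition: 200 families,
  per-branch loss probability 0.2 on the five-clade tree, 20 replicate
  seeds — sizes chosen so the parsimony bound is exercised across many event
  configurations while each replicate stays sub-second). All-absent families
  are regenerated, so emitted families are observable, which slightly biases
  realized loss counts downward — irrelevant to the bound being tested
  (reconstruction minimality: inferred losses ≤ simulated losses, always).
* `make_alignment_fixture()` plants a lysine column, substitutions and
  truncations in uniform-random amino-acid sequences. There is no
  substitution matrix, no indel model, no rate heterogeneity: identifiability
  of the planted truth is the requirement, realism is not. Passing tests show
  the classifier recovers planted states through arbitrary background
  sequence, not that it handles alignment *errors* — a misaligned column in
  real data misleads it exactly as it would a human reader of the alignment.
* `make_hit_fixture()` emits strictly ordered bit scores (ties only on
  request) and labels subjects; with zero noise the filter's kept set equals
  the true-opsin set definitionally, and the test asserts exactly that plus
  the determinism of the decision log.

Each generator takes one integer seed and sets the RNG once; identical seeds
give byte-identical outputs (asserted).

## Degenerate inputs and numerical conventions

Empty hit tables filter to empty tables; an empty family subset counts zero;
a family absent everywhere has no inferable origin and errors (after the
uncertainty policy is applied, so a family present only as `uncertain` errors
exactly when the policy resolves it absent). All event lists are postorder;
no stage of the packaged analysis uses randomness, so the consolidated
`reproduce_paper()` run is deterministic and idempotent. E-values at the
threshold are retained (≤, matching the conventional cutoff semantics).

## Known limitations

* The engine is parsimony-only: no gain/loss rates, no probabilistic
  reconciliation, no duplication/loss cost weighting. Where a likelihood
  framework would average over histories, this package commits to the single
  minimal one.
* The matrix granularity choice means the packaged numbers are statements
  about five terminal clades; a different clade partition is a different
  analysis and requires re-deriving the matrix from sequence evidence.
* The cluster tier of the annotation cascade trusts the supplied cluster ids
  verbatim (they stand in for similarity-cluster membership); no clustering
  is performed, so its recall is bounded by the metadata's coverage.
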