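---
title: "Comparing rule-based model families with contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing rule-based model families with contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapkit)
```

## The abstraction

A rule-based model specifies a signaling system as reaction rules over
molecular patterns. Its *contact map* is a compact undirected graph: one
node per molecule type, containing one node per binding site (component)
and one per internal state, with an edge for every possible binding
interaction realized by some rule, and unstructured marker nodes for
synthesis and degradation. Crucially, each structure appears exactly once
regardless of rule multiplicity, so a model whose implied reaction network
has thousands of species is summarized by a graph of a few dozen nodes.
The map abstracts the generative rule set, not the reaction network — two
models with different rule sets can share a contact map (see Limitations).

Every element carries a canonical string identifier (molecule `M`,
component `M.c#k` with `k` the 1-based occurrence among same-named sites,
state `M.c#k~s`, edge `{...|...}` with endpoints sorted, unstructured
`M.@syn`/`M.@deg`). Identifier equality *is* element equality across
models; no synonym matching is attempted.

## Parsing decisions

`parseBNGL()` covers the practical BNGL subset that determines the contact
map: block structure, molecule types, seed species and observables (carried
verbatim), and reaction rules with `#` comments, line continuations,
labels, and reversible arrows (`<->` kept as one rule with two rate
expressions). Rates are opaque strings, never evaluated; compartments,
energy patterns and local rate functions are out of scope because the
contact map does not use them, and simulation actions are recognized and
ignored.

Distributed models often omit the `molecule types` block, so molecules used
only in rules are auto-declared from their maximal observed component
signature, with duplicate same-named components resolved left-to-right —
the i-th same-named component written in a pattern maps to occurrence *i*
of the declaration, matching BioNetGen's positional convention and making
the occurrence index in identifiers well defined. A state used in a rule
but missing from the declaration is appended with a warning. A numbered
bond tag must appear exactly twice on one side of a rule; violations are
parse errors naming the rule and tag.

Two further conventions shape edge identity:

* A bond endpoint carries a state qualifier only when the rule writes an
  explicit state on the bonded component on that side (a site that binds
  only when phosphorylated yields an endpoint like `Shc.Y317#1~pY`).
  Qualified and unqualified endpoints are distinct edges.
* Wildcard bonds (`!+`, `!?`) mark a component as binding but contribute no
  edge — the partner is unknown, so there is nothing to draw or match.

Modifiability is detected with a per-rule heuristic: a component is
modifiable when some rule's multiset of explicitly written states for that
(molecule, component, occurrence) differs between the reactant and product
sides. Rules whose molecule appears on only one side — synthesis and
degradation — are excluded, since creating a molecule in a default state
does not modify it. The heuristic is exact for models that write state
changes explicitly, which covers the shipped families and everything the
generator emits; a rule set that changes states only through rule-graph
mapping tricks would evade it, and full BioNetGen rule-graph mapping is
deliberately out of scope.

## The similarity metric

The metric operates on an adjacency-matrix abstraction built bottom-up:
every state is a row; a component is a row only if it has no states already
included; molecules contribute only through their components (a molecule
with no declared sites gets an implicit whole-molecule component, so it
always owns at least one row). For maps *A* and *B*:

* shared nodes `N_s` — rows present in both (identifier equality);
* shared edges `E_s` — edge identifiers present in both;
* node fraction `f_N = N_s / min(rows(A), rows(B))`, edge fraction
  likewise, with "smaller" judged independently per measure;
* absolute score `S = N_s f_N + E_s f_E`.

Fractions are stored in [0, 1] (reports may print percentages); this makes
the self-score law clean: `S(A, A) = rows(A) + edges(A)`. When the smaller
graph has no rows (or edges) the corresponding fraction is defined as 0 —
the paired count term is then also 0, so the score is unaffected and no
division by zero occurs. Edges incident to unstructured
synthesis/degradation nodes are *not* counted by default (they are not
binding interactions); `countUnstructured = TRUE` includes them for users
who consider turnover part of structure. Ties — in the most-complete choice
and in sorting — break lexicographically by model name, so orderings are
deterministic and golden-testable. The most complete member (greatest
rows + edges) reflects how families grow: researchers add structure over
time, so the largest member is the natural sorting reference.

## Comparison semantics

`compareSimilarities()` / `compareDifferences()` are defined as set
intersection and difference over the full element-identifier sets
(molecules, components, states, unstructured nodes, edges). A state element
is shared only on a full match including the state label; a component
element is shared even when its state lists differ (the differing states
then surface as difference elements). An edge is shared only when both
endpoints, including qualifiers, match. The implementation uses hashed set
operations; property tests pin it to a literal O(n²) double loop over
element pairs, so the nested-iteration semantics are observable only as
results, never as cost. `findElement()` answers the family-wide question
"which members contain this site/edge?" and treats an id present nowhere as
all-false, not an error.

## Layout and rendering

`forceLayout()` is two-level: molecule boxes are placed by a
Fruchterman–Reingold pass (`igraph::layout_with_fr`) over the
molecule-adjacency graph, with a fixed iteration count (300) and fixed
cooling; components sit on a grid inside their box in declaration order;
states stack beside their component. No layout algorithm or parameters are
prescribed by the contact-map abstraction itself — any crossing-reducing
layout serves — so the testable contracts are the ones that matter for
comparison: *pinning exactness* (pinned molecule/component coordinates pass
through bit-identically) and *determinism* (same map, seed and pins give a
bit-identical layout; a single unpinned molecule lands at the origin by
convention). Coordinates are abstract units, y-down.

`stabilizeLayouts()` applies a stored reference layout across a family:
elements named in the reference and present in a model are pinned, the rest
are placed force-directed with a per-model seed derived as
`hash(modelName) XOR userSeed` (a stable 31-bit string hash), so panels are
reproducible without global coupling and shared elements occupy identical
positions in every panel. Stored layouts use a versioned tab-separated
format (`#cmapkit-layout v1`; also reads bare `id x y` triples) with
entries sorted on write, so files are diffable and bit-stable. The original
interactive tool kept user-dragged positions in files of an unspecified
format; the dialect here is this package's own.

`renderPanels()` draws grayscale panels (attention belongs to the
overlays), row-wise in family order. Highlight overlays approximate
bubbleset contours with one padded convex hull per connected highlighted
group (connectivity through containment and through edges); the hull is
taken over pad-inflated glyph rectangles, which guarantees the documented
invariant — every highlighted glyph lies geometrically inside its hull —
without the full bubbleset algorithm, which is out of scope. Panels in a
pairwise comparison get a tinted background, so a model that is a complete
subgraph of its partner is still visibly marked despite its empty overlay.
Similarity overlays are green, differences red-orange, mirroring common
usage.

## The synthetic generator

`generateFamily()` emulates the target data: a family grown from a common
core by insertions and deletions of molecules, components, states, binding
edges and synthesis rules. Defaults (5 core molecules, 1–3 components
each, 40% of components carrying two states, 5 binding edges, 4 models,
one edit of each kind per model) match the scale of the published
signaling families the package reconstructs — contact maps with roughly
10–20 adjacency rows and 4–6 edges. Model 0 receives insertions only, so a
planted strict superset always exists; edits apply in a fixed order so the
bookkeeping is unambiguous. Ground truth (element sets, pairwise
shared/only sets, similarity factors, the intended ordering) is computed by
direct bookkeeping on the generator's internal structures — never through
the parser or contact-map code — which makes the end-to-end recovery suite
a genuine two-route check. Names come from fixed pronounceable pools so
identifiers in golden files stay readable.

What the generator does *not* emulate: duplicate same-named components
(occurrence > 1), state-qualified binding, and wildcard bonds — those are
covered by handcrafted fixtures (the trivalent-ligand model exercises
occurrences; the receptor models exercise qualified endpoints). Passing
the synthetic suites therefore demonstrates correctness of the pipeline on
clean, explicitly declared families; real-world files with exotic BNGL
extensions (compartments, energy patterns) are outside the subset and are
skipped with warnings rather than parsed.

## Shipped fixtures

The families under `inst/extdata/` (`egfr_synthetic`, `fceri_synthetic`)
are synthetic reconstructions, written from the published structural
descriptions of the corresponding signaling systems: the EGFR model has 24
rules compressing to 5 molecules, 6 edges and 3 modifiable components
(including the dual-role phosphosite on the adaptor, which both changes
state and binds); the FceRI family shares a receptor-centered core with
4–5 edges per member, and the trivalent-ligand variant differs from its
bivalent sibling by exactly one ligand site (`Lig.l#3`). They are labelled
synthetic in their directory names and serve as compact, verifiable stand-ins
for the original distribution files.

## Problem sizes and numerical choices

The test suite and acceptance checks run at the scale the method is meant
for: families of 2–5 models with maps of 10–40 elements, 100 seeded
families for end-to-end ground-truth recovery, brute-force oracles on maps
of at most 12 elements. Scores are plain double arithmetic on small
integers — no tolerances are needed beyond `all.equal` defaults; identity
laws are asserted exactly. All randomness (generator, layouts) flows from
user seeds kept below 2^31.

## Limitations

* Comparison is contact-map-deep: models with similar but distinct rule
  sets can be identical at this level; detecting such differences needs
  finer-grained rule comparison, which is out of scope.
* Identifier equality is the sole matching mechanism; cross-group
  nomenclature differences must be reconciled before comparison (synonym
  support would be a natural extension).
* Reaction-network generation and simulation are out of scope: the package
  never computes species/reaction counts or time courses.
* The modifiability heuristic is per-rule and explicit-state-based, as
  described above.
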