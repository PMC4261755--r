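# cmapkit

Structural comparison of families of rule-based biochemical models, built
around the *contact map* abstraction.

Rule-based models (BioNetGen language, BNGL) describe cell-signaling systems
as reaction rules over molecular patterns. A single model with a few dozen
rules can imply a reaction network of thousands of species, so comparing two
models by their rule text or their networks is impractical. The contact map
compresses a model into a small undirected graph — molecule nodes containing
binding-site (component) nodes and internal-state nodes, with one edge per
possible binding interaction — in which every structure appears exactly once
no matter how many rules mention it. `cmapkit` parses BNGL into contact
maps, scores and sorts model families with a graph-similarity metric,
computes the shared- and difference-element sets behind comparison overlays,
stabilizes layouts across a family by pinning shared elements, and renders
grayscale small-multiple SVG panels with highlight overlays. It is a
scriptable library plus CLI for computational biologists curating families
of related models.

## The similarity metric

Each contact map is abstracted as an adjacency matrix built bottom-up: every
state is a row/column, and a component is a row/column only if it has no
states already in the matrix (a molecule always owns at least one component,
possibly an implicit whole-molecule one). Elements are matched across models
purely by canonical identifier — molecule name, component name, state name,
and occurrence ("number of times seen"); synonyms are not matched. For two
maps *A*, *B* with shared row count *N_s*, shared edge count *E_s*, and
smaller-graph fractions *f_N*, *f_E* (fraction of the smaller graph's
rows/edges present in the larger), the absolute similarity score is

    S(A, B) = N_s · f_N + E_s · f_E

The two count terms reward large absolute overlap; the two fraction terms
reward containment — if *G* is a subgraph of *H*, both fractions are 100%
regardless of size. Families are sorted row-wise by score against the *most
complete* member (greatest rows + edges). Element identifiers follow a
stable public grammar: molecule `M`, component `M.c#k`, state `M.c#k~s`,
edge `{M.c#k[~s]|N.d#j[~t]}` (endpoints sorted), unstructured
synthesis/degradation `M.@syn` / `M.@deg`.

## Worked example

The package ships a small synthetic EGFR-signaling family under
`inst/extdata/egfr_synthetic/` (reconstructions labelled synthetic; see the
vignette). The full model has 24 reaction rules that compress into a
five-molecule contact map:

```r
library(cmapkit)
dir <- system.file("extdata", "egfr_synthetic", package = "cmapkit")
models <- readBNGLDir(dir)
cms <- lapply(models, contactMap)

cms$egfr
#> ContactMap 'egfr': 5 molecule(s), 10 component(s), 6 state(s), 6 edge(s)
#>   modifiable components: 3; unstructured nodes: 0; matrix rows: 13

sortFamily(unname(cms))
#> FamilyOrdering: reference 'egfr'
#>    1. egfr (score 19.000)
#>    2. egfr_no_sos (score 17.000)
#>    3. egfr_no_shc (score 12.000)
#>    4. egfr_core (score 7.000)
```

The reference model `egfr` scores 19 against itself — its 13 adjacency rows
plus 6 edges. `egfr_core` (ligand binding, dimerization, phosphorylation
only) is a complete subgraph of `egfr`, so both fraction terms are 100% and
its score equals its own size:

```r
sharedFractions(cms$egfr_core, cms$egfr)
#> nodes edges
#>     1     1

compareDifferences(cms$egfr_no_sos, cms$egfr)
#> ComparisonResult (differences) egfr_no_sos vs egfr: 0 only in first, 3 only in second
```

The three elements found only in the full model are the `Sos` molecule, its
binding site, and the `Grb2`–`Sos` interaction:
`Sos`, `Sos.dom#1`, `{Grb2.SH3#1|Sos.dom#1}`. To draw the family with a
stabilized layout and a difference overlay:

```r
ref <- asStoredLayout(forceLayout(cms$egfr, seed = 1))
lays <- stabilizeLayouts(unname(cms), ref, seed = 1)
renderPanels(unname(cms), lays, ordering = sortFamily(unname(cms)),
             path = "egfr_family.svg")
```

The same operations are available from a shell via the wrapper script
(`system.file("exec", "cmapkit", package = "cmapkit")`), e.g.
`cmapkit stats <dir>`, `cmapkit sort <dir>`,
`cmapkit compare <dir> --mode differences --models A,B`,
`cmapkit render <dir> --out panels.svg`.

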