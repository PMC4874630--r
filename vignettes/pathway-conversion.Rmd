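---
title: "From reaction hyperedges to GPML: the conversion model and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From reaction hyperedges to GPML: the conversion model and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbridge)
```

This vignette is the package's account of what it computes and why the
design is the way it is: the source data model, the hyperedge decomposition
and flattening rules, the annotation policy, the over-representation
statistic and its assumptions, the complex-scoring and coverage
conventions, what the synthetic generators do and do not emulate, and the
numerical choices that make everything deterministic.

## The source model

Reaction-centric databases store a pathway as entities participating in
reactions through typed roles.  `pathbridge` captures that shape in a JSON
document format (schema in `inst/extdata/source-pathway.schema.json`):

* **Entities** carry a class (`protein`, `small_molecule`, `rna`, `gene`,
  `process_node` for links to other pathways, `complex`, `entity_set`,
  `other`), diagram geometry, ordered cross-references and PubMed
  literature ids.  Complexes are molecular assemblies with per-member
  stoichiometry; entity sets group *alternative* members that play the same
  role in a reaction, so member stoichiometry is meaningless there and the
  converter ignores it for sets.
* **Reactions** are hyperedges: a backbone polyline plus role-typed
  branches (`input`, `output`, `catalyst`, `activator`, `inhibitor`), each
  referencing an entity.  Every reaction must have at least one input or
  output; process nodes cannot participate in reactions.
* Coordinates are diagram units with the origin top-left and y increasing
  downward — GPML's own convention — so conversion involves no axis flip.

`validate_source_pathway()` enforces the whole invariant set (unique ids,
referential integrity, positive geometry and stoichiometry, container
restrictions) and returns violations as data rather than raising, so a
caller can report all problems at once.  `read_source_pathway()` applies it
and fails with the offending field or id.

## Conversion

Conversion is three steps: carry the metadata, convert the elements,
annotate.

**Metadata.**  The output GPML records the data source and source version
as comments, the organism and authors as attributes, and maintainers (with
email) as comments with source `"Maintainer"` — GPML has no dedicated
maintainer-email slot, so a tagged comment is the least lossy encoding.

**Element mapping.**  `protein → Protein`, `small_molecule → Metabolite`,
`rna → Rna`, `gene → GeneProduct`, `process_node → Pathway`,
`other → Unknown`.  Complexes and entity sets are not node types: each
becomes a GPML Group (style `"Complex"` or `"Group"` respectively) plus one
in-diagram placeholder data node of type `Complex` carrying the container's
label and annotation.  The placeholder uses the `Complex` node type for
both container kinds — GPML has no dedicated "set" node type, and the group
style already distinguishes them.

**Hyperedge decomposition.**  Each reaction becomes one backbone
interaction following the stored polyline, its end arrowhead encoding the
reaction type (`mim-conversion` for transitions, `mim-binding` for
bindings, plain `Arrow` otherwise).  The first input and first output in
document order attach directly to the backbone endpoints (document order is
already unambiguous; the lexicographic tie-break would only matter for an
unordered source).  Every *additional* input/output and every catalyst,
activator and inhibitor becomes its own interaction joined to a fresh
anchor on the backbone.  With `m` anchored branches the anchors sit at
fractions `k/(m+1)`, `k = 1..m`, of the backbone's arc length — even
spacing reproduces the familiar rendered look and guarantees positions in
the open interval (0, 1).  Branch arrowheads encode the role: outputs get
`Arrow` at the node end, catalysts `mim-catalysis`, activators
`mim-stimulation` and inhibitors `TBar` at the anchor end (the convention
rendering engines expect at the attachment point); extra inputs carry no
arrowhead.  This gives the counting law used throughout the tests:

```
interactions = 1 + max(0, #in − 1) + max(0, #out − 1) + #cat + #act + #inh
anchors      = interactions − 1
```

and makes the decomposition reversible: `recover_participants()`
reconstructs the (reaction, role, entity) triples from the document
structure alone, and the test suite asserts exact multiset conservation on
generated pathways.

**Flattening.**  Container components are recursively expanded to their
non-container leaves and drawn once each in a left-to-right, top-to-bottom
grid below the lowest diagram element (10 columns by default, 100 × 30 unit
cells, 60 units of clearance).  The deduplication key is the primary
(first) cross-reference when present, otherwise the display name — labels
are not unique, so the xref wins when available.  Duplicate occurrences are
preserved as pathway comments rather than drawn.  The container → component
linkage is written into the GPML as `"ComplexComponents"` comments on the
placeholder nodes, so any downstream consumer (and `read_component_map()`)
can recover it; the same mapping is returned programmatically as the
`"conversion"` attribute.  Complex-member stoichiometry above 1 is recorded
in a comment on the component node.  Note the flattened nodes are ordinary
data nodes: pathway statistics deliberately see complex members as pathway
content.

**Compartments and notes.**  A compartment becomes a Group plus a labelled
rectangle Shape (double-line border for membranes).  Node membership is
decided by geometric containment of the node's center in the compartment
rectangle, with container-group membership taking precedence (GPML allows
one group per node); the source model's optional `compartment` field is
validated but geometry decides, since rendering is what membership means in
a diagram.

**Annotation.**  Per-class source preference: proteins UniProt-first,
metabolites ChEBI-first, RNAs/genes Ensembl-first, all falling back to
Reactome identifiers; interactions, complexes and pathway links take
Reactome identifiers only.  Absence of any acceptable xref is permitted and
logged.  Every PubMed literature id is carried to exactly one output
element (the entity's main node — flattened copies do not duplicate
references) and encoded the GPML way, as `BiopaxRef` pointers into a
trailing Biopax section.

## The over-representation statistic

With `N` measured identifiers, `R` of which qualify under the user
criterion, a pathway containing `n` measured identifiers with `r`
qualifying is scored

$$z = \frac{r - nR/N}{\sqrt{n \frac{R}{N}\left(1-\frac{R}{N}\right)\left(1-\frac{n-1}{N-1}\right)}},$$

the count `r` standardized by its mean and variance under drawing `n`
identifiers without replacement from the measured universe (the
hypergeometric null).  The assumptions are the usual ones for this
statistic: identifiers are exchangeable under the null, and pathways are
scored marginally (no multiplicity adjustment is built in — the score
ranks).  The variance is zero when `n = 0`, `R = 0`, `R = N` or `n = N`;
those cases return `NA` and rank last.  Counting conventions, chosen where
the statistic's definition leaves room:

* Identifiers, not probes: rows are collapsed after identifier mapping, a
  gene qualifying if *any* of its probes qualifies, so multi-probe genes
  are not double counted against pathway nodes.
* A row with a missing value in a criterion column does not qualify but
  stays in `n` and `N`.
* `n` counts distinct identifiers on a pathway's data nodes, excluding the
  complex placeholder nodes (their content is already present as flattened
  component nodes) and including those component nodes — so a pathway
  authored with complexes scores identically to one authored with the same
  genes as plain nodes, a property the test suite asserts directly.
* Ties in the ranking break lexicographically by pathway name, for
  determinism.

## Complex scoring and colour rules

A complex's score is `100 · q / d` where `d` is the number of distinct
components with a data row and `q` of them qualify.  Components without
data are excluded from both counts — the alternative (counting them as
non-qualifying) would conflate "not measured" with "not significant",
contradicting the usual grey-for-unmeasured rendering convention.  A
complex with no measured component is undefined (`NA`) and takes the
default colour.  Colour rules evaluate in user order, first match wins, and
threshold comparisons are exact: a strict `> 25` rule leaves a score of
exactly 25 unhighlighted.  Gradients interpolate linearly in RGB between
two anchor scores, clamping outside.  Entity sets are scored alongside
complexes — they share the component map, and the percentage is equally
meaningful for alternative members.

## Coverage

A term is covered by a collection iff at least one of its annotated
entities occurs in the collection's identifier set; `compute_coverage()`
partitions terms into only-A / only-B / overlap / uncovered, and the
identities `only_A + only_B + overlap = combined`,
`combined + uncovered = total` hold by construction and are
property-tested.  Coverage is by *direct* annotation — no ontology-graph
ancestor propagation — and identifier unification happens through an
optional static two-column mapping file rather than a live service, for
reproducibility.

## The synthetic generators

The generators exist to exercise mechanics, not to imitate any database's
content distribution.  `gen_source_pathway()` draws 30 base entities and 10
reactions by default (protein-dominated class mix; reactions with 1–3
inputs, 1–3 outputs, 0–2 catalysts and occasional activators/inhibitors;
containers added on top at rate `p_complex = 0.2`, mean size 3, with a
third of later containers nesting an earlier one — nesting is capped at
depth 2 so recursive-flattening oracles stay hand-checkable).  About 15% of
entities lack the class-preferred annotation to exercise the Reactome
fallback, and 5% carry no xref at all.

`gen_expression_table()` plants a signal: planted-pathway genes carry
signal with probability 0.8, background genes 0.1; signal genes draw
`P.value ~ U(0, 0.05)` and `logFC ~ ±N(2, 0.25)`, background genes
`P.value ~ U(0, 1)` and `logFC ~ N(0, 0.25)`.  Under the canonical
criterion `abs([logFC]) > 1 AND [P.value] < 0.05` a signal gene qualifies
with probability ≈ 1 and a background gene essentially never, so the
planted fraction translates directly into qualification rates.  These
simple mixtures are sufficient for recovery and null-calibration tests;
they do **not** emulate correlated genes, probe-level noise,
composition-dependent effect sizes or realistic pathway overlap, so a
passing recovery test says the machinery ranks a strong clean signal first
— not that the statistic is powerful on real data.

Every generator output is byte-reproducible from `(spec, seed)`; the
generators save and restore the caller's RNG state, and each carries a
ground-truth attribute sufficient to recompute every oracle without
re-parsing outputs.

## Numerical and determinism choices

* Numeric XML attributes are written as the shortest decimal (15–17
  significant digits) that re-parses to the identical double, so the
  write/read round trip is exact and output is byte-stable.
* All generated ids come from deterministic per-kind counters
  (`dn_0001`, `bb_0001`, `an_0001`, ...), so converting the same input
  twice yields byte-identical GPML.
* Anchor coordinates are computed by arc-length interpolation along the
  backbone polyline; a zero-length backbone degenerates to its first
  point.
* Output files are written atomically (temp file + rename) and carry no
  timestamps, only version/seed/digest provenance, preserving whole-chain
  byte determinism.
* The writer's output is validated in the tests against a self-authored
  subset XSD covering exactly the emitted dialect
  (`inst/extdata/gpml2013a-subset.xsd`); it is not the full GPML 2013a
  schema.

Test problem sizes — 100 round-trip fixtures of 8 entities, 500 random
reactions for the counting law, 20 settings × 10⁵ hypergeometric draws for
z calibration, 100 recovery replicates over a 20-pathway collection, 500
permutations for the null — were chosen as the smallest sizes at which the
Monte-Carlo standard errors make the assertions meaningful.

## Known limitations

* The GPML reader is the writer's inverse, not a general GPML consumer: it
  tolerates and ignores unknown attributes with a logged warning but does
  not understand the full attribute surface (graphics styling, states,
  GPML 2021).
* Visual styling (colours, fonts, the exact look of complex nodes) is out
  of scope; colour output from the scoring module is a data artifact
  (id → hex), not rendering.
* No live database, BridgeDb or BioMart access: identifier unification is
  via static mapping files, and real exports must be adapted to the
  documented JSON schema.
* Reverse conversion (GPML back to the reaction-centric model) is not
  provided; `recover_participants()` recovers topology for verification,
  not a full document.
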