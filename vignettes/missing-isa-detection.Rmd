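---
title: "Detecting missing IS-A relations in biomedical terminologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting missing IS-A relations in biomedical terminologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isagap)
```

## The problem

Description-logic based terminologies such as SNOMED CT and the NCI
thesaurus let a reasoner infer the subtype (IS-A) hierarchy from concepts'
logical definitions — but only below *fully defined* concepts. When a
curator leaves a concept *primitive*, the reasoner will not place any
subtypes under it, so a concept whose definition is strictly more specific
can sit beside it in the hierarchy with no IS-A edge between them. `isagap`
hunts for exactly these reasoner-invisible gaps. It does **not** run a
reasoner; it consumes an already-inferred release (an RF2 snapshot or the
package's native tables) and audits it.

The pipeline, `find_missing_isa()`, has four stages:

1. **Non-lattice extraction.** A concept pair is *non-lattice* when it has
   two or more maximal common descendants (MCDs); such fragments
   concentrate modeling defects. For each non-lattice pair we compute the
   minimal common ancestors (MCAs) of its MCDs and aggregate every concept
   on a path from an MCD up to an MCA into a subgraph. Candidate pairs are
   all hierarchically unrelated concept pairs inside a subgraph.
2. **Logical subsumption.** Concept X's inferred definition — its set of
   relation groups, direct parents counting as singleton IS-A groups — is
   more specific than Y's when every group of Y has a corresponding group
   of X, which in turn means every relation of the Y-group has a
   more-specific counterpart. Relation specificity is decided by the
   *inclusion rule* (attribute and value each the same or a descendant) or,
   failing that, the *property-chain rule*: with an axiom
   `k_a ∘ k_b ⊑ k_Y`, the relation `(k_X, v_X)` is more specific than
   `(k_Y, v_Y)` when `k_X ⊑ k_a` and `v_X` carries a `k_b` relation to
   `v_Y`. The canonical instance is
   `Causative agent ∘ Is modification of ⊑ Causative agent`, which relates
   an adverse reaction to a modified substance to the reaction to the base
   substance even though the substances are not hierarchically related.
3. **Lexical corroboration.** Because the supertype is primitive, its
   logical definition is by assumption incomplete, so a purely logical
   match can be spurious. Each concept name (semantic tag stripped) yields
   a feature set: `pobj`/`dobj` dependency pairs ("of nerve"), multi-word
   base noun phrases ("malignant neoplasm"), and the residual single words
   not consumed by a dependency pair. The *enriched* set unions in every
   ancestor's features. A suggestion requires the child's enriched set to
   be a superset of the parent's.
4. **Pruning.** Suggestions lying on a directed cycle of existing edges
   plus the suggestion set are dropped; then suggestions derivable by
   transitivity from existing edges plus the other kept suggestions are
   dropped.

## Parameters that matter

`pipeline_config()` exposes the decision points:

* `require_primitive_supertype` (default `TRUE`). In an inferred release a
  fully defined supertype with a genuinely more-specific subtype would
  already have the edge, so only primitive supertypes can hide missing
  relations. On hand-built toy ontologies no reasoner has run, but the
  filter enforces the same semantics; disable it to explore.
* `require_attribute_relation` (default `TRUE`). A supertype defined only
  by IS-A groups gives the comparison nothing to grip; suggestions under
  it would be near-vacuous.
* `chain_value_subtype_allowed` (default `FALSE`). The chain rule demands
  an intermediate relation to exactly the supertype's value; the flag
  relaxes "exactly" to "or a descendant". Off by default because the
  strict reading is the documented semantics of the rule.
* `injective_group_matching` (default `FALSE`). Group matching is
  existential: one subtype group may witness several supertype groups. The
  stricter one-to-one variant is available (decided by exhaustive search;
  group counts per concept are single-digit in practice) for sensitivity
  analysis.
* `provider`. Which syntactic analyzer produces dependency labels and noun
  phrase spans (next section).

## The bundled lexical provider

Feature extraction is parameterized over a provider so a statistical
dependency parser can be plugged in at run time. The test and default
provider is a deterministic rule-based analyzer: tokens are split on
whitespace (keeping `/` inside tokens, so "and/or" stays one word); a
fixed closed class of prepositions is recognized; each maximal run of
non-preposition tokens is a base noun-phrase span; and the last token of a
run that follows a preposition is labelled `pobj` with the preposition as
its head. On the head-final `<modifier>* <noun> (of <modifier>* <noun>)*`
shapes that dominate terminology labels this reproduces a statistical
parser's pairs exactly, and it is bit-stable across versions — which the
byte-identical-rerun guarantee needs. It produces no `dobj` labels (a
custom provider may), performs no lemmatization, plural folding, synonym
expansion or stop-word removal, and keeps all features lowercase.

Two extraction choices deserve a note. Single-word noun phrases are *not*
emitted as phrase features; they fall through to the residual-word rule,
which discards them when a dependency pair consumed their token. This is
what makes the feature set of "Malignant neoplasm of peripheral nerve of
abdomen (disorder)" come out as exactly
`{of nerve, of abdomen, malignant, neoplasm, peripheral, malignant
neoplasm, peripheral nerve}` — "abdomen" and "nerve" are swallowed by
their dependency pairs. Second, a residual word is excluded if its token
served as either the head or the dependent of a pair.

## Design choices in the graph stages

* Common-descendant and common-ancestor computations use
  descendant-**or-self** semantics, which makes singleton cases
  well-defined (a pair endpoint can itself be a common descendant).
* Subgraph nodes are computed as (descendants-or-self of some MCA) ∩
  (ancestors-or-self of some MCD) — the union of all MCD-to-MCA paths.
* Candidate pairs are generated from *all* unrelated node pairs of each
  subgraph, not only those involving MCDs, and only within single
  subgraphs, de-duplicated across subgraphs with provenance kept.
* Non-lattice enumeration is exact: all unordered pairs are screened via a
  cached reachability matrix (pairs sharing fewer than two common
  descendants are discarded by one matrix product before any maximality
  filtering). No heuristic pre-filter on child counts is applied, since a
  single-child concept can still head a non-lattice pair.
* Both orientations of every candidate pair are tested.

## Pruning order and tie-breaks

Cycle removal runs **before** redundancy removal: an edge on a cycle makes
the other edges of the cycle trivially "derivable", which would corrupt
the redundancy check. Cycle removal is simultaneous — every suggestion on
a cycle of (existing ∪ all suggestions) goes, so mutually-suggested pairs
knock each other out. Redundancy removal processes suggestions in sorted
`(child, parent)` order and repeats to a fixed point; the sequential
variant is used because "remove everything implied by the rest" is
ill-defined when two suggestions mutually imply each other. The result is
a minimal subset whose closure with the existing edges still covers every
suggestion, and the ordering makes it deterministic. Suggestion tables are
sorted before writing, so identical inputs give byte-identical TSVs.

## The synthetic generators

`random_dag(n, edge_prob, seed)` draws child-to-parent edges only from
higher to lower concept index (acyclic by construction) and assigns
synthetic `"<modifier> <noun> of <site>"` names from a controlled
vocabulary the rule-based provider parses exactly.

`plant_missing_isas(n_background, n_planted, seed)` builds, per planted
relation, a five-concept motif: two shared roots, a primitive parent with
one attribute group, a fully defined child whose groups are pointwise
same-or-more-specific, and a decoy so the roots have three maximal common
descendants and hence form a non-lattice pair. Odd-numbered motifs realize
specificity through the inclusion rule (the child's value a child of the
parent's value), even-numbered ones through a property chain with an
"is modification of"-style intermediate. The child's name prefixes the
parent's with one modifier token, so the lexical superset holds by
construction. The defaults — 200 background concepts, 5 planted relations,
background edge probability `4 / n_background` (about two parents per
concept, a realistic sparse terminology density) — are the package's
standing validation conditions. Background concepts deliberately carry no
attribute relations, so the supertype attribute filter excludes every
background-only pair; the generator's certificate re-runs the full
pipeline and asserts that exactly the planted set is recovered.

What the generator does **not** emulate: real terminologies' scale (the
validation instances have a few hundred concepts, full releases have
hundreds of thousands), their noisy names (abbreviations, punctuation,
coordination), near-miss lexical overlaps between unrelated concepts, and
genuinely wrong existing edges. Perfect recall and precision on planted
instances therefore demonstrates that the machinery finds exactly what its
rules define — not that those rules achieve any particular precision on a
real release, where curatorial review remains indispensable.

## Degenerate inputs and numerics

Empty supertype definitions hold vacuously at the comparison level; the
attribute-relation filter keeps them from producing suggestions. An empty
IS-A table is a valid ontology (every concept parentless). Attribute
tables without a group column get one singleton group per relation, the
convention for terminologies that do not group relations. Inactive
concepts are dropped together with any relation that mentions them;
unknown identifiers are validation errors, as are IS-A cycles (reported
with one offending cycle). All computations are exact set/graph
operations; there are no tolerances.

## Problem sizes

The shipped validation suite works at desk scale by choice: oracle
equivalence on twenty random DAGs of 20–50 concepts against brute-force
fixed-point oracles, and recovery on ten planted instances of ~240
concepts each. The worked-example fixture has 14 concepts. All graph
queries go through a cached dense reachability matrix, which is the right
trade-off at these sizes; a full-release run would want the packed-bitset
variant of the same computation.

## Known limitations

* No reasoning beyond the two relation-specificity rules: no nested
  existentials, no chains longer than two properties, no chaining of
  chains, no general concept inclusions.
* Property chains are supplied as a table, not parsed from OWL axiom
  refsets; in current SNOMED releases the relevant chains are few.
* Lexical matching is exact string matching over lowercased features;
  plural/singular variants ("nerve" vs "nerves") only connect through
  enrichment via ancestors that carry both forms.
* The tool suggests; it does not repair. A confirmed missing relation may
  be better fixed by amending a logical definition than by asserting the
  edge, which is an editorial decision outside this package's scope.
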