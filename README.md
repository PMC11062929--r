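# isagap

Quality assurance for the IS-A hierarchy of description-logic based
biomedical terminologies (SNOMED CT, NCI thesaurus, and anything else with
concept names and grouped logical definitions).

Reasoners infer subtypes only under *fully defined* concepts. A concept
whose inferred definition is strictly more specific than a *primitive*
neighbour's can therefore sit beside it with no IS-A edge — a missing
hierarchical relation no amount of re-classification will surface.
`isagap` finds candidates for these gaps:

1. **Non-lattice extraction** — pairs of concepts with ≥ 2 maximal common
   descendants flag defect-prone fragments; hierarchically unrelated pairs
   inside those subgraphs are the candidates.
2. **Logical screening** — X's definition `I_X = {X_n}` (relation groups;
   direct parents as singleton IS-A groups) is more specific than `I_Y`
   iff every group `Y_m` has a corresponding `X_n` in which every relation
   `(k_Y, v_Y)` has a more-specific counterpart `(k_X, v_X)`, by the
   *inclusion rule* (`k_X ⊑ k_Y` and `v_X ⊑ v_Y`) or the *property-chain
   rule* (`k_a ∘ k_b ⊑ k_Y`, `k_X ⊑ k_a`, and `v_X —k_b→ v_Y`, e.g.
   `Causative agent ∘ Is modification of ⊑ Causative agent`).
3. **Lexical corroboration** — the child's ancestor-enriched lexical
   feature set (dependency pairs, multi-word noun phrases, residual words
   of the tag-stripped name) must be a superset of the parent's.
4. **Pruning** — cycle-causing suggestions, then transitively redundant
   ones, are removed.

Input formats: SNOMED CT RF2 snapshot releases (`load_rf2_snapshot()`) and
a plain TSV/JSON native format for toy or NCIt-style ontologies
(`load_native_tables()`; ungrouped attribute tables get one singleton
group per relation).

## Worked example

The bundled fixture reconstructs a real non-lattice fragment around the
pair ("Neoplasm of peripheral nerves of trunk", "Neoplasm of abdomen"):

```r
library(isagap)
ont <- paper_fixture_snomed()

inferred_definition(ont, "126992002")
#> <inferred_definition> 126992002: 3 relation group(s)
#>   [1] {(116680003 : n-abdomen)}
#>   [2] {(116680003 : npn-trunk)}
#>   [3] {(assoc-morph : morph-neoplasm), (finding-site : site-pn-abdomen)}

initial_feature_set("Malignant neoplasm of peripheral nerve of abdomen (disorder)")
#> [1] "malignant"          "malignant neoplasm" "neoplasm"
#> [4] "of abdomen"         "of nerve"           "peripheral"
#> [7] "peripheral nerve"

summary(find_missing_isa(ont))
#> <isa_report>
#>   non-lattice subgraphs : 1
#>   candidate pairs       : 4
#>   raw suggestions       : 2
#>   removed (cycle)       : 0
#>   removed (redundant)   : 0
#>   kept                  : 2
#>   Malignant neoplasm of peripheral nerve of abdomen (disorder) IS-A Neoplasm of peripheral nerves of abdomen (disorder)  [inclusion, lexical margin 4]
#>   Benign ganglioneuroma of abdomen (disorder) IS-A Neoplasm of peripheral nerves of abdomen (disorder)  [inclusion, lexical margin 3]
```

The supertype "Neoplasm of peripheral nerves of abdomen (disorder)" is
primitive, so neither suggested edge could have been inferred by a
reasoner; both were screened logically (every relation group matched via
the inclusion rule) and lexically (the child's enriched feature set covers
the parent's, with the margin counting the child's extra features). The
pair of concepts above the fragment has three maximal common descendants —
the two suggested children plus the supertype itself — which is what made
the fragment non-lattice and put the pairs on the candidate list.

`paper_fixture_chain()` holds the matching property-chain example:
`relation_more_specific()` returns `"chain"` for (Causative agent: Sodium
calcium edetate) vs (Causative agent: Edetate), and `NULL` once the chain
table is emptied.

`plant_missing_isas(n_background, n_planted, seed)` generates synthetic
ontologies with planted missing relations (and a self-check certificate)
for validation; `random_dag()` supplies random hierarchies for
property-based testing against brute-force oracles.

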