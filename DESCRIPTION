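Package: isagap
Title: Detecting Missing IS-A Relations in Biomedical Terminologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the subsumption (IS-A) hierarchy of description-logic
    based biomedical terminologies such as SNOMED CT and the NCI thesaurus.
    Candidate concept pairs are drawn from non-lattice subgraphs of the
    hierarchy, screened by relation-group-level logical-definition
    subsumption (an inclusion rule plus a property-chain rule), corroborated
    by an ancestor-enriched lexical-feature superset check, and finally
    pruned of redundant and cycle-causing suggestions. Includes readers for
    SNOMED CT RF2 snapshot releases and a simple native table format, worked
    example fixtures, and a generator of synthetic ontologies with planted
    missing IS-A relations for validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
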