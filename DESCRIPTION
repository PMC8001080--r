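Package: ontoslim
Title: Slimming Chemical Ontologies into Browsable Application Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a simplified, curator-friendly view of a large
    chemical ontology such as ChEBI. Extracts the subset of an OBO ontology
    reachable from a curated seed list, automatically prunes uncurated
    single-lineage grouping chains, synthesizes "other" catch-all classes,
    applies reviewed edit scripts for manual reorganizations, materializes
    "has role" existential axioms into a browsable compound-by-role hierarchy,
    reports curated terms lacking roles, computes tree-complexity metrics
    (source depths, children per parent), and validates used identifiers
    against new ontology releases. Includes a synthetic-ontology generator
    emulating the pathologies of real chemical ontologies (deep single-child
    grouping chains, multi-parent terms, obsolete and merged identifiers) and
    a command-line interface for weekly-build automation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
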