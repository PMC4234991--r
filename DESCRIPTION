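Package: phenolink
Title: Linking Genetic Associations to a Phenotype Ontology with
    Gene-Overlap Resampling Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a queryable knowledge base that links genetic-association
    records (gene, phenotype description, optional variant and p-value) to
    concepts of a human-phenotype ontology parsed from OBO flat files.
    Concept labels are matched to free-text phenotype descriptions by exact
    case-folded substring search over a generalized suffix array; precomputed
    phenotype-to-concept mappings can be imported directly.  Each concept's
    gene set is closed over its ontological descendants; gene sets of several
    concepts can be intersected and the size of the overlap assessed with an
    empirical p-value obtained by resampling same-size gene sets from the
    knowledge base's gene universe, with an exact hypergeometric-composition
    null for verification.  Includes a synthetic fixture generator with
    planted gene overlaps and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    stats
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
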