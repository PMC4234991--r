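# phenolink

Links genetic-association records to a human-phenotype ontology and tests
whether the genes shared by several related phenotypes could have overlapped
by chance.

## Who this is for

Individual gene-phenotype associations from GWAS and legacy association
catalogues are often weak, especially for complex neuropsychiatric
phenotypes. One way to lend weight to an unconfirmed association is *in
silico* replication across the phenotype ontology: if the same genes turn up
in the association lists of several **distinct but ontologically related**
phenotypes, that convergence is unlikely to be noise. `phenolink` is for
anyone who has (1) an ontology in OBO format (e.g. the Human Phenotype
Ontology), (2) association tables pairing gene symbols with free-text
phenotype descriptions, and wants to browse, link and test them from R or
the shell.

## What it does

* **Ontology**: parses OBO `[Term]` stanzas into a DAG of concepts with
  `is_a` edges; navigation (`descendants()`, `ancestors()`), deterministic
  substring search over names and synonyms (`search_concepts()`).
* **Text matching**: a generalized suffix array over phenotype descriptions
  (`build_suffix_array()`, `find_occurrences()`; O(|pattern| · log n)
  lookup) drives exact case-folded substring matching of concept labels to
  association records (`map_labels()`), with a minimum label length
  (default 4) and a stoplist (default `EO`, `ALS`, `age`, `CAD`) to remove
  unspecific short labels. Precomputed phenotype-to-concept mappings can be
  imported instead (`import_mapping()`).
* **Knowledge base**: merges tables and link sets with provenance
  (`build_knowledgebase()`), persists to a single-file SQLite database
  (`persist_kb()` / `load_kb()`).
* **Analysis**: for chosen concepts `c_1..c_m`, each concept's gene set is
  closed over its ontological descendants; the observed common overlap of
  size `k` is then assessed by resampling: every trial draws, per concept,
  a uniform same-size gene sample without replacement from the knowledge
  base's gene universe, and succeeds when the samples share at least `k`
  genes. With early stopping (default) a success at trial `t` reports
  `p = 1/t`; zero successes within the cap `N` (default 1000) reports the
  bound `p < 1/N`. The exact null
  `P(|S_1 ∩ … ∩ S_m| ≥ k)` is also available in closed form
  (`exact_overlap_null()`, a composition of hypergeometric kernels; the
  classical hypergeometric tail at `m = 2`).
* **Fixtures**: `generate_fixture()` emits a synthetic OBO + TSV corpus
  with *planted* gene overlaps and exact ground truth, so the whole
  pipeline is testable without downloading any external database.

## Worked example

Four phenotype concepts are planted to share exactly the genes COMT, HTR2A,
SLC6A3 and SLC6A4 (each concept also carries 10 private genes, partly
attached to a child concept so that descendant closure is exercised), in a
200-gene universe:

```r
library(phenolink)

ids <- sprintf("HP:%07d", 2:5)
fx <- generate_fixture(fixture_params(
  n_concepts = 20, n_records_per_source = 150, universe = 200, seed = 42,
  planted = list(list(concept_ids = ids,
                      genes = c("COMT", "HTR2A", "SLC6A3", "SLC6A4"))),
  n_private_genes = 10))
kb <- fixture_kb(fx)   # parse OBO, text-match, import mapping, assemble
kb
#> Phenotype-association knowledge base
#>   concepts:            20 (0 obsolete)
#>   association records: 300
#>   links:               212
#>   genes:               200
#>   concepts with links: 19

intersect_genes(kb, ids)
#> Gene intersection of 4 concepts
#>   HP:0000002        14 genes
#>   HP:0000003        14 genes
#>   HP:0000004        14 genes
#>   HP:0000005        14 genes
#>   common genes (k = 4): COMT, HTR2A, SLC6A3, SLC6A4

empirical_pvalue(kb, ids, max_trials = 1000, seed = 7)
#> Empirical overlap p-value (4 concepts, k_observed = 4)
#>   trials: 1000 of max 1000  successes: 0  seed: 7
#>   p < 0.001
```

Each of the four concepts contributes a 14-gene descendant-closed set
(4 planted + 10 private); their intersection recovers exactly the planted
genes, and in 1,000 random same-size draws from the 200-gene universe no
draw ever shared 4 or more genes, so only the upper bound `p < 0.001` can
be reported — the observed overlap is far out in the null's tail.

The same workflow is available from the shell via the launcher in
`inst/exec/phenolink` (subcommands `build`, `search`, `show`, `intersect`,
`pvalue`, `fixture`; see `phenolink --help`).

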