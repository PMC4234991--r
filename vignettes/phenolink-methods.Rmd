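---
title: "Linking genetic associations to a phenotype ontology: methods and design"
author: "phenolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking genetic associations to a phenotype ontology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolink)
```

## The problem

Genome-wide association studies report many gene-phenotype associations, but
for complex diseases individual associations are often weak and hard to
replicate. One route to *in silico* replication is structural: if the same
genes are associated with several **distinct but ontologically related**
phenotypes — say bulimia, schizophrenia, depression and psychosis, all
neurological abnormalities — that convergence is itself evidence that the
gene-phenotype relationship is not spurious. Acting on this idea requires
three ingredients, which this package provides:

1. a phenotype ontology (a DAG of concepts connected by `is_a` edges, as in
   the Human Phenotype Ontology) with navigation and substring search;
2. a way to attach free-text genetic-association records to ontology
   concepts, either by exact substring matching of concept labels against
   phenotype descriptions or by importing a precomputed mapping;
3. an analysis layer: descendant-closed gene sets per concept, gene
   intersection across a user-chosen set of concepts, and an empirical
   p-value for the observed overlap obtained by resampling.

## Data model

A **knowledge base** bundles an ontology, a table of association records
(gene symbol, free-text phenotype description, source, optional variant id
and association p-value), a set of **links** — a many-to-many relation
between concepts and records, each tagged with provenance `matched` (found
by text matching) or `imported` (taken from a published mapping) — and the
**gene universe**, the set of all distinct gene symbols occurring in the
records. Gene symbols are uppercased for identity; no alias resolution is
attempted. Links are distinct (concept, record) pairs: the same pair found
by both routes is stored once. The knowledge base persists to a single-file
SQLite database (tables `concept`, `concept_parent`, `synonym`,
`association`, `link`, `meta`).

## Ontology handling

`parse_obo()` interprets only `[Term]` stanzas and the keys `id`, `name`,
`synonym`, `is_a`, `is_obsolete`. The parent graph must be a DAG; a cycle is
a hard error (every closure computation assumes acyclicity), and a dangling
`is_a` target is an error rather than a warning because a silently dropped
edge would silently change every descendant closure below it. Obsolete terms
are parsed but excluded from navigation, search, matching and analysis,
which matches how ontology consumers generally treat them. Multiple
parentage is fully supported; `descendants()` and `ancestors()` deduplicate
concepts reachable along several paths.

`search_concepts()` searches names *and* synonyms case-insensitively and
orders hits by name length (most specific first), then id, so output is
deterministic.

## Text matching

Concept labels are matched to phenotype descriptions as **pure case-folded
substrings**. The index is a generalized suffix array built over the
distinct descriptions, each terminated by a control-character sentinel
(U+0001); construction uses prefix doubling over integer codepoint ranks
(O(n log n), fully vectorized), and lookup is two binary searches per label
(O(|label| log n) probes). Indexing the descriptions and querying each label
yields exactly the same link relation as the converse direction (indexing
labels, scanning descriptions) with fewer, longer documents; the equivalence
is property-tested against a quadratic containment oracle.

Two filters make unanchored substring matching usable in practice and are
explicit, auditable configuration rather than hidden post-hoc edits:

* `min_label_length` (default **4** characters) — very short labels match
  almost anything. The value 4 is a package decision: it is the smallest
  length that excludes the known offending 2-3 character labels while
  keeping real disease names.
* `stoplist` (default `eo`, `als`, `age`, `cad`) — short or ambiguous
  labels known to produce unspecific hits when matched as unanchored
  substrings.

By default only primary concept names are matched; `use_synonyms = TRUE`
extends matching to synonyms, and `word_boundary = TRUE` restricts matches
to those flanked by non-alphanumeric characters. Both are off by default
because plain name-substring matching is the behaviour the rest of the
pipeline is calibrated to, and the extensions change the link relation in
ways a user should opt into knowingly. Case folding is simple lowercasing;
there is no stemming, punctuation stripping or fuzzy matching.

## Descendant closure and intersection

`concept_gene_set()` attributes to a concept the genes of every record
linked to the concept **or to any of its descendants**. This closure is what
lets a broad concept ("neurological abnormality") aggregate evidence
recorded against its specific subtypes. `intersect_genes()` computes the
per-concept closed gene sets and their common intersection; the result is
permutation-invariant and anti-monotone (adding a concept never grows the
common set). Both properties are tested.

## The empirical p-value

For concepts \(c_1, \dots, c_m\) with closed gene sets of sizes
\(n_1, \dots, n_m\) and observed common overlap \(k\), each trial draws, for
every concept independently, a uniform random sample **without replacement**
of size \(n_i\) from the gene universe \(U\), and succeeds when the sampled
sets share at least \(k\) genes ("at least", not "exactly": a chance overlap
larger than the observed one counts against significance). Two estimators
are provided:

* `early_stop = TRUE` (default): sampling repeats until the first success,
  capped at `max_trials` (default 1000). Success at trial \(t\) reports
  \(\hat p = 1/t\); no success within the cap reports the **bound**
  \(p < 1/\text{max\_trials}\) (rendered "p < 0.001" at the default cap).
  This mirrors the repeat-until-found procedure of interactive exploration.
* `early_stop = FALSE`: all `max_trials` trials run and the add-one
  estimator \((s + 1)/(N + 1)\) is reported. This is the statistically
  cleaner fixed-N choice and the one used for calibration testing.

The sampling universe is the knowledge base's own gene universe, not an
external gene catalogue: the null hypothesis is "these concepts' gene sets
are arbitrary draws from the genes this knowledge base maps", which is the
exchangeable population the observed sets actually live in.

By default sample sizes are the **distinct-gene** set sizes, because the
success criterion is defined on genes. The alternative
`sampling_unit = "association_rows"` samples as many association rows as
the concept's closure links and reduces them to genes, for sensitivity
analysis when gene multiplicity across associations matters.

Randomness uses R's default Mersenne-Twister generator under an explicit
integer seed; identical seeds give bitwise-identical results.

### Exact null for verification

`exact_overlap_null()` computes \(P(|S_1 \cap \dots \cap S_m| \ge k)\)
exactly by composing hypergeometric transition kernels: conditional on the
running intersection of the first \(j\) sets having size \(t\), that
intersection is (by exchangeability of universe elements) a uniform random
\(t\)-subset, so its overlap with the next set follows
\(\mathrm{Hypergeom}(U, t, n_{j+1})\). For \(m = 2\) this reduces to the
classical hypergeometric tail. The implementation is itself cross-checked
two independent ways in the tests: against `phyper()` at \(m = 2\), and
against exhaustive bitmask enumeration of all subset combinations on
universes of at most 12 genes at \(m \ge 3\). The Monte-Carlo sampler is
then required to agree with the exact null within three binomial standard
errors.

## The synthetic fixture generator

`generate_fixture()` emits an OBO ontology, a GAD-style TSV (descriptions
embed concept names, so links arise by text matching), a GWASdb-style TSV
(descriptions deliberately contain **no** concept names; links arrive only
through the emitted mapping file) and an exact ground-truth record. Design
choices that make ground truth exact:

* Concept names are equal-length words built from a consonant-vowel
  syllable alphabet, so no name is a substring of any other name or of the
  English filler text, and text matching is collision-free by construction.
* Planted concepts are placed as siblings directly under the root, each
  with one dedicated "carrier" child; half of a planted concept's gene
  records attach to the carrier, so recovering the planted genes genuinely
  requires descendant closure. The random background DAG is kept outside
  these subtrees, so each planted concept's closed gene set is exactly its
  shared-plus-private genes.
* Private genes are drawn disjointly across planted concepts, so the
  intersection of a planted group is exactly its shared genes.
* Every universe symbol appears in at least one record, so the knowledge
  base's gene universe has exactly the requested size; remaining record
  quota is filled with unlinked noise records, emulating the substantial
  fraction of real association records whose descriptions match no concept.

What the generator does **not** emulate: realistic ontology topology (depth
and fan-out distributions of a real phenotype ontology), realistic gene
multiplicity across associations, effect sizes, linkage disequilibrium, or
the messy free text of real association databases. Passing tests therefore
demonstrate correctness of the machinery (parsing, matching, closure,
counting, sampling), not robustness to real-world text noise — the
stoplist/minimum-length filters exist precisely because real text is
messier than the fixtures.

## Problem sizes used in the verification suite

The test suite verifies each pillar at deliberately modest, fully stated
scales: 200 random corpora (each at most 5 kb) times 50 patterns for the
suffix array against a naive scan; 100 random label/corpus pairs for the
link relation against a quadratic oracle; 100 random DAGs of up to 200
nodes for closure against boolean-matrix reachability; 20,000 fixed-N
trials for Monte-Carlo calibration at two settings (two concepts of 50
genes in a 1,000-gene universe against the hypergeometric tail; three
concepts of 5 genes in a 12-gene universe against exhaustive enumeration);
a 500-concept round trip through SQLite; and the four-concept worked
example (four 100-gene sets sharing exactly 4 genes in a 10,000-gene
universe), which yields zero successes in 1,000 trials and the bound
p < 0.001.

## Known limitations

* Matching is exact substring only: no fuzzy matching, stemming or concept
  recognition; paraphrased descriptions produce no links.
* Only `is_a` edges are honoured; `part_of` and other relationship types
  are ignored.
* No analytic p-value is attempted for \(m > 2\) at realistic sizes; the
  exact composition is cheap but the resampling estimate is the primary
  interface, matching the exploratory workflow.
* Single-selection inference: no multiple-testing correction across many
  concept selections is applied.
* The early-stop estimator \(1/t\) is upward-biased for small \(t\); use
  `early_stop = FALSE` when an unbiased-ish estimate matters more than
  mirroring the interactive procedure.
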