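test_that("association TSVs parse with uppercasing, trimming and drop-count", {
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text",
    "r1\tcomt\tschizophrenia",
    "r2\t htr2a \tdepression",
    "r3\t\tdepression",
    "r4\tDRD2\t"), dialect = "GAD") |> suppressWarnings()
  expect_identical(tab$records$gene, c("COMT", "HTR2A"))
  expect_identical(tab$records$phenotype_text[1], "schizophrenia")
  expect_identical(tab$n_dropped, 2L)
  expect_identical(tab$source, "GAD")
  expect_warning(read_association_table(text = c(
    "record_id\tgene\tphenotype_text", "r1\t\tx"), dialect = "GAD"),
    "dropped 1 row")
})

test_that("a header-only file yields zero records", {
  tab <- read_association_table(text = "record_id\tgene\tphenotype_text",
                                dialect = "GAD")
  expect_identical(nrow(tab$records), 0L)
  expect_identical(tab$n_dropped, 0L)
})

test_that("dialect column requirements and row errors are enforced", {
  expect_error(read_association_table(text = "record_id\tgene",
                                      dialect = "GAD"),
               "missing required column 'phenotype_text'")
  expect_error(read_association_table(
    text = c("record_id\tgene\tphenotype_text", "r1\tA\tx", "r1\tB\ty"),
    dialect = "GAD"), "duplicate record_id 'r1'")
  expect_error(read_association_table(
    text = c("record_id\tgene\tphenotype_text\tpvalue\tvariant_id",
             "r1\tA\tx\tnot_a_number\trs1"),
    dialect = "GWASDB"), "pvalue")
  ok <- read_association_table(
    text = c("record_id\tgene\tphenotype_text\tpvalue\tvariant_id",
             "r1\tA\tx\t3.2e-8\trs1"), dialect = "GWASDB")
  expect_equal(ok$records$pvalue, 3.2e-8)
  expect_identical(ok$records$variant_id, "rs1")
})

test_that("imported mappings link by exact case-folded text equality", {
  obo <- c("[Term]", "id: HP:0100753", "name: Schizophrenia")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text\tpvalue\tvariant_id",
    "g1\tCOMT\tSchizophrenia\t1e-5\trs1",
    "g2\tDRD2\tschizophrenia\t1e-6\trs2",
    "g3\tAPOE\tdementia\t1e-4\trs3"), dialect = "GWASDB")
  res <- import_mapping(text = "schizophrenia\tHP:0100753",
                        ontology = onto, table = tab)
  expect_identical(res$links$record_id, c("g1", "g2"))
  expect_identical(unique(res$links$provenance), "imported")
  expect_identical(nrow(res$skipped), 0L)
  # unknown concept id: no links, one skip entry
  res2 <- import_mapping(text = "dementia\tHP:9999999",
                         ontology = onto, table = tab)
  expect_identical(nrow(res2$links), 0L)
  expect_identical(res2$skipped$reason, "unknown concept")
  # empty mapping file
  res3 <- import_mapping(text = "", ontology = onto, table = tab)
  expect_identical(nrow(res3$links), 0L)
  expect_error(import_mapping(text = "only-one-field", ontology = onto,
                              table = tab), "malformed mapping line 1")
})

test_that("building merges tables, prefixes colliding ids and dedups links", {
  obo <- c("[Term]", "id: K:1", "name: alpha cond", "",
           "[Term]", "id: K:2", "name: beta cond")
  onto <- parse_obo(text = obo)
  gad <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text", "r1\tCOMT\talpha cond",
    "r2\tDRD2\tbeta cond"), dialect = "GAD")
  gw <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text\tpvalue\tvariant_id",
    "r1\tHTR2A\tx\t1e-5\trs1"), dialect = "GWASDB")
  l_gad <- map_labels(onto, gad)
  l_gw <- import_mapping(text = "x\tK:2", ontology = onto, table = gw)$links
  kb <- build_knowledgebase(onto, list(gad, gw), list(l_gad, l_gw))
  expect_setequal(kb$records$record_id, c("GAD:r1", "GWASDB:r1", "r2"))
  expect_setequal(kb$gene_universe, c("COMT", "DRD2", "HTR2A"))
  # links were rewritten through the same rename
  expect_true(all(kb$links$record_id %in% kb$records$record_id))
  expect_identical(
    kb$links$record_id[kb$links$provenance == "imported"], "GWASDB:r1")
  s <- summary(kb)
  expect_identical(s[["records"]], 3L)
  expect_identical(s[["links"]], 3L)
  expect_identical(s[["concepts_with_links"]], 2L)
})

test_that("duplicated (concept, record) pairs collapse to the union size", {
  obo <- c("[Term]", "id: K:1", "name: alpha cond")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text", "r1\tCOMT\talpha cond"),
    dialect = "GAD")
  dup <- data.frame(concept_id = "K:1", record_id = "r1",
                    provenance = "imported", stringsAsFactors = FALSE)
  kb <- build_knowledgebase(onto, list(tab),
                            list(map_labels(onto, tab), dup))
  expect_identical(nrow(kb$links), 1L)
})

test_that("building is invariant to the order of tables and linksets", {
  obo <- c("[Term]", "id: K:1", "name: alpha cond", "",
           "[Term]", "id: K:2", "name: beta cond")
  onto <- parse_obo(text = obo)
  gad <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text", "a1\tCOMT\talpha cond"),
    dialect = "GAD")
  gw <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text\tpvalue\tvariant_id",
    "b1\tDRD2\tbeta cond\t1e-5\trs1"), dialect = "GWASDB")
  l1 <- map_labels(onto, gad)
  l2 <- import_mapping(text = "beta cond\tK:2", ontology = onto,
                       table = gw)$links
  kb_a <- build_knowledgebase(onto, list(gad, gw), list(l1, l2))
  kb_b <- build_knowledgebase(onto, list(gw, gad), list(l2, l1))
  expect_identical(summary(kb_a), summary(kb_b))
  expect_identical(kb_a$links, kb_b$links)
  expect_identical(kb_a$gene_universe, kb_b$gene_universe)
})

test_that("integrity errors surface dangling links", {
  obo <- c("[Term]", "id: K:1", "name: alpha cond")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text", "r1\tCOMT\talpha cond"),
    dialect = "GAD")
  bad_rec <- data.frame(concept_id = "K:1", record_id = "ghost",
                        provenance = "matched", stringsAsFactors = FALSE)
  expect_error(build_knowledgebase(onto, list(tab), list(bad_rec)),
               "unknown record 'ghost'")
  bad_con <- data.frame(concept_id = "K:9", record_id = "r1",
                        provenance = "matched", stringsAsFactors = FALSE)
  expect_error(build_knowledgebase(onto, list(tab), list(bad_con)),
               "unknown concept 'K:9'")
})

test_that("SQLite persistence round-trips the whole data model", {
  set.seed(61)
  fx <- generate_fixture(fixture_params(
    n_concepts = 40, n_records_per_source = 80, universe = 100, seed = 9,
    planted = list(list(concept_ids = c("HP:0000002", "HP:0000003"),
                        genes = c("COMT", "HTR2A")))))
  kb <- fixture_kb(fx)
  path <- withr::local_tempfile(fileext = ".sqlite")
  persist_kb(kb, path)
  kb2 <- load_kb(path)
  expect_identical(summary(kb2), summary(kb))
  expect_identical(kb2$gene_universe, kb$gene_universe)
  expect_equal(kb2$records[order(kb2$records$record_id), ],
               kb$records[order(kb$records$record_id), ],
               ignore_attr = TRUE)
  expect_equal(kb2$links, kb$links, ignore_attr = TRUE)
  expect_identical(kb2$ontology$parents, kb$ontology$parents)
  expect_identical(kb2$ontology$children[order(names(kb2$ontology$children))],
                   kb$ontology$children[order(names(kb$ontology$children))])
  expect_identical(kb2$ontology$name, kb$ontology$name)
  expect_identical(sort(kb2$ontology$roots), sort(kb$ontology$roots))
  # link multiplicity preserved exactly
  expect_identical(nrow(kb2$links), nrow(kb$links))
})

test_that("loading a missing or alien file raises a storage error", {
  expect_error(load_kb(file.path(tempdir(), "nope-not-here.sqlite")),
               "no such knowledge-base")
  alien <- withr::local_tempfile(fileext = ".sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), alien)
  DBI::dbExecute(con, "CREATE TABLE misc (x TEXT)")
  DBI::dbDisconnect(con)
  expect_error(load_kb(alien), "missing table 'concept'")
})
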