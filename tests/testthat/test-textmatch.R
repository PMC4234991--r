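test_that("the banana suffix array matches the naive sort oracle", {
  idx <- build_suffix_array("banana")
  expect_identical(idx$sa, naive_suffix_order(idx$text))
  # restricted to in-document suffixes (dropping the sentinel suffix)
  in_doc <- idx$sa[idx$sa != nchar("banana")]
  expect_identical(in_doc, c(5L, 3L, 1L, 0L, 4L, 2L))
})

test_that("degenerate corpora build valid empty or one-character indexes", {
  idx0 <- build_suffix_array(character(0))
  expect_length(idx0$sa, 0)
  expect_identical(nrow(idx0$doc_bounds), 0L)
  idx1 <- build_suffix_array("a")
  expect_true(0L %in% idx1$sa)
  expect_identical(find_occurrences(idx1, "a"),
                   data.frame(doc_index = 0L, offset = 0L))
  expect_error(build_suffix_array("bad\x01doc"), "sentinel")
})

test_that("suffixes are in nondecreasing lexicographic order (invariant)", {
  set.seed(11)
  for (trial in 1:10) {
    docs <- random_corpus(sample(1:6, 1), 80)
    idx <- build_suffix_array(docs)
    expect_identical(idx$sa, naive_suffix_order(idx$text))
    # doc_bounds partition [0, nchar(text))
    expect_identical(idx$doc_bounds[1, "start"][[1]], 0L)
    expect_identical(idx$doc_bounds[nrow(idx$doc_bounds), "end"][[1]],
                     length(idx$ints))
    if (nrow(idx$doc_bounds) > 1)
      expect_identical(unname(idx$doc_bounds[-1, "start"]),
                       unname(idx$doc_bounds[-nrow(idx$doc_bounds), "end"]))
  }
})

test_that("pattern occurrences match a naive per-document scan", {
  idx <- build_suffix_array("banana")
  expect_identical(find_occurrences(idx, "ana"),
                   data.frame(doc_index = c(0L, 0L), offset = c(1L, 3L)))
  idx2 <- build_suffix_array(c("aba", "ba"))
  expect_identical(find_occurrences(idx2, "ba"),
                   data.frame(doc_index = c(0L, 1L), offset = c(1L, 0L)))
  expect_identical(nrow(find_occurrences(idx2, "abab")), 0L)
  expect_error(find_occurrences(idx2, ""), "nonempty")

  set.seed(21)
  for (trial in 1:25) {
    docs <- random_corpus(sample(1:8, 1), 120)
    idx <- build_suffix_array(docs)
    for (p in 1:10) {
      plen <- sample(1:6, 1)
      pat <- paste(sample(c("a", "c", "g", "t", " "), plen, replace = TRUE),
                   collapse = "")
      expect_identical(find_occurrences(idx, pat), naive_scan(docs, pat),
                       label = sprintf("trial %d pattern '%s'", trial, pat))
    }
  }
})

test_that("matching is case-insensitive in both label and description", {
  obo <- c("[Term]", "id: HP:0100753", "name: Schizophrenia")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text",
    "r1\tCOMT\tschizophrenia",
    "r2\tDRD2\tSCHIZOPHRENIA, chronic",
    "r3\tAPOE\talzheimer disease"), dialect = "GAD")
  links <- map_labels(onto, tab)
  expect_identical(links$record_id, c("r1", "r2"))
  expect_identical(unique(links$concept_id), "HP:0100753")
  expect_identical(unique(links$provenance), "matched")
})

test_that("short and stoplisted labels produce no links under the defaults", {
  obo <- c("[Term]", "id: L:1", "name: EO", "",
           "[Term]", "id: L:2", "name: ALS", "",
           "[Term]", "id: L:3", "name: age", "",
           "[Term]", "id: L:4", "name: CAD", "",
           "[Term]", "id: L:5", "name: asthma")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text",
    "r1\tG1\tearly onset EO forms",
    "r2\tG2\tage-related ALS with CAD",
    "r3\tG3\tasthma in children"), dialect = "GAD")
  links <- map_labels(onto, tab)
  expect_identical(links$concept_id, "L:5")
  expect_identical(links$record_id, "r3")
  # lowering the length floor and clearing the stoplist brings them back
  loose <- map_labels(onto, tab, match_config(min_label_length = 1,
                                              stoplist = character(0)))
  expect_true(all(c("L:1", "L:2", "L:3", "L:4") %in% loose$concept_id))
})

test_that("label mapping equals the quadratic containment oracle", {
  set.seed(31)
  syll <- c("ka", "lo", "mi", "ru", "tes", "val", "dor", "nix")
  for (trial in 1:20) {
    n_lab <- sample(3:12, 1)
    labels <- unique(vapply(seq_len(n_lab), function(i)
      paste(sample(syll, sample(1:3, 1), replace = TRUE), collapse = ""),
      character(1)))
    obo <- unlist(lapply(seq_along(labels), function(i)
      c("[Term]", sprintf("id: Q:%03d", i), paste0("name: ", labels[i]), "")))
    onto <- parse_obo(text = obo)
    n_doc <- sample(5:30, 1)
    docs <- vapply(seq_len(n_doc), function(i)
      paste(sample(c(labels, "study", "risk", "cohort"), sample(2:5, 1),
                   replace = TRUE), collapse = " "), character(1))
    tab <- read_association_table(text = c(
      "record_id\tgene\tphenotype_text",
      sprintf("r%03d\tG%03d\t%s", seq_len(n_doc), seq_len(n_doc), docs)),
      dialect = "GAD")
    got <- map_labels(onto, tab)
    attr(got, "source") <- NULL
    expect_identical(got, quadratic_links(onto, tab),
                     label = sprintf("trial %d", trial))
  }
})

test_that("links are invariant under row permutation and re-casing", {
  set.seed(41)
  obo <- c("[Term]", "id: P:1", "name: bulimia", "",
           "[Term]", "id: P:2", "name: psychosis")
  onto <- parse_obo(text = obo)
  rows <- c("r1\tCOMT\tbulimia nervosa", "r2\tHTR2A\tacute Psychosis",
            "r3\tSLC6A4\tBULIMIA with psychosis", "r4\tDRD2\tunrelated")
  base <- read_association_table(
    text = c("record_id\tgene\tphenotype_text", rows), dialect = "GAD")
  perm <- read_association_table(
    text = c("record_id\tgene\tphenotype_text", sample(rows)), dialect = "GAD")
  l1 <- map_labels(onto, base); l2 <- map_labels(onto, perm)
  expect_identical(l1, l2)
})

test_that("raising the minimum label length never adds links", {
  set.seed(51)
  obo <- c("[Term]", "id: M:1", "name: ab", "",
           "[Term]", "id: M:2", "name: abcd", "",
           "[Term]", "id: M:3", "name: abcdefgh")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text",
    "r1\tG1\txxabcdefghxx", "r2\tG2\tab only", "r3\tG3\tabcd here"),
    dialect = "GAD")
  prev <- NULL
  for (mll in 1:9) {
    links <- map_labels(onto, tab, match_config(min_label_length = mll,
                                                stoplist = character(0)))
    key <- paste(links$concept_id, links$record_id)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("synonym matching is off by default and on by config", {
  obo <- c("[Term]", "id: Y:1", "name: major depressive disorder",
           "synonym: \"unipolar depression\" EXACT []")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text",
    "r1\tSLC6A4\tunipolar depression cohort"), dialect = "GAD")
  expect_identical(nrow(map_labels(onto, tab)), 0L)
  with_syn <- map_labels(onto, tab, match_config(use_synonyms = TRUE))
  expect_identical(with_syn$record_id, "r1")
})

test_that("word-boundary mode drops matches embedded inside words", {
  obo <- c("[Term]", "id: W:1", "name: rash")
  onto <- parse_obo(text = obo)
  tab <- read_association_table(text = c(
    "record_id\tgene\tphenotype_text",
    "r1\tG1\tskin rash observed", "r2\tG2\tcrash and trashing",
    "r3\tG3\trash"), dialect = "GAD")
  substr_links <- map_labels(onto, tab)
  expect_setequal(substr_links$record_id, c("r1", "r2", "r3"))
  wb <- map_labels(onto, tab, match_config(word_boundary = TRUE))
  expect_setequal(wb$record_id, c("r1", "r3"))
})
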