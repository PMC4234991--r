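#' Parameters for the synthetic fixture generator
#'
#' Bundles the knobs of [generate_fixture()].  The defaults produce a small
#' corpus whose structure mirrors a real phenotype-association knowledge
#' base: a DAG-shaped ontology, one association table whose free-text
#' descriptions embed concept names (linked by text matching), a second
#' table whose descriptions carry no concept names and are linked through a
#' separate mapping file, and a fraction of associations that remain
#' unlinked.
#'
#' @param n_concepts Total concepts in the generated ontology (including the
#'   single root).
#' @param max_children Soft cap on the number of children per background
#'   concept.
#' @param n_phenotype_texts Number of distinct "noise" phenotype
#'   descriptions containing no concept name; records carrying them stay
#'   unlinked.
#' @param n_records_per_source Rows per association table (one GAD-style,
#'   one GWASdb-style).  Zero yields valid empty tables (and then no
#'   plantings are allowed).
#' @param universe Gene universe: either an integer size (symbols are
#'   generated) or a character vector of symbols.  Planted gene symbols are
#'   always included.
#' @param planted List of plantings; each element is a list with
#'   \code{concept_ids} (ids that must exist in the generated ontology and
#'   must not be the root) and \code{genes} (symbols every one of those
#'   concepts will share).  Concept ids follow the generated pattern
#'   \code{HP:0000001 .. HP:<n_concepts>}.
#' @param n_private_genes Private (unshared) genes given to every planted
#'   concept, so its descendant-closed gene set has size
#'   \code{length(genes) + n_private_genes}.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical outputs.
#' @return A list of class \code{"fixture_params"}.
#' @export
fixture_params <- function(n_concepts = 60L, max_children = 6L,
                           n_phenotype_texts = 20L,
                           n_records_per_source = 250L,
                           universe = 400L, planted = list(),
                           n_private_genes = 12L, seed = 1L) {
  p <- list(n_concepts = as.integer(n_concepts),
            max_children = as.integer(max_children),
            n_phenotype_texts = as.integer(n_phenotype_texts),
            n_records_per_source = as.integer(n_records_per_source),
            universe = universe, planted = planted,
            n_private_genes = as.integer(n_private_genes),
            seed = as.integer(seed))
  stopifnot(p$n_concepts >= 1L, p$max_children >= 1L,
            p$n_phenotype_texts >= 0L, p$n_records_per_source >= 0L,
            p$n_private_genes >= 0L)
  structure(p, class = "fixture_params")
}

.fx_id <- function(i) sprintf("HP:%07d", i)

# Collision-free concept names: fixed-length words of three
# consonant-vowel syllables indexed in base 100.  All names share one
# length, so none can be a proper substring of another, and the
# consonant-vowel structure keeps them out of English filler words.
.fx_names <- function(n) {
  cons <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n",
            "p", "r", "s", "t", "v", "w", "x", "z", "c", "q")
  vows <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vows, paste0))  # 100 syllables
  stopifnot(n <= length(syll)^3)
  i <- seq_len(n) - 1L
  word <- paste0(syll[(i %/% 10000L) %% 100L + 1L],
                 syll[(i %/% 100L) %% 100L + 1L],
                 syll[i %% 100L + 1L])
  paste0(toupper(substr(word, 1, 1)), substr(word, 2, nchar(word)),
         " phenotype")
}

#' Generate a synthetic ontology + association corpus with planted overlaps
#'
#' Emits OBO text, two association TSVs, a phenotype-to-concept mapping TSV
#' and a ground-truth record, so that the full pipeline (parse, text-match,
#' import mapping, build, intersect) is testable end to end without any
#' external data.
#'
#' The generated ontology is a DAG: concept 1 is the root; every planted
#' concept is a direct child of the root and owns one dedicated "carrier"
#' child (a fraction of its gene records attach to the carrier, so recovering
#' the planted genes requires descendant closure); all remaining concepts
#' form a random DAG under the root with 1-2 parents each, kept outside the
#' planted subtrees so planted gene sets are exact by construction.  Concept
#' names are equal-length words from a syllable alphabet, so no name is a
#' substring of another and text matching is collision-free.  GAD-style
#' descriptions embed concept names verbatim; GWASdb-style descriptions do
#' not, and are linked only through the emitted mapping file.
#'
#' @param params A [fixture_params()] object.
#' @return A list of class \code{"phenolink_fixture"} with elements
#'   \code{obo}, \code{gad_tsv}, \code{gwasdb_tsv}, \code{mapping_tsv}
#'   (character vectors of lines) and \code{truth}, a list with
#'   \code{planted}, \code{expected_links} (data.frame concept_id,
#'   record_id, provenance), \code{per_concept_expected_genes} (named list,
#'   planted concepts only), \code{universe} and \code{concept_names}.
#' @export
generate_fixture <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  n <- params$n_concepts
  ids <- .fx_id(seq_len(n))
  nms <- .fx_names(n)
  root <- ids[1]

  planted <- params$planted
  focal <- unique(unlist(lapply(planted, `[[`, "concept_ids"),
                         use.names = FALSE))
  if (length(focal)) {
    if (params$n_records_per_source == 0L)
      stop("plantings require n_records_per_source > 0")
    bad <- setdiff(focal, ids)
    if (length(bad))
      stop(sprintf("planted concept id '%s' not in the generated ontology",
                   bad[1]))
    if (root %in% focal) stop("the root concept cannot be planted")
  }
  avail <- setdiff(ids[-1], focal)
  if (length(avail) < length(focal))
    stop("n_concepts too small to give every planted concept a carrier child")
  carrier <- stats::setNames(avail[seq_along(focal)], focal)
  background <- setdiff(avail, unname(carrier))

  # parent lists
  parents <- stats::setNames(
    replicate(n, character(0), simplify = FALSE), ids)
  for (f in focal) parents[[f]] <- root
  for (f in focal) parents[[carrier[[f]]]] <- f
  n_children <- stats::setNames(integer(n), ids)
  bg_pool <- root  # candidate parents for background concepts, in id order
  for (b in background) {
    open <- bg_pool[n_children[bg_pool] < params$max_children]
    if (!length(open)) open <- root
    k <- min(length(open), sample(1:2, 1))
    ps <- sample(open, k)
    parents[[b]] <- sort(ps)
    n_children[ps] <- n_children[ps] + 1L
    bg_pool <- c(bg_pool, b)
  }

  obo <- character(0)
  for (i in seq_len(n)) {
    obo <- c(obo, "[Term]", paste0("id: ", ids[i]), paste0("name: ", nms[i]))
    for (p in parents[[ids[i]]])
      obo <- c(obo, paste0("is_a: ", p, " ! ", nms[match(p, ids)]))
    obo <- c(obo, "")
  }

  # gene universe
  planted_genes <- unique(unlist(lapply(planted, `[[`, "genes"),
                                 use.names = FALSE))
  if (is.numeric(params$universe)) {
    U <- as.integer(params$universe)
    stopifnot(U >= length(planted_genes))
    universe <- sprintf("GN%05d", seq_len(U))
    universe[seq_along(planted_genes)] <- planted_genes
  } else {
    universe <- unique(toupper(as.character(params$universe)))
    missing <- setdiff(planted_genes, universe)
    if (length(missing))
      stop(sprintf("planted gene '%s' is not in the supplied universe",
                   missing[1]))
  }

  # per-focal gene sets: shared planted genes + disjoint private genes
  pool <- setdiff(universe, planted_genes)
  focal_genes <- list()
  for (f in focal) {
    shared <- unique(unlist(lapply(planted, function(g)
      if (f %in% g$concept_ids) g$genes else NULL), use.names = FALSE))
    if (params$n_private_genes > length(pool))
      stop("gene universe too small for the requested private genes")
    priv <- if (params$n_private_genes)
      sample(pool, params$n_private_genes) else character(0)
    pool <- setdiff(pool, priv)
    focal_genes[[f]] <- c(shared, priv)
  }

  gad_text <- stats::setNames(
    sprintf("study of %s risk in adults", tolower(nms)), ids)
  gw_text <- stats::setNames(sprintf("trait profile %d", seq_len(n)), ids)

  # record accumulation: target concept NA_character_ means "unlinked"
  gad_rows <- list(); gw_rows <- list()
  add_row <- function(src, gene, target) {
    row <- list(gene = gene, target = target)
    if (src == "GAD") gad_rows[[length(gad_rows) + 1L]] <<- row
    else gw_rows[[length(gw_rows) + 1L]] <<- row
  }

  for (f in focal) {
    genes <- focal_genes[[f]]
    for (i in seq_along(genes)) {
      target <- if (i %% 2L == 0L) carrier[[f]] else f
      src <- if (i %% 4L %in% c(0L, 1L)) "GAD" else "GWASDB"
      add_row(src, genes[i], target)
    }
  }

  # coverage: every remaining universe gene appears in at least one record
  used <- unique(unlist(focal_genes, use.names = FALSE))
  remaining <- setdiff(universe, used)
  link_targets <- if (length(background)) background else root
  for (i in seq_along(remaining)) {
    src <- if (i %% 2L == 0L) "GAD" else "GWASDB"
    add_row(src, remaining[i],
            link_targets[(i %% length(link_targets)) + 1L])
  }

  noise_texts <- if (params$n_phenotype_texts > 0L)
    sprintf("unmapped condition cluster %d", seq_len(params$n_phenotype_texts))
  else character(0)

  target_n <- params$n_records_per_source
  if (target_n > 0L) {
    if (length(gad_rows) > target_n || length(gw_rows) > target_n)
      stop(sprintf(paste0("n_records_per_source = %d is too small: the ",
                          "plantings and universe coverage need %d GAD and ",
                          "%d GWASdb rows"),
                   target_n, length(gad_rows), length(gw_rows)))
    # pad with unlinked noise records reusing random universe genes
    while (length(gad_rows) < target_n)
      add_row("GAD", sample(universe, 1), NA_character_)
    while (length(gw_rows) < target_n)
      add_row("GWASDB", sample(universe, 1), NA_character_)
  } else {
    gad_rows <- list(); gw_rows <- list()
  }

  fmt_rows <- function(rows, src) {
    if (!length(rows)) return(list(tsv = character(0), links = NULL))
    gene <- vapply(rows, `[[`, "", "gene")
    target <- vapply(rows, function(r)
      if (is.na(r$target)) NA_character_ else r$target, "")
    rid <- sprintf("%s%05d", if (src == "GAD") "gad" else "gw",
                   seq_along(rows))
    if (src == "GAD") {
      txt <- ifelse(is.na(target),
                    if (length(noise_texts))
                      noise_texts[(seq_along(rows) %% max(1L, length(noise_texts))) + 1L]
                    else "unmapped condition",
                    gad_text[target])
      tsv <- paste(rid, gene, txt, sep = "\t")
      prov <- "matched"
    } else {
      txt <- ifelse(is.na(target),
                    if (length(noise_texts))
                      noise_texts[(seq_along(rows) %% max(1L, length(noise_texts))) + 1L]
                    else "unmapped condition",
                    gw_text[target])
      pv <- sprintf("%.3g", round(stats::runif(length(rows), 1e-8, 1e-3), 10))
      var <- sprintf("rs%06d", sample.int(999999L, length(rows), replace = TRUE))
      tsv <- paste(rid, gene, txt, pv, var, sep = "\t")
      prov <- "imported"
    }
    ok <- !is.na(target)
    links <- data.frame(concept_id = target[ok], record_id = rid[ok],
                        provenance = prov, stringsAsFactors = FALSE)
    list(tsv = tsv, links = links)
  }
  gad <- fmt_rows(gad_rows, "GAD")
  gw <- fmt_rows(gw_rows, "GWASDB")
  gad_tsv <- c("record_id\tgene\tphenotype_text", gad$tsv)
  gw_tsv <- c("record_id\tgene\tphenotype_text\tpvalue\tvariant_id", gw$tsv)

  mapped_concepts <- sort(unique(gw$links$concept_id))
  mapping_tsv <- if (length(mapped_concepts))
    paste(gw_text[mapped_concepts], mapped_concepts, sep = "\t")
  else character(0)

  expected_links <- rbind(gad$links, gw$links)
  if (is.null(expected_links))
    expected_links <- data.frame(concept_id = character(0),
                                 record_id = character(0),
                                 provenance = character(0),
                                 stringsAsFactors = FALSE)
  expected_links <- expected_links[order(expected_links$concept_id,
                                         expected_links$record_id,
                                         method = "radix"), , drop = FALSE]
  row.names(expected_links) <- NULL

  per_expected <- lapply(focal, function(f) sort(focal_genes[[f]]))
  names(per_expected) <- focal

  structure(list(
    obo = obo, gad_tsv = gad_tsv, gwasdb_tsv = gw_tsv,
    mapping_tsv = mapping_tsv,
    truth = list(planted = planted, expected_links = expected_links,
                 per_concept_expected_genes = per_expected,
                 universe = universe,
                 concept_names = stats::setNames(nms, ids),
                 carrier = carrier)),
    class = "phenolink_fixture")
}

#' Write a generated fixture to a directory
#'
#' @param fixture A \code{"phenolink_fixture"} from [generate_fixture()].
#' @param dir Output directory (created if needed).  Writes
#'   \code{ontology.obo}, \code{gad.tsv}, \code{gwasdb.tsv} and
#'   \code{mapping.tsv}.
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "phenolink_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(fixture$obo, file.path(dir, "ontology.obo"))
  writeLines(fixture$gad_tsv, file.path(dir, "gad.tsv"))
  writeLines(fixture$gwasdb_tsv, file.path(dir, "gwasdb.tsv"))
  writeLines(fixture$mapping_tsv, file.path(dir, "mapping.tsv"))
  invisible(dir)
}

#' Build a knowledge base directly from a generated fixture
#'
#' Convenience wrapper running the full pipeline in memory: parse the OBO
#' text, read both association tables, text-match GAD-style descriptions,
#' import the GWASdb-style mapping, and assemble the knowledge base.
#'
#' @param fixture A \code{"phenolink_fixture"}.
#' @param config A [match_config()] for the text-matching step.
#' @return A \code{"knowledgebase"}.
#' @export
fixture_kb <- function(fixture, config = match_config()) {
  stopifnot(inherits(fixture, "phenolink_fixture"))
  onto <- parse_obo(text = fixture$obo)
  gad <- read_association_table(text = fixture$gad_tsv, dialect = "GAD")
  gw <- read_association_table(text = fixture$gwasdb_tsv, dialect = "GWASDB")
  matched <- map_labels(onto, gad, config)
  imported <- import_mapping(text = fixture$mapping_tsv, ontology = onto,
                             table = gw)$links
  build_knowledgebase(onto, list(gad, gw), list(matched, imported))
}
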