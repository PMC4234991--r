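ASSOC_SOURCES <- c("GAD", "GWASDB", "OTHER")

#' Read a genetic-association table from TSV
#'
#' Two tab-separated dialects are supported, both with a mandatory header
#' line, UTF-8, and no quoting.  The \code{GAD} dialect (rows carrying
#' free-text phenotype descriptions) requires columns \code{record_id},
#' \code{gene}, \code{phenotype_text}.  The \code{GWASDB} dialect
#' additionally requires \code{pvalue} and \code{variant_id}.  Extra columns
#' are ignored.  Gene symbols are whitespace-trimmed and uppercased; rows
#' with an empty gene or phenotype description are dropped with a counted
#' warning.  P-values may be decimal or scientific notation and must lie in
#' (0, 1].
#'
#' A historical association dump with differently named columns can be
#' adapted by renaming its header to this column map.
#'
#' @param file Path to a TSV file.  Ignored when \code{text} is given.
#' @param text Character scalar or vector holding TSV content directly.
#' @param dialect \code{"GAD"} or \code{"GWASDB"}.
#' @return An object of class \code{"association_table"}: list with
#'   \code{records} (data.frame with columns \code{record_id}, \code{gene},
#'   \code{phenotype_text}, \code{source}, \code{pvalue}, \code{variant_id}),
#'   \code{source}, and \code{n_dropped} (rows removed by the empty-field
#'   filter).
#' @export
read_association_table <- function(file = NULL, text = NULL,
                                   dialect = c("GAD", "GWASDB")) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be given")
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("association table is empty (no header line)")

  required <- c("record_id", "gene", "phenotype_text")
  if (dialect == "GWASDB") required <- c(required, "pvalue", "variant_id")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  for (col in required)
    if (!col %in% header)
      stop(sprintf("missing required column '%s' for dialect %s", col, dialect))

  n <- length(lines) - 1L
  get_col <- function(fields, col) {
    i <- match(col, header)
    vapply(fields, function(f) if (length(f) >= i) f[i] else "", character(1))
  }
  if (n > 0L) {
    fields <- strsplit(lines[-1], "\t", fixed = TRUE)
    record_id <- trimws(get_col(fields, "record_id"))
    gene <- toupper(trimws(get_col(fields, "gene")))
    phenotype_text <- trimws(get_col(fields, "phenotype_text"))
    if ("pvalue" %in% header) {
      raw_p <- trimws(get_col(fields, "pvalue"))
      pvalue <- suppressWarnings(as.numeric(raw_p))
      bad <- nzchar(raw_p) & (is.na(pvalue) | pvalue <= 0 | pvalue > 1)
      if (any(bad))
        stop(sprintf("unparsable or out-of-range pvalue '%s' at data row %d",
                     raw_p[which(bad)[1]], which(bad)[1]))
    } else pvalue <- rep(NA_real_, n)
    variant_id <- if ("variant_id" %in% header)
      trimws(get_col(fields, "variant_id")) else rep(NA_character_, n)
    variant_id[!nzchar(variant_id) | is.na(variant_id)] <- NA_character_
  } else {
    record_id <- gene <- phenotype_text <- character(0)
    pvalue <- numeric(0); variant_id <- character(0)
  }

  keep <- nzchar(gene) & nzchar(phenotype_text)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(sprintf("dropped %d row(s) with empty gene or phenotype_text",
                    n_dropped))
  records <- data.frame(record_id = record_id[keep], gene = gene[keep],
                        phenotype_text = phenotype_text[keep],
                        source = rep(dialect, sum(keep)),
                        pvalue = pvalue[keep], variant_id = variant_id[keep],
                        stringsAsFactors = FALSE)
  dup <- duplicated(records$record_id)
  if (any(dup))
    stop(sprintf("duplicate record_id '%s'", records$record_id[which(dup)[1]]))
  structure(list(records = records, source = dialect, n_dropped = n_dropped),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association table [%s]: %d records (%d rows dropped)\n",
              x$source, nrow(x$records), x$n_dropped))
  invisible(x)
}

#' Import a precomputed phenotype-to-concept mapping
#'
#' Reads a two-column TSV of \code{(phenotype_key, concept_id)} pairs, such
#' as the published trait-to-ontology mapping distributed with GWAS
#' association catalogues, and links every record whose phenotype description
#' equals a key (case-folded exact equality) to the mapped concept.  Keys
#' matching no record and concept ids absent from the ontology are collected
#' into a skip report rather than raising an error.
#'
#' @param file Path to the mapping TSV (no header).  Ignored when
#'   \code{text} is given.
#' @param text Character scalar/vector holding the TSV content.
#' @param ontology An \code{"ontology"} object.
#' @param table An \code{"association_table"}.
#' @return A list with \code{links} (data.frame \code{concept_id},
#'   \code{record_id}, \code{provenance = "imported"}) and \code{skipped}
#'   (data.frame \code{phenotype_key}, \code{concept_id}, \code{reason}).
#' @export
import_mapping <- function(file = NULL, text = NULL, ontology, table) {
  stopifnot(inherits(ontology, "ontology"), inherits(table, "association_table"))
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be given")
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]

  empty_links <- data.frame(concept_id = character(0),
                            record_id = character(0),
                            provenance = character(0), stringsAsFactors = FALSE)
  skipped <- data.frame(phenotype_key = character(0), concept_id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(list(links = empty_links, skipped = skipped))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad))
    stop(sprintf("malformed mapping line %d: expected 2 tab-separated fields",
                 bad[1]))
  key <- tolower(trimws(vapply(fields, `[`, "", 1L)))
  cid <- trimws(vapply(fields, `[`, "", 2L))

  rec_text <- tolower(table$records$phenotype_text)
  links <- empty_links
  live <- ontology$ids[!ontology$obsolete[ontology$ids]]
  for (i in seq_along(key)) {
    if (!cid[i] %in% live) {
      skipped <- rbind(skipped, data.frame(
        phenotype_key = key[i], concept_id = cid[i],
        reason = if (cid[i] %in% ontology$ids) "obsolete concept"
                 else "unknown concept", stringsAsFactors = FALSE))
      next
    }
    recs <- table$records$record_id[rec_text == key[i]]
    if (!length(recs)) {
      skipped <- rbind(skipped, data.frame(
        phenotype_key = key[i], concept_id = cid[i],
        reason = "no matching record", stringsAsFactors = FALSE))
      next
    }
    links <- rbind(links, data.frame(
      concept_id = cid[i], record_id = recs,
      provenance = "imported", stringsAsFactors = FALSE))
  }
  links <- unique(links)
  row.names(links) <- NULL
  attr(links, "source") <- table$source
  list(links = links, skipped = skipped)
}

#' Assemble a knowledge base from ontology, tables and link sets
#'
#' Merges association tables (a record_id occurring in more than one source
#' is disambiguated by prefixing the source name, e.g. \code{"GAD:r1"}; links
#' referring to it are rewritten accordingly), unions the link sets with
#' (concept, record) pair deduplication, and computes the gene universe as
#' the set of all distinct gene symbols in the merged records.
#'
#' @param ontology An \code{"ontology"} object.
#' @param tables List of \code{"association_table"} objects.
#' @param linksets List of link data.frames (columns \code{concept_id},
#'   \code{record_id}, \code{provenance}), in the same order as the tables
#'   they were derived from; a link set derived from table \code{i} must be
#'   passed as element \code{i} (or tagged with \code{source} attribute) so
#'   record-id rewriting can be applied.  Link sets may also be the
#'   \code{links} element of [import_mapping()] output.
#' @return An object of class \code{"knowledgebase"}: list with
#'   \code{ontology}, \code{records} (merged data.frame keyed by unique
#'   \code{record_id}), \code{links} (deduplicated data.frame), and
#'   \code{gene_universe} (sorted character vector).
#' @export
build_knowledgebase <- function(ontology, tables, linksets = list()) {
  stopifnot(inherits(ontology, "ontology"))
  if (inherits(tables, "association_table")) tables <- list(tables)
  if (is.data.frame(linksets)) linksets <- list(linksets)
  for (t in tables) stopifnot(inherits(t, "association_table"))

  all_ids <- unlist(lapply(tables, function(t) t$records$record_id),
                    use.names = FALSE)
  collide <- unique(all_ids[duplicated(all_ids)])

  rename_one <- function(t) {
    r <- t$records
    hit <- r$record_id %in% collide
    map <- stats::setNames(r$record_id, r$record_id)
    map[hit] <- paste0(t$source, ":", r$record_id[hit])
    r$record_id <- unname(map[r$record_id])
    list(records = r, map = map, source = t$source)
  }
  renamed <- lapply(tables, rename_one)
  records <- do.call(rbind, c(lapply(renamed, `[[`, "records"),
                              list(make.row.names = FALSE)))
  if (is.null(records))
    records <- data.frame(record_id = character(0), gene = character(0),
                          phenotype_text = character(0), source = character(0),
                          pvalue = numeric(0), variant_id = character(0),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(records$record_id))
    stop("record_id collision within a single source after merge")

  # rewrite link record ids through the same per-source rename maps
  fix_links <- function(ls, i) {
    if (!nrow(ls)) return(ls)
    if (length(renamed) && length(collide)) {
      src <- attr(ls, "source")
      maps <- if (!is.null(src))
        renamed[vapply(renamed, `[[`, "", "source") == src] else renamed
      for (m in maps) {
        hit <- ls$record_id %in% names(m$map)
        ls$record_id[hit] <- unname(m$map[ls$record_id[hit]])
      }
    }
    ls
  }
  links <- do.call(rbind, c(lapply(seq_along(linksets), function(i)
    fix_links(linksets[[i]], i)), list(make.row.names = FALSE)))
  if (is.null(links))
    links <- data.frame(concept_id = character(0), record_id = character(0),
                        provenance = character(0), stringsAsFactors = FALSE)
  links <- unique(links[, c("concept_id", "record_id", "provenance")])
  # a pair carried by both provenances collapses to one link (matched wins ties
  # deterministically by sort order)
  links <- links[order(links$concept_id, links$record_id, links$provenance,
                       method = "radix"), , drop = FALSE]
  links <- links[!duplicated(links[, c("concept_id", "record_id")]), ,
                 drop = FALSE]
  row.names(links) <- NULL

  bad_rec <- setdiff(links$record_id, records$record_id)
  if (length(bad_rec))
    stop(sprintf("link references unknown record '%s'", bad_rec[1]))
  bad_con <- setdiff(links$concept_id, ontology$ids)
  if (length(bad_con))
    stop(sprintf("link references unknown concept '%s'", bad_con[1]))

  structure(list(ontology = ontology, records = records, links = links,
                 gene_universe = sort(unique(records$gene))),
            class = "knowledgebase")
}

#' Summary counts of a knowledge base
#'
#' @param object A \code{"knowledgebase"}.
#' @param ... Unused.
#' @return Named integer vector: concepts, obsolete concepts, records, links,
#'   genes, and concepts that carry at least one link.
#' @export
summary.knowledgebase <- function(object, ...) {
  c(concepts = length(object$ontology$ids),
    obsolete_concepts = sum(object$ontology$obsolete),
    records = nrow(object$records),
    links = nrow(object$links),
    genes = length(object$gene_universe),
    concepts_with_links = length(unique(object$links$concept_id)))
}

#' @export
print.knowledgebase <- function(x, ...) {
  s <- summary(x)
  cat("Phenotype-association knowledge base\n")
  cat(sprintf("  concepts:            %d (%d obsolete)\n",
              s[["concepts"]], s[["obsolete_concepts"]]))
  cat(sprintf("  association records: %d\n", s[["records"]]))
  cat(sprintf("  links:               %d\n", s[["links"]]))
  cat(sprintf("  genes:               %d\n", s[["genes"]]))
  cat(sprintf("  concepts with links: %d\n", s[["concepts_with_links"]]))
  invisible(x)
}

KB_TABLES <- c("concept", "concept_parent", "synonym", "association", "link",
               "meta")

#' Persist a knowledge base to SQLite
#'
#' Writes the knowledge base to a single-file SQLite database with tables
#' \code{concept(id, name, obsolete)}, \code{concept_parent(child, parent)},
#' \code{synonym(concept, label)}, \code{association(record_id, gene,
#' phenotype_text, source, pvalue, variant_id)}, \code{link(concept,
#' record_id, provenance)} and \code{meta(key, value)}.
#' \code{load_kb(persist_kb(kb, path))} is the identity on the data model.
#'
#' @param kb A \code{"knowledgebase"}.
#' @param path File path to write (overwritten if present).
#' @return \code{path}, invisibly.
#' @export
persist_kb <- function(kb, path) {
  stopifnot(inherits(kb, "knowledgebase"))
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE concept (
      id TEXT PRIMARY KEY, name TEXT, obsolete INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE concept_parent (child TEXT, parent TEXT)")
  DBI::dbExecute(con, "CREATE TABLE synonym (concept TEXT, label TEXT)")
  DBI::dbExecute(con, "CREATE TABLE association (
      record_id TEXT PRIMARY KEY, gene TEXT, phenotype_text TEXT,
      source TEXT, pvalue REAL NULL, variant_id TEXT NULL)")
  DBI::dbExecute(con, "CREATE TABLE link (
      concept TEXT, record_id TEXT, provenance TEXT,
      UNIQUE(concept, record_id))")
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT, value TEXT)")

  o <- kb$ontology
  DBI::dbWriteTable(con, "concept", data.frame(
    id = o$ids, name = unname(o$name[o$ids]),
    obsolete = as.integer(o$obsolete[o$ids]), stringsAsFactors = FALSE),
    append = TRUE)
  par_child <- rep(o$ids, vapply(o$parents[o$ids], length, 0L))
  if (length(par_child))
    DBI::dbWriteTable(con, "concept_parent", data.frame(
      child = par_child,
      parent = unlist(o$parents[o$ids], use.names = FALSE),
      stringsAsFactors = FALSE), append = TRUE)
  syn_c <- rep(o$ids, vapply(o$synonyms[o$ids], length, 0L))
  if (length(syn_c))
    DBI::dbWriteTable(con, "synonym", data.frame(
      concept = syn_c, label = unlist(o$synonyms[o$ids], use.names = FALSE),
      stringsAsFactors = FALSE), append = TRUE)
  DBI::dbWriteTable(con, "association", kb$records, append = TRUE)
  if (nrow(kb$links))
    DBI::dbWriteTable(con, "link", stats::setNames(
      kb$links, c("concept", "record_id", "provenance")), append = TRUE)
  DBI::dbWriteTable(con, "meta", data.frame(
    key = c("format", "format_version"),
    value = c("phenolink-kb", "1"), stringsAsFactors = FALSE), append = TRUE)
  invisible(path)
}

#' Load a knowledge base from SQLite
#'
#' @param path Path to a file written by [persist_kb()].
#' @return A \code{"knowledgebase"} equal to the persisted one on all fields.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such knowledge-base file: %s", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  have <- DBI::dbListTables(con)
  missing <- setdiff(KB_TABLES, have)
  if (length(missing))
    stop(sprintf("not a knowledge-base file: missing table '%s'", missing[1]))

  concept <- DBI::dbReadTable(con, "concept")
  cp <- DBI::dbReadTable(con, "concept_parent")
  syn <- DBI::dbReadTable(con, "synonym")
  records <- DBI::dbReadTable(con, "association")
  link <- DBI::dbReadTable(con, "link")

  ids <- concept$id
  parents <- stats::setNames(
    replicate(length(ids), character(0), simplify = FALSE), ids)
  if (nrow(cp)) {
    sp <- split(cp$parent, factor(cp$child, levels = ids))
    for (id in ids) parents[[id]] <- as.character(sp[[id]])
  }
  synonyms <- stats::setNames(
    replicate(length(ids), character(0), simplify = FALSE), ids)
  if (nrow(syn)) {
    ss <- split(syn$label, factor(syn$concept, levels = ids))
    for (id in ids) synonyms[[id]] <- as.character(ss[[id]])
  }
  children <- stats::setNames(
    replicate(length(ids), character(0), simplify = FALSE), ids)
  for (id in ids) for (p in parents[[id]])
    children[[p]] <- c(children[[p]], id)
  obsolete <- stats::setNames(concept$obsolete == 1L, ids)
  live <- ids[!obsolete[ids]]
  onto <- structure(list(
    ids = ids, name = stats::setNames(concept$name, ids),
    synonyms = synonyms, parents = parents, children = children,
    obsolete = obsolete,
    roots = live[vapply(parents[live], length, 0L) == 0L]),
    class = "ontology")

  links <- data.frame(concept_id = link$concept, record_id = link$record_id,
                      provenance = link$provenance, stringsAsFactors = FALSE)
  links <- links[order(links$concept_id, links$record_id, method = "radix"),
                 , drop = FALSE]
  row.names(links) <- NULL
  structure(list(ontology = onto, records = records, links = links,
                 gene_universe = sort(unique(records$gene))),
            class = "knowledgebase")
}
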