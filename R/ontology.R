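#' Parse an OBO flat file into a phenotype ontology
#'
#' Reads OBO 1.2-style flat text and returns a directed acyclic graph of
#' concepts.  Only \code{[Term]} stanzas are interpreted, and within them only
#' the keys \code{id}, \code{name}, \code{synonym}, \code{is_a} and
#' \code{is_obsolete}; every other stanza and key is ignored.  Trailing
#' \code{! comment} text on \code{is_a} lines is stripped.  Obsolete terms are
#' recorded but excluded from navigation, search and downstream linking.
#'
#' @param file Path to an OBO file (or a connection).  Ignored when
#'   \code{text} is given.
#' @param text Character vector holding OBO text directly, either as one
#'   string or as lines.
#' @return An object of class \code{"ontology"}: a list with elements
#'   \describe{
#'     \item{ids}{character vector of all term ids, in file order}
#'     \item{name}{named character vector, id -> display label}
#'     \item{synonyms}{named list, id -> character vector of synonym strings}
#'     \item{parents}{named list, id -> character vector of parent ids}
#'     \item{children}{named list, id -> character vector of child ids
#'       (exact inverse of \code{parents})}
#'     \item{obsolete}{named logical vector}
#'     \item{roots}{ids of non-obsolete concepts with no parents}
#'   }
#' @details Errors are raised for duplicate term ids, \code{is_a} targets not
#'   defined anywhere in the file, and cycles in the parent graph (the message
#'   lists one offending path).  Edges from or to obsolete terms are dropped.
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All",
#'          "[Term]", "id: HP:0003540", "name: Platelet aggregation defect",
#'          "is_a: HP:0000001 ! All")
#' onto <- parse_obo(text = obo)
#' onto$name[["HP:0003540"]]
#' @export
parse_obo <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be given")
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)

  # split into stanzas; interpret [Term] only
  stanza_start <- grepl("^\\[.+\\]\\s*$", lines)
  stanza_id <- cumsum(stanza_start)
  term_ids <- character(0)
  name <- character(0)
  synonyms <- list()
  parents <- list()
  obsolete <- logical(0)

  if (any(stanza_start)) {
    headers <- trimws(lines[stanza_start])
    for (s in seq_len(max(stanza_id))) {
      if (headers[s] != "[Term]") next
      body <- lines[stanza_id == s & !stanza_start]
      kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
      keys <- vapply(kv, function(m) if (length(m)) m[2] else NA_character_,
                     character(1))
      vals <- vapply(kv, function(m) if (length(m)) m[3] else NA_character_,
                     character(1))
      id <- vals[which(keys == "id")[1]]
      if (is.na(id) || !nzchar(trimws(id))) next
      id <- trimws(id)
      if (id %in% term_ids)
        stop(sprintf("duplicate term id '%s' in OBO input", id))
      term_ids <- c(term_ids, id)
      nm <- vals[which(keys == "name")[1]]
      name[id] <- if (is.na(nm)) "" else trimws(nm)
      syn_vals <- vals[keys == "synonym" & !is.na(keys)]
      # the synonym value is the quoted string portion of the line
      syn <- regmatches(syn_vals, regexec("\"([^\"]*)\"", syn_vals))
      synonyms[[id]] <- unique(vapply(
        syn, function(m) if (length(m) == 2) m[2] else NA_character_,
        character(1)))
      synonyms[[id]] <- synonyms[[id]][!is.na(synonyms[[id]]) &
                                         nzchar(synonyms[[id]])]
      isa_vals <- vals[keys == "is_a" & !is.na(keys)]
      isa <- trimws(sub("!.*$", "", isa_vals))
      isa <- unique(isa[nzchar(isa) & isa != id])
      parents[[id]] <- isa
      obs <- vals[which(keys == "is_obsolete")[1]]
      obsolete[id] <- !is.na(obs) && trimws(obs) == "true"
    }
  }

  # dangling is_a targets
  for (id in term_ids) {
    missing <- setdiff(parents[[id]], term_ids)
    if (length(missing))
      stop(sprintf("is_a target '%s' of term '%s' is not defined in the file",
                   missing[1], id))
  }

  # drop edges touching obsolete terms; obsolete terms keep no parents
  for (id in term_ids) {
    if (obsolete[id]) parents[[id]] <- character(0)
    else parents[[id]] <- parents[[id]][!obsolete[parents[[id]]]]
  }

  children <- stats::setNames(
    replicate(length(term_ids), character(0), simplify = FALSE), term_ids)
  for (id in term_ids)
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)

  onto <- structure(list(
    ids = term_ids, name = name, synonyms = synonyms,
    parents = parents, children = children, obsolete = obsolete,
    roots = character(0)), class = "ontology")
  .check_acyclic(onto)
  live <- term_ids[!obsolete[term_ids]]
  onto$roots <- live[vapply(parents[live], length, 0L) == 0L]
  onto
}

# Kahn topological check; on failure walks parent edges to exhibit one cycle.
.check_acyclic <- function(onto) {
  ids <- onto$ids
  if (!length(ids)) return(invisible(TRUE))
  indeg <- vapply(onto$parents[ids], length, 0L)  # edges child -> parent
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg <- stats::setNames(indeg, ids)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in onto$children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    start <- ids[indeg > 0L][1]
    path <- start; v <- start
    repeat {
      v <- intersect(onto$parents[[v]], ids[indeg > 0L])[1]
      if (v %in% path) {
        path <- c(path[which(path == v)[1]:length(path)], v)
        stop(sprintf("cycle detected in is_a graph: %s",
                     paste(path, collapse = " -> ")))
      }
      path <- c(path, v)
    }
  }
  invisible(TRUE)
}

.check_concept <- function(ontology, concept_id, allow_obsolete = FALSE) {
  stopifnot(inherits(ontology, "ontology"))
  if (length(concept_id) != 1L || !concept_id %in% ontology$ids)
    stop(sprintf("unknown concept id '%s'", paste(concept_id, collapse = ",")))
  if (!allow_obsolete && ontology$obsolete[[concept_id]])
    stop(sprintf("concept '%s' is obsolete", concept_id))
  invisible(concept_id)
}

.reach <- function(adj, start) {
  out <- character(0)
  frontier <- adj[[start]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
  }
  setdiff(out, start)
}

#' Descendants of a concept
#'
#' All concept ids reachable from \code{concept_id} by following child edges,
#' excluding the concept itself.  Concepts reachable along several paths in
#' the DAG are counted once.
#'
#' @param ontology An \code{"ontology"} object from [parse_obo()].
#' @param concept_id A single concept accession present in the ontology
#'   (non-obsolete).
#' @return Character vector of descendant ids (unordered set; deduplicated).
#' @seealso [ancestors()], [search_concepts()]
#' @export
descendants <- function(ontology, concept_id) {
  .check_concept(ontology, concept_id)
  .reach(ontology$children, concept_id)
}

#' Ancestors of a concept
#'
#' All concept ids reachable from \code{concept_id} by following parent
#' (\code{is_a}) edges, excluding the concept itself.  For any non-root
#' concept the result contains at least one root.
#'
#' @inheritParams descendants
#' @return Character vector of ancestor ids (unordered set; deduplicated).
#' @export
ancestors <- function(ontology, concept_id) {
  .check_concept(ontology, concept_id, allow_obsolete = TRUE)
  .reach(ontology$parents, concept_id)
}

#' Substring search over concept names and synonyms
#'
#' Returns every non-obsolete concept whose name or any synonym contains the
#' query case-insensitively.  Results are ordered by name length (shortest,
#' i.e. most specific match, first) and then by id, so the ordering is
#' deterministic.
#'
#' @inheritParams descendants
#' @param query A nonempty string (leading/trailing whitespace is trimmed; an
#'   empty or whitespace-only query is an error, never "match everything").
#' @return A data.frame with columns \code{id} and \code{name}, possibly with
#'   zero rows.
#' @export
search_concepts <- function(ontology, query) {
  stopifnot(inherits(ontology, "ontology"))
  query <- trimws(query)
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("query must be a single nonempty string")
  q <- tolower(query)
  live <- ontology$ids[!ontology$obsolete[ontology$ids]]
  hit <- vapply(live, function(id) {
    grepl(q, tolower(ontology$name[[id]]), fixed = TRUE) ||
      any(grepl(q, tolower(ontology$synonyms[[id]]), fixed = TRUE))
  }, logical(1))
  ids <- live[hit]
  nm <- unname(ontology$name[ids])
  ord <- order(nchar(nm), ids, method = "radix")
  data.frame(id = ids[ord], name = nm[ord], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.ontology <- function(x, ...) {
  live <- sum(!x$obsolete)
  cat(sprintf("Phenotype ontology: %d concepts (%d obsolete), %d roots\n",
              length(x$ids), sum(x$obsolete), length(x$roots)))
  invisible(x)
}

#' Serialize an ontology back to OBO text
#'
#' Writes the interpreted fields (id, name, synonyms, is_a, is_obsolete) as
#' OBO 1.2-style \code{[Term]} stanzas, such that
#' \code{parse_obo(text = write_obo(x))} reproduces \code{x} on those fields.
#'
#' @inheritParams descendants
#' @return Character vector of OBO lines.
#' @export
write_obo <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  out <- character(0)
  for (id in ontology$ids) {
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ontology$name[[id]]))
    for (s in ontology$synonyms[[id]])
      out <- c(out, sprintf("synonym: \"%s\" EXACT []", s))
    for (p in ontology$parents[[id]])
      out <- c(out, paste0("is_a: ", p, " ! ", ontology$name[[p]]))
    if (ontology$obsolete[[id]]) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  out
}
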