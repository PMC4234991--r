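# Independent brute-force oracles used across the test files.  Each is a
# deliberately naive implementation sharing no code with the package.

# all suffix start offsets (0-based) of the case-folded text, sorted by a
# plain string sort of the suffix strings
naive_suffix_order <- function(text) {
  n <- nchar(text)
  if (!n) return(integer(0))
  suff <- substring(text, seq_len(n), n)
  order(suff, method = "radix") - 1L
}

# every (doc_index 0-based, offset 0-based) where pattern occurs, by direct
# position-by-position substring comparison per document
naive_scan <- function(documents, pattern) {
  documents <- tolower(documents)
  pattern <- tolower(pattern)
  m <- nchar(pattern)
  out <- list()
  for (d in seq_along(documents)) {
    n <- nchar(documents[d])
    if (n < m) next
    starts <- which(substring(documents[d], 1:(n - m + 1), m:n) == pattern)
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(doc_index = d - 1L,
                                            offset = starts - 1L)
  }
  if (!length(out)) return(data.frame(doc_index = integer(0),
                                      offset = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$doc_index, res$offset), , drop = FALSE]
  row.names(res) <- NULL
  res
}

# quadratic label-in-description containment: the link relation map_labels
# must reproduce (names only, min length + stoplist filter applied)
quadratic_links <- function(ontology, table, min_len = 4L,
                            stoplist = c("eo", "als", "age", "cad")) {
  rec <- table$records
  out <- list()
  live <- ontology$ids[!ontology$obsolete[ontology$ids]]
  for (id in live) {
    lab <- tolower(trimws(ontology$name[[id]]))
    if (nchar(lab) < min_len || lab %in% stoplist) next
    hit <- grepl(lab, tolower(rec$phenotype_text), fixed = TRUE)
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        concept_id = id, record_id = rec$record_id[hit],
        provenance = "matched", stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(concept_id = character(0),
                                      record_id = character(0),
                                      provenance = character(0),
                                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$concept_id, res$record_id), , drop = FALSE]
  row.names(res) <- NULL
  res
}

# transitive closure of the child relation by boolean matrix squaring; rows
# give reachability (strictly below the node)
reachability_matrix <- function(ids, parents) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) A[parents[[id]], id] <- TRUE  # parent -> child edge
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# random parent lists forming a DAG over n nodes (node i may only have
# parents among nodes 1..i-1); returns list(ids, parents, obo)
random_dag <- function(n, id_prefix = "TT") {
  ids <- sprintf("%s:%05d", id_prefix, seq_len(n))
  parents <- stats::setNames(
    replicate(n, character(0), simplify = FALSE), ids)
  for (i in seq_len(n)[-1]) {
    k <- sample(1:min(2L, i - 1L), 1)
    parents[[ids[i]]] <- sort(sample(ids[seq_len(i - 1L)], k))
  }
  obo <- character(0)
  for (i in seq_len(n)) {
    obo <- c(obo, "[Term]", paste0("id: ", ids[i]),
             paste0("name: node ", sprintf("%05d", i)))
    for (p in parents[[ids[i]]]) obo <- c(obo, paste0("is_a: ", p))
    obo <- c(obo, "")
  }
  list(ids = ids, parents = parents, obo = obo)
}

# exact P(|S1 n ... n Sm| >= k) by exhaustive bitmask enumeration over all
# but the first set (fixed by symmetry); universe must stay small
enum_overlap_tail <- function(set_sizes, U, k) {
  stopifnot(U <= 14, length(set_sizes) >= 2)
  popcnt <- vapply(0:(2^U - 1),
                   function(x) sum(bitwAnd(x, 2^(0:(U - 1))) > 0), 0)
  masks_of_size <- function(s) {
    all_m <- 0:(2^U - 1)
    all_m[popcnt[all_m + 1] == s]
  }
  s1_mask <- sum(2^(seq_len(set_sizes[1]) - 1))  # WLOG first s1 elements
  rest <- lapply(set_sizes[-1], masks_of_size)
  inter <- s1_mask
  # expand the uniform cross product one set at a time, tracking the
  # intersection mask of every combination
  for (m in rest) inter <- as.vector(outer(inter, m, bitwAnd))
  mean(popcnt[inter + 1] >= k)
}

# diamond DAG: root R; A,B is_a R; C is_a A and B; D is_a C
diamond_obo <- function() {
  c("[Term]", "id: DD:1", "name: rootnode", "",
    "[Term]", "id: DD:2", "name: node aa", "is_a: DD:1", "",
    "[Term]", "id: DD:3", "name: node bb", "is_a: DD:1", "",
    "[Term]", "id: DD:4", "name: node cc", "is_a: DD:2", "is_a: DD:3", "",
    "[Term]", "id: DD:5", "name: node dd", "is_a: DD:4", "")
}

# tiny knowledge base built by hand: concept -> genes via one record each
toy_kb <- function(obo, assignments) {
  onto <- parse_obo(text = obo)
  rows <- character(0)
  links <- list()
  i <- 0L
  for (cid in names(assignments)) for (g in assignments[[cid]]) {
    i <- i + 1L
    rid <- sprintf("r%04d", i)
    rows <- c(rows, paste(rid, g, paste("desc", rid), sep = "\t"))
    links[[i]] <- data.frame(concept_id = cid, record_id = rid,
                             provenance = "matched", stringsAsFactors = FALSE)
  }
  tab <- read_association_table(
    text = c("record_id\tgene\tphenotype_text", rows), dialect = "GAD")
  build_knowledgebase(onto, list(tab),
                      if (length(links)) list(do.call(rbind, links))
                      else list())
}

random_corpus <- function(n_docs, max_len, alphabet = c("a", "c", "g", "t", " ")) {
  vapply(seq_len(n_docs), function(i) {
    len <- sample.int(max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}
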