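SENTINEL <- "\x01"
SENTINEL_INT <- 1L

#' Build a generalized suffix array over a document corpus
#'
#' Case-folds every document, concatenates them with a control-character
#' sentinel (U+0001) terminating each document, and sorts all suffix start
#' offsets of the concatenated text lexicographically (prefix-doubling over
#' integer ranks, fully vectorized, O(n log n)).  Offsets are codepoints, not
#' bytes, so multi-byte UTF-8 text is handled transparently.
#'
#' @param documents Character vector of documents (may be empty).  No
#'   document may contain the sentinel character.
#' @return An object of class \code{"suffix_index"}: list with
#'   \describe{
#'     \item{text}{the concatenated case-folded corpus, sentinels included}
#'     \item{ints}{integer codepoints of \code{text} (used for comparisons)}
#'     \item{sa}{0-based suffix start offsets in lexicographic order;
#'       \code{length(sa) == nchar(text)}}
#'     \item{doc_bounds}{integer matrix, one row per document, columns
#'       \code{start}/\code{end}: half-open 0-based ranges (each including its
#'       trailing sentinel) that partition \code{[0, nchar(text))}}
#'   }
#' @examples
#' idx <- build_suffix_array("banana")
#' find_occurrences(idx, "ana")
#' @export
build_suffix_array <- function(documents) {
  documents <- as.character(documents)
  if (any(grepl(SENTINEL, documents, fixed = TRUE)))
    stop("documents must not contain the sentinel character (U+0001)")
  docs <- tolower(documents)
  if (!length(docs)) {
    return(structure(list(text = "", ints = integer(0), sa = integer(0),
                          doc_bounds = matrix(integer(0), ncol = 2,
                                              dimnames = list(NULL, c("start", "end")))),
                     class = "suffix_index"))
  }
  lens <- nchar(docs, type = "chars") + 1L  # + sentinel
  end <- cumsum(lens)
  start <- c(0L, end[-length(end)])
  text <- paste0(paste0(docs, SENTINEL), collapse = "")
  ints <- utf8ToInt(text)
  n <- length(ints)

  # prefix doubling: rank suffixes by their first k characters, double k
  r <- match(ints, sort(unique(ints)))
  k <- 1L
  while (max(r) < n) {
    r2 <- c(r[-seq_len(k)], rep.int(0L, min(k, n)))
    o <- order(r, r2, method = "radix")
    changed <- c(TRUE, r[o[-1L]] != r[o[-n]] | r2[o[-1L]] != r2[o[-n]])
    nr <- integer(n)
    nr[o] <- cumsum(changed)
    r <- nr
    k <- 2L * k
  }
  sa <- integer(n)
  sa[r] <- seq_len(n) - 1L
  structure(list(text = text, ints = ints, sa = sa,
                 doc_bounds = cbind(start = start, end = end)),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat(sprintf("Suffix index: %d documents, %d characters\n",
              nrow(x$doc_bounds), length(x$ints)))
  invisible(x)
}

# compare suffix starting at 0-based offset `pos` against pattern codepoints:
# -1 suffix-prefix < pattern, 0 pattern is a prefix of the suffix, +1 greater
.cmp_suffix <- function(ints, pos, pat) {
  m <- length(pat)
  avail <- length(ints) - pos
  take <- min(m, avail)
  if (take > 0L) {
    s <- ints[(pos + 1L):(pos + take)]
    d <- which(s != pat[seq_len(take)])
    if (length(d)) return(if (s[d[1L]] < pat[d[1L]]) -1L else 1L)
  }
  if (avail < m) -1L else 0L
}

#' Find all occurrences of a pattern in an indexed corpus
#'
#' Binary search over the suffix array: O(|pattern| * log n) character probes
#' to locate the contiguous block of suffixes having the (case-folded)
#' pattern as a prefix.  Occurrences never span documents because the
#' sentinel terminating each document cannot occur in a pattern.
#'
#' @param index A \code{"suffix_index"} from [build_suffix_array()].
#' @param pattern A single nonempty string; case-folded before search.
#' @return A data.frame with integer columns \code{doc_index} (0-based
#'   ordinal of the document in input order) and \code{offset} (0-based
#'   codepoint offset within the document), sorted by (doc_index, offset).
#' @export
find_occurrences <- function(index, pattern) {
  stopifnot(inherits(index, "suffix_index"))
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a single nonempty string")
  pat <- utf8ToInt(tolower(pattern))
  if (any(pat == SENTINEL_INT))
    stop("pattern must not contain the sentinel character")
  n <- length(index$sa)
  empty <- data.frame(doc_index = integer(0), offset = integer(0))
  if (!n || length(pat) > n) return(empty)

  # lo: first i with suffix >= pattern-as-prefix; hi: first i with suffix > it
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.cmp_suffix(index$ints, index$sa[mid], pat) < 0L) lo <- mid + 1L
    else hi <- mid
  }
  first <- lo
  hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.cmp_suffix(index$ints, index$sa[mid], pat) <= 0L) lo <- mid + 1L
    else hi <- mid
  }
  if (first >= lo) return(empty)
  offs <- index$sa[first:(lo - 1L)]
  doc <- findInterval(offs, index$doc_bounds[, "start"])
  res <- data.frame(doc_index = doc - 1L,
                    offset = offs - index$doc_bounds[doc, "start"])
  res <- res[order(res$doc_index, res$offset, method = "radix"), , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Configuration for label-to-description matching
#'
#' Controls which concept labels participate in substring matching and how.
#' The defaults reproduce unanchored case-folded substring matching with the
#' short ambiguous labels "EO", "ALS", "age" and "CAD" excluded; those labels
#' are notorious for producing unspecific hits when matched as unanchored
#' substrings of disease descriptions.
#'
#' @param min_label_length Minimum label length (characters) for a label to
#'   be matched; default 4.
#' @param stoplist Character vector of labels to exclude (case-folded
#'   internally); default \code{c("eo", "als", "age", "cad")}.
#' @param use_synonyms Also match concept synonyms, not only primary names;
#'   default \code{FALSE}.
#' @param word_boundary Require matches to start and end at non-alphanumeric
#'   boundaries instead of pure substring matching; default \code{FALSE}.
#' @return A list of class \code{"match_config"}.
#' @export
match_config <- function(min_label_length = 4L,
                         stoplist = c("eo", "als", "age", "cad"),
                         use_synonyms = FALSE,
                         word_boundary = FALSE) {
  min_label_length <- as.integer(min_label_length)
  stopifnot(length(min_label_length) == 1L, min_label_length >= 1L)
  structure(list(min_label_length = min_label_length,
                 stoplist = tolower(as.character(stoplist)),
                 use_synonyms = isTRUE(use_synonyms),
                 word_boundary = isTRUE(word_boundary)),
            class = "match_config")
}

.is_word_char <- function(int) {
  (int >= utf8ToInt("a") & int <= utf8ToInt("z")) |
    (int >= utf8ToInt("A") & int <= utf8ToInt("Z")) |
    (int >= utf8ToInt("0") & int <= utf8ToInt("9"))
}

#' Match concept labels to association records by substring occurrence
#'
#' Builds a suffix index over the distinct case-folded phenotype descriptions
#' of an association table and queries it with every eligible concept label.
#' A label is eligible when the concept is non-obsolete, the case-folded
#' label has at least \code{min_label_length} characters and is not on the
#' stoplist.  One link is emitted per (concept, record) pair whose record's
#' description contains the label; pairs are deduplicated and the relation is
#' many-to-many.
#'
#' @param ontology An \code{"ontology"} object.
#' @param table An \code{"association_table"} from
#'   [read_association_table()].
#' @param config A [match_config()].
#' @return A data.frame of links with columns \code{concept_id},
#'   \code{record_id} and \code{provenance} (always \code{"matched"}), sorted
#'   by (concept_id, record_id).
#' @export
map_labels <- function(ontology, table, config = match_config()) {
  stopifnot(inherits(ontology, "ontology"),
            inherits(table, "association_table"),
            inherits(config, "match_config"))
  rec <- table$records
  texts <- tolower(rec$phenotype_text)
  docs <- unique(texts)
  doc_of_record <- match(texts, docs)
  idx <- build_suffix_array(docs)

  live <- ontology$ids[!ontology$obsolete[ontology$ids]]
  out_concept <- character(0)
  out_record <- character(0)
  for (id in live) {
    labels <- ontology$name[[id]]
    if (config$use_synonyms) labels <- c(labels, ontology$synonyms[[id]])
    labels <- unique(tolower(trimws(labels)))
    labels <- labels[nchar(labels) >= config$min_label_length &
                       !labels %in% config$stoplist]
    if (!length(labels)) next
    hit_docs <- integer(0)
    for (lab in labels) {
      occ <- find_occurrences(idx, lab)
      if (!nrow(occ)) next
      if (config$word_boundary) {
        keep <- vapply(seq_len(nrow(occ)), function(i) {
          b <- idx$doc_bounds[occ$doc_index[i] + 1L, ]
          s <- b[["start"]] + occ$offset[i]       # 0-based global start
          e <- s + nchar(lab)                     # 0-based global end (excl)
          before_ok <- s == b[["start"]] ||
            !.is_word_char(idx$ints[s])           # char just before match
          after_ok <- !.is_word_char(idx$ints[e + 1L])  # char just after
          before_ok && after_ok
        }, logical(1))
        occ <- occ[keep, , drop = FALSE]
      }
      hit_docs <- c(hit_docs, occ$doc_index + 1L)
    }
    if (!length(hit_docs)) next
    recs <- rec$record_id[doc_of_record %in% unique(hit_docs)]
    out_concept <- c(out_concept, rep(id, length(recs)))
    out_record <- c(out_record, recs)
  }
  links <- data.frame(concept_id = out_concept, record_id = out_record,
                      provenance = rep("matched", length(out_concept)),
                      stringsAsFactors = FALSE)
  links <- unique(links)
  links <- links[order(links$concept_id, links$record_id, method = "radix"),
                 , drop = FALSE]
  row.names(links) <- NULL
  attr(links, "source") <- table$source
  links
}
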