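#' Descendant-closed gene set of a concept
#'
#' The genes attributed to a concept are those of every association record
#' linked (by text matching or imported mapping) to the concept itself or to
#' any of its ontological descendants.  This closure is what makes
#' cross-phenotype intersections meaningful: an association recorded against
#' a specific subtype also counts as evidence for every broader phenotype
#' above it.
#'
#' @param kb A \code{"knowledgebase"}.
#' @param concept_id A single non-obsolete concept accession.
#' @return Sorted character vector of distinct gene symbols (possibly empty).
#' @export
concept_gene_set <- function(kb, concept_id) {
  stopifnot(inherits(kb, "knowledgebase"))
  .check_concept(kb$ontology, concept_id)
  ids <- c(concept_id, descendants(kb$ontology, concept_id))
  recs <- kb$links$record_id[kb$links$concept_id %in% ids]
  sort(unique(kb$records$gene[kb$records$record_id %in% recs]))
}

#' Intersect the gene sets of several concepts
#'
#' Computes the descendant-closed gene set of each selected concept and their
#' common intersection.  The result is invariant under permutation of the
#' concept ids, and adding a concept to the selection can never grow the
#' common set.
#'
#' @param kb A \code{"knowledgebase"}.
#' @param concept_ids Character vector of distinct, existing, non-obsolete
#'   concept accessions (length >= 1).
#' @return An object of class \code{"intersection_result"}: list with
#'   \code{concept_ids}, \code{per_concept_genes} (named list of gene sets),
#'   \code{common_genes} (sorted character vector) and \code{k_observed}
#'   (\code{length(common_genes)}).
#' @export
intersect_genes <- function(kb, concept_ids) {
  stopifnot(inherits(kb, "knowledgebase"))
  if (!length(concept_ids)) stop("concept_ids must contain at least one id")
  if (anyDuplicated(concept_ids))
    stop("concept_ids must not contain duplicates")
  per <- lapply(concept_ids, function(id) concept_gene_set(kb, id))
  names(per) <- concept_ids
  common <- Reduce(intersect, per)
  common <- sort(common)
  structure(list(concept_ids = concept_ids, per_concept_genes = per,
                 common_genes = common, k_observed = length(common)),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("Gene intersection of %d concepts\n", length(x$concept_ids)))
  for (id in x$concept_ids)
    cat(sprintf("  %-14s %5d genes\n", id, length(x$per_concept_genes[[id]])))
  cat(sprintf("  common genes (k = %d): %s\n", x$k_observed,
              if (x$k_observed) paste(x$common_genes, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Resampling p-value for an observed gene-set overlap
#'
#' Assesses how surprising the observed intersection of the selected
#' concepts' gene sets is under a null model of random same-size gene sets.
#' Each trial draws, independently for every concept, a uniform sample
#' without replacement from the knowledge base's gene universe, of the same
#' size as that concept's observed (descendant-closed) gene set; the trial
#' succeeds when the sampled sets share at least \code{k_observed} genes.
#'
#' With \code{early_stop = TRUE} (the default) sampling repeats until the
#' first success, capped at \code{max_trials}: a success at trial t reports
#' \code{p_estimate = 1/t}; no success within the cap reports the upper bound
#' \code{p_estimate = 1/max_trials} with \code{is_bound = TRUE} (with the
#' default cap of 1000 this renders as \code{p < 0.001}).  With
#' \code{early_stop = FALSE} all \code{max_trials} trials are run and the
#' add-one estimate \code{(successes + 1)/(max_trials + 1)} is reported,
#' which is never exactly zero and is the statistically cleaner fixed-N
#' estimator.
#'
#' @param kb A \code{"knowledgebase"}.
#' @param concept_ids As in [intersect_genes()].
#' @param max_trials Trial cap, >= 1 (default 1000).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param early_stop Stop at the first successful trial (default TRUE).
#' @param sampling_unit \code{"distinct_genes"} (default): each concept's
#'   sample size is the size of its distinct descendant-closed gene set.
#'   \code{"association_rows"}: the sample size is the number of association
#'   rows linked to the concept's closure; each trial samples that many rows
#'   from all records and reduces them to distinct genes, a sensitivity
#'   variant for when the same gene recurs across many associations.
#' @return An object of class \code{"pvalue_result"}: list with
#'   \code{concept_ids}, \code{k_observed}, \code{trials_run},
#'   \code{successes}, \code{p_estimate}, \code{is_bound}, \code{seed},
#'   \code{max_trials}, \code{early_stop}, \code{sampling_unit}.
#' @export
empirical_pvalue <- function(kb, concept_ids, max_trials = 1000L,
                             seed = 1L, early_stop = TRUE,
                             sampling_unit = c("distinct_genes",
                                               "association_rows")) {
  sampling_unit <- match.arg(sampling_unit)
  max_trials <- as.integer(max_trials)
  stopifnot(max_trials >= 1L)
  obs <- intersect_genes(kb, concept_ids)
  k <- obs$k_observed
  universe <- kb$gene_universe
  U <- length(universe)
  m <- length(concept_ids)

  if (sampling_unit == "distinct_genes") {
    sizes <- vapply(obs$per_concept_genes, length, 0L)
  } else {
    ids_of <- lapply(concept_ids, function(id)
      c(id, descendants(kb$ontology, id)))
    sizes <- vapply(ids_of, function(ids)
      length(unique(kb$links$record_id[kb$links$concept_id %in% ids])), 0L)
  }
  if (any(sizes > if (sampling_unit == "distinct_genes") U
          else nrow(kb$records)))
    stop("per-concept sample size exceeds the sampling universe")

  gene_of_record <- match(kb$records$gene, universe)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  one_trial <- function() {
    if (sampling_unit == "distinct_genes") {
      drawn <- unlist(lapply(sizes, function(s) sample.int(U, s)),
                      use.names = FALSE)
      sum(tabulate(drawn, nbins = U) == m) >= k
    } else {
      sets <- lapply(sizes, function(s)
        unique(gene_of_record[sample.int(nrow(kb$records), s)]))
      length(Reduce(intersect, sets)) >= k
    }
  }

  successes <- 0L
  trials_run <- 0L
  if (early_stop) {
    repeat {
      trials_run <- trials_run + 1L
      if (one_trial()) { successes <- 1L; break }
      if (trials_run >= max_trials) break
    }
    is_bound <- successes == 0L
    p <- if (is_bound) 1 / max_trials else 1 / trials_run
  } else {
    for (i in seq_len(max_trials))
      if (one_trial()) successes <- successes + 1L
    trials_run <- max_trials
    is_bound <- FALSE
    p <- (successes + 1) / (max_trials + 1)
  }
  structure(list(concept_ids = concept_ids, k_observed = k,
                 trials_run = trials_run, successes = successes,
                 p_estimate = p, is_bound = is_bound,
                 seed = as.integer(seed), max_trials = max_trials,
                 early_stop = early_stop, sampling_unit = sampling_unit),
            class = "pvalue_result")
}

#' Render a p-value result as text
#'
#' A zero-success capped run is a bound and prints as \code{p < 1/N} (for the
#' default cap of 1000, \code{p < 0.001}); otherwise the point estimate is
#' printed.
#'
#' @param x A \code{"pvalue_result"}.
#' @param ... Unused.
#' @export
print.pvalue_result <- function(x, ...) {
  cat(sprintf("Empirical overlap p-value (%d concepts, k_observed = %d)\n",
              length(x$concept_ids), x$k_observed))
  cat(sprintf("  trials: %d of max %d  successes: %d  seed: %d\n",
              x$trials_run, x$max_trials, x$successes, x$seed))
  cat(sprintf("  %s\n", format_pvalue(x)))
  invisible(x)
}

#' @rdname print.pvalue_result
#' @export
format_pvalue <- function(x) {
  stopifnot(inherits(x, "pvalue_result"))
  if (x$is_bound)
    sprintf("p < %s", format(1 / x$max_trials, scientific = FALSE))
  else sprintf("p = %s", format(x$p_estimate, digits = 6,
                                scientific = FALSE))
}

#' Exact null probability of a gene-set overlap
#'
#' Exact probability that m independently drawn uniform random subsets of a
#' universe of size \code{universe_size}, with the given sizes and drawn
#' without replacement, have a common intersection of at least \code{k}
#' elements.  Computed by composing hypergeometric transition kernels over
#' the running intersection size: given that the intersection of the first j
#' sets has size t, it is (by exchangeability of the universe elements) a
#' uniform random t-subset, so its overlap with the next set of size s is
#' Hypergeometric(universe, t, s).  For m = 2 this reduces to the classical
#' hypergeometric tail used for gene-set overlap tests.
#'
#' @param set_sizes Integer vector of subset sizes (length m >= 1), each
#'   <= \code{universe_size}.
#' @param universe_size Universe size, >= 1.
#' @param k Overlap threshold, >= 0.
#' @return The probability P(|S1 \eqn{\cap} ... \eqn{\cap} Sm| >= k).
#' @examples
#' exact_overlap_null(c(5, 5), 10, 5)   # 1/choose(10,5)
#' @export
exact_overlap_null <- function(set_sizes, universe_size, k) {
  set_sizes <- as.integer(set_sizes)
  universe_size <- as.integer(universe_size)
  k <- as.integer(k)
  stopifnot(length(set_sizes) >= 1L, universe_size >= 1L, k >= 0L,
            all(set_sizes >= 0L), all(set_sizes <= universe_size))
  if (k == 0L) return(1)
  # dist[t + 1] = P(running intersection has size t)
  dist <- numeric(universe_size + 1L)
  dist[set_sizes[1L] + 1L] <- 1
  for (s in set_sizes[-1L]) {
    new <- numeric(universe_size + 1L)
    for (t in which(dist > 0) - 1L) {
      j <- 0:min(t, s)
      new[j + 1L] <- new[j + 1L] +
        dist[t + 1L] * stats::dhyper(j, t, universe_size - t, s)
    }
    dist <- new
  }
  if (k > universe_size) return(0)
  sum(dist[(k + 1L):(universe_size + 1L)])
}
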