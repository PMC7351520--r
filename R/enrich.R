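#' @title Two-sided over-representation analysis with kappa term grouping
#' @name ncnet-enrich
#' @description Hypergeometric over-representation of network mRNA targets
#'   against pathway gene-set collections, with two-sided p-values (doubled
#'   smaller tail, capped at one), Benjamini-Hochberg correction, strict
#'   significance at adjusted p < alpha, per-term up/down direction fractions,
#'   and grouping of redundant significant terms by Cohen's kappa over their
#'   overlap-membership vectors.
NULL

#' Two-sided hypergeometric test
#'
#' With X ~ Hypergeometric(N, K, n) (k of the n drawn genes fall in the
#' K-member term), the two-sided p-value is `min(1, 2 * min(P[X >= k],
#' P[X <= k]))`: the smaller of the enrichment and depletion tails, doubled
#' and capped.
#'
#' @param k overlap count; `0 <= k <= min(K, n)`.
#' @param K term size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value in [0, 1].
#' @export
hypergeom_two_sided <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, n + K - N))
    stop("inconsistent hypergeometric bounds (k=", k, ", K=", K,
         ", n=", n, ", N=", N, ")")
  upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)  # P[X >= k]
  lower <- stats::phyper(k, K, N - K, n)                          # P[X <= k]
  min(1, 2 * min(upper, lower))
}

#' Over-representation analysis of a query gene set
#'
#' Each term is intersected with the universe first; terms empty after
#' intersection are dropped. One two-sided hypergeometric test per remaining
#' term, BH adjustment across all tested terms, significance at adjusted
#' p < alpha (strict). The direction fraction is the proportion of
#' up-regulated genes among the term's overlap with the query.
#'
#' @param query character vector of query gene symbols (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene symbols (typically all
#'   differential transcripts of the contrast).
#' @param terms a [gene_set_collection()].
#' @param directions optional named character vector (`"up"`/`"down"`) giving
#'   each query gene's regulation direction.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return An `enrichment_result` data.frame: `term_id, term_name, k, K, n, N,
#'   p, p_adj, fraction_up, significant`, ordered by `p_adj`; attribute
#'   `membership` holds each term's overlap gene vector.
#' @export
enrich_collection <- function(query, universe, terms, directions = NULL,
                              alpha = 0.05) {
  stopifnot(inherits(terms, "gene_set_collection"), alpha > 0, alpha < 1)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  tn <- attr(terms, "term_names")
  inter <- lapply(terms, intersect, universe)
  keep <- lengths(inter) > 0
  inter <- inter[keep]
  if (!length(inter)) {
    res <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      fraction_up = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(res, "membership") <- list()
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  overlap <- lapply(inter, intersect, query)
  k <- lengths(overlap)
  K <- lengths(inter)
  p <- mapply(hypergeom_two_sided, k, K, MoreArgs = list(n = n, N = N))
  frac_up <- vapply(overlap, function(g) {
    if (!length(g) || is.null(directions)) return(NA_real_)
    mean(directions[g] == "up")
  }, 0)
  res <- data.frame(term_id = names(inter),
                    term_name = unname(tn[names(inter)]),
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N, p = p, p_adj = bh_adjust(p),
                    fraction_up = frac_up,
                    stringsAsFactors = FALSE)
  res$significant <- res$p_adj < alpha
  ord <- order(res$p_adj, res$p, res$term_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "membership") <- overlap[res$term_id]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Cohen's kappa between two binary membership vectors
#'
#' Agreement of two gene sets over a common query: `kappa = (po - pe) /
#' (1 - pe)` from the 2x2 co-membership table. When both vectors are constant
#' and identical the kappa is defined as 1; constant but different, 0.
#'
#' @param a,b logical vectors of equal length.
#' @return kappa in [-1, 1].
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Group significant terms by kappa connectivity
#'
#' Computes Cohen's kappa between every pair of significant terms from their
#' binary overlap-membership vectors over the query set, joins pairs with
#' kappa at or above the threshold, and takes connected components as groups
#' (the ClueGO-style redundancy reduction). Each group's representative is its
#' member with the smallest adjusted p (ties: smallest term id).
#'
#' @param results an [enrich_collection()] result.
#' @param query the query gene vector the results were computed from.
#' @param kappa_min minimum kappa to join two terms (default 0.4).
#' @return `results` with added columns `group_id` (NA for non-significant
#'   terms) and `representative` (logical).
#' @export
kappa_group_terms <- function(results, query, kappa_min = 0.4) {
  stopifnot(inherits(results, "enrichment_result"),
            kappa_min >= 0, kappa_min <= 1)
  membership <- attr(results, "membership")
  query <- unique(as.character(query))
  sig <- results$term_id[results$significant]
  results$group_id <- NA_integer_
  results$representative <- FALSE
  if (length(sig)) {
    vecs <- lapply(membership[sig], function(g) query %in% g)
    g <- igraph::make_empty_graph(length(sig), directed = FALSE)
    igraph::V(g)$name <- sig
    if (length(sig) > 1) {
      pairs <- utils::combn(seq_along(sig), 2)
      ok <- apply(pairs, 2, function(ij)
        cohens_kappa(vecs[[ij[1]]], vecs[[ij[2]]]) >= kappa_min)
      if (any(ok))
        g <- igraph::add_edges(g, as.vector(pairs[, ok, drop = FALSE]))
    }
    comp <- igraph::components(g)$membership
    results$group_id[match(sig, results$term_id)] <- unname(comp[sig])
    for (grp in unique(comp)) {
      ids <- sig[comp == grp]
      sub <- results[results$term_id %in% ids, ]
      rep_id <- sub$term_id[order(sub$p_adj, sub$term_id)][1]
      results$representative[results$term_id == rep_id] <- TRUE
    }
  }
  attr(results, "membership") <- membership
  class(results) <- c("enrichment_result", "data.frame")
  results
}
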