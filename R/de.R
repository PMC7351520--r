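#' @title Differential expression on small-RNA count matrices
#' @name ncnet-de
#' @description Exact negative-binomial differential-expression calling:
#'   low-count filtering, upper-quartile normalisation, common-dispersion
#'   estimation by conditional maximum likelihood, the classic conditional
#'   exact test, and Benjamini-Hochberg adjustment with thresholded up/down
#'   calls.
NULL

#' Construct a count matrix with sample-group labels
#'
#' @param counts integer matrix, features x samples, non-negative; must have
#'   row and column names.
#' @param groups character/factor of group labels, one per sample (named by
#'   sample or in column order).
#' @return A `count_matrix`: list with elements `counts`, `groups` (named
#'   character) and `lib_sizes` (column sums).
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("F", seq_len(nrow(counts)))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(counts), names(groups))
    if (length(miss)) stop("no group for sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[colnames(counts)]
  } else {
    if (length(groups) != ncol(counts))
      stop("groups must have one label per sample")
    names(groups) <- colnames(counts)
  }
  if (any(is.na(groups) | !nzchar(groups))) stop("every sample needs a group")
  structure(list(counts = counts, groups = groups,
                 lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' Read a count matrix and its sample-group map from TSV
#'
#' @param counts_path TSV with features as rows, first column `feature_id`,
#'   remaining columns one per sample.
#' @param groups_path two-column TSV (`sample`, `group`).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, groups_path) {
  df <- utils::read.delim(counts_path, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "feature_id")
    stop(counts_path, ": first column must be feature_id")
  m <- as.matrix(df[-1])
  rownames(m) <- df$feature_id
  g <- utils::read.delim(groups_path, sep = "\t", colClasses = "character")
  if (!all(c("sample", "group") %in% names(g)))
    stop(groups_path, ": expected columns sample, group")
  count_matrix(m, stats::setNames(g$group, g$sample))
}

#' Write a count matrix and group map to TSV
#'
#' @param m a [count_matrix()].
#' @param counts_path,groups_path output file paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(m, counts_path, groups_path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  write_tsv_plain(df, counts_path)
  write_tsv_plain(data.frame(sample = names(m$groups), group = m$groups),
                  groups_path)
  invisible(counts_path)
}

#' Remove features never reaching a minimum read count
#'
#' Retains exactly the features whose maximum raw count across samples is at
#' least `min_reads`; the sample set is unchanged.
#'
#' @param m a [count_matrix()].
#' @param min_reads minimum reads required in at least one sample (default 10).
#' @return The filtered [count_matrix()].
#' @export
filter_low_counts <- function(m, min_reads = 10L) {
  stopifnot(inherits(m, "count_matrix"), min_reads >= 0)
  keep <- apply(m$counts, 1L, max) >= min_reads
  count_matrix(m$counts[keep, , drop = FALSE], m$groups)
}

#' Upper-quartile normalisation factors
#'
#' For each sample the chosen quantile of its counts, restricted to features
#' nonzero in at least one sample, is divided by the library size; the
#' resulting per-sample rates are rescaled to geometric mean one. Dividing each
#' sample's rate by its factor equalises upper quartiles across samples.
#'
#' @param m a [count_matrix()].
#' @param quantile quantile to match across samples (default 0.75).
#' @param lib_sizes optional library sizes overriding the column sums (e.g.
#'   sequencing depths that include reads outside the matrix).
#' @return Named numeric vector of factors with geometric mean 1.
#' @export
upper_quartile_factors <- function(m, quantile = 0.75, lib_sizes = NULL) {
  stopifnot(inherits(m, "count_matrix"), quantile > 0, quantile < 1)
  if (is.null(lib_sizes)) lib_sizes <- m$lib_sizes
  zero_samp <- m$lib_sizes == 0
  if (any(zero_samp))
    stop("all-zero sample(s): ",
         paste(names(m$lib_sizes)[zero_samp], collapse = ", "))
  expressed <- rowSums(m$counts) > 0
  q <- apply(m$counts[expressed, , drop = FALSE], 2L,
             stats::quantile, probs = quantile, names = FALSE)
  if (any(q == 0))
    stop("upper quantile is zero for sample(s): ",
         paste(colnames(m$counts)[q == 0], collapse = ", "),
         "; filter low counts first or raise the quantile")
  rate <- q / lib_sizes
  rate / exp(mean(log(rate)))
}

# Scale counts to the geometric-mean effective library size and round
# half-to-even; the conditional exact machinery requires equal integer totals.
equalize_libsizes <- function(m, factors = NULL, quantile = 0.75) {
  if (is.null(factors)) factors <- upper_quartile_factors(m, quantile)
  eff <- m$lib_sizes * factors
  common <- exp(mean(log(eff)))
  pseudo <- round(sweep(m$counts, 2L, common / eff, `*`))
  list(pseudo = pseudo, common_size = common, factors = factors)
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximises, over a single dispersion shared by all features, the
#' negative-binomial log-likelihood conditional on each feature's per-group
#' total, after equalising effective library sizes (upper-quartile factors).
#' Deterministic given the input. The Poisson limit (dispersion 0) is included
#' in the comparison, so data with no excess variance return exactly 0.
#'
#' @param m a [count_matrix()]; at least two groups with two or more samples
#'   each.
#' @param factors optional pre-computed normalisation factors.
#' @param interval search interval for the dispersion (default `c(1e-4, 5)`).
#' @return Estimated dispersion phi >= 0.
#' @export
estimate_common_dispersion <- function(m, factors = NULL,
                                       interval = c(1e-4, 5)) {
  stopifnot(inherits(m, "count_matrix"))
  sizes <- table(m$groups)
  if (sum(sizes >= 2L) < 2L)
    stop("need >= 2 groups with >= 2 samples each; ",
         "with single-replicate groups supply a fixed dispersion instead")
  eq <- equalize_libsizes(m, factors)
  groups <- split(seq_along(m$groups), m$groups)
  groups <- groups[lengths(groups) >= 2L]
  ll <- function(phi) {
    r <- 1 / phi
    tot <- 0
    for (idx in groups) {
      y <- eq$pseudo[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      tot <- tot + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
        sum(lgamma(n * r) - lgamma(z + n * r))
    }
    tot
  }
  # Poisson limit of the phi-dependent part: -sum(z) * log(n) per group
  ll0 <- sum(vapply(groups, function(idx) {
    -sum(rowSums(eq$pseudo[, idx, drop = FALSE])) * log(length(idx))
  }, 0))
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE,
                         tol = 1e-6)
  if (opt$objective > ll0 + 1e-8) opt$maximum else 0
}

#' Conditional exact negative-binomial test for two groups
#'
#' For each feature, computes the probability under the null NB model --
#' conditional on the feature's total count after library-size equalisation --
#' of group-sum splits as extreme or more extreme than observed. Two-sided
#' p-values sum the probabilities of all splits whose probability does not
#' exceed the observed split's (ties included). The log2 fold change is the
#' ratio of normalised per-sample mean rates (group_b over group_a) with a
#' small prior count added to both, so presence/absence features stay finite.
#'
#' @param m a [count_matrix()].
#' @param group_a,group_b group labels to compare (fold change is b over a).
#' @param phi common NB dispersion (>= 0; 0 gives the exact binomial/Poisson
#'   conditional test).
#' @param factors optional pre-computed normalisation factors for all samples
#'   of `m`.
#' @param prior_count prior added to each group's mean rate for the fold
#'   change (default 0.125).
#' @return data.frame with columns `feature_id`, `log2fc`, `p_raw`.
#' @export
exact_nb_test <- function(m, group_a, group_b, phi, factors = NULL,
                          prior_count = 0.125) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(phi) != 1L || is.na(phi) || phi < 0)
    stop("phi must be a single dispersion >= 0")
  for (g in c(group_a, group_b))
    if (!g %in% m$groups) stop("unknown group label: ", g)
  eq <- equalize_libsizes(m, factors)
  ia <- which(m$groups == group_a)
  ib <- which(m$groups == group_b)
  na <- length(ia); nb <- length(ib)
  za <- rowSums(eq$pseudo[, ia, drop = FALSE])
  zb <- rowSums(eq$pseudo[, ib, drop = FALSE])
  log2fc <- log2((zb / nb + prior_count) / (za / na + prior_count))
  p <- vapply(seq_along(za), function(i) {
    cond_exact_p(za[i], za[i] + zb[i], na, nb, phi)
  }, 0)
  data.frame(feature_id = rownames(m$counts), log2fc = log2fc, p_raw = p,
             stringsAsFactors = FALSE)
}

# Two-sided conditional exact p for observing group-A sum `a` out of total `z`
# split between na and nb samples under common dispersion phi. Sums the
# probabilities of all splits no more probable than the observed one.
cond_exact_p <- function(a, z, na, nb, phi) {
  if (z == 0) return(1)
  k <- 0:z
  if (phi == 0) {
    lp <- stats::dbinom(k, z, na / (na + nb), log = TRUE)
  } else {
    r <- 1 / phi
    mu <- z / (na + nb)            # arbitrary common rate; cancels after normalisation
    la <- stats::dnbinom(k, size = na * r, mu = na * mu, log = TRUE)
    lb <- stats::dnbinom(k, size = nb * r, mu = nb * mu, log = TRUE)
    lp <- la + rev(lb)
    lp <- lp - logsumexp(lp)       # normalisation
  }
  obs <- lp[a + 1L]
  min(1, sum(exp(lp[lp <= obs + 1e-10])))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around the standard BH step-up procedure: sorted
#' p-values are multiplied by m/rank, cumulative minima taken from the largest
#' down, capped at one, and returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold differential-expression calls
#'
#' @param results data.frame with columns `log2fc` and `fdr` (e.g. the output
#'   of [exact_nb_test()] augmented with [bh_adjust()]).
#' @param threshold FDR threshold in (0, 1); boundary-inclusive, matching the
#'   study conventions FDR <= 0.05 (lncRNA) and <= 0.06 (miRNA).
#' @return `results` with an added `call` column: `"up"` if `fdr <= threshold`
#'   and `log2fc > 0`, `"down"` if `fdr <= threshold` and `log2fc < 0`,
#'   `"ns"` otherwise (a zero fold change is never called).
#' @export
call_differential <- function(results, threshold) {
  stopifnot(is.data.frame(results), all(c("log2fc", "fdr") %in% names(results)),
            threshold > 0, threshold < 1)
  call <- rep("ns", nrow(results))
  sig <- results$fdr <= threshold
  call[sig & results$log2fc > 0] <- "up"
  call[sig & results$log2fc < 0] <- "down"
  results$call <- call
  results
}

#' Full differential-expression analysis for one contrast
#'
#' Convenience pipeline: low-count filter, upper-quartile factors,
#' common-dispersion estimate, conditional exact test, BH adjustment and
#' thresholded calls.
#'
#' @param m a [count_matrix()].
#' @param group_a,group_b groups to compare (fold change is b over a).
#' @param min_reads low-count filter threshold (default 10).
#' @param fdr_threshold call threshold (default 0.06, the small-RNA
#'   convention).
#' @param phi optional fixed dispersion; estimated from `m` when `NULL`.
#' @return data.frame `feature_id, log2fc, p_raw, fdr, call` with attributes
#'   `dispersion` and `norm_factors`.
#' @export
de_analysis <- function(m, group_a, group_b, min_reads = 10L,
                        fdr_threshold = 0.06, phi = NULL) {
  m <- filter_low_counts(m, min_reads)
  keep <- m$groups %in% c(group_a, group_b)
  m2 <- count_matrix(m$counts[, keep, drop = FALSE], m$groups[keep])
  factors <- upper_quartile_factors(m2)
  if (is.null(phi)) phi <- estimate_common_dispersion(m2, factors)
  res <- exact_nb_test(m2, group_a, group_b, phi, factors)
  res$fdr <- bh_adjust(res$p_raw)
  res <- call_differential(res, fdr_threshold)
  attr(res, "dispersion") <- phi
  attr(res, "norm_factors") <- factors
  res
}
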