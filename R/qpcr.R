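#' @title qPCR relative quantification and cross-platform concordance
#' @name ncnet-qpcr
#' @description The validation stage: 2^-ddCt relative expression against an
#'   endogenous control assay (GUSB for lncRNAs, let-7a-5p for miRNAs) and a
#'   control subject group, one-way ANOVA with Fisher's LSD post hoc per
#'   assay, and Spearman rank concordance between qPCR and sequencing fold
#'   changes.
NULL

#' Construct and validate a qPCR plate
#'
#' @param df data.frame with columns `sample_id, group, assay_id, ct_target,
#'   ct_reference, reference_assay`; Ct values are PCR cycles (finite,
#'   typically 10-40).
#' @return A `qpcr_plate` data.frame.
#' @export
qpcr_plate <- function(df) {
  need <- c("sample_id", "group", "assay_id", "ct_target", "ct_reference",
            "reference_assay")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qPCR plate missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (col in c("sample_id", "group", "assay_id", "reference_assay"))
    df[[col]] <- as.character(df[[col]])
  df$ct_target <- as.numeric(df$ct_target)
  df$ct_reference <- as.numeric(df$ct_reference)
  bad <- !is.finite(df$ct_target)
  if (any(bad))
    stop("missing/non-finite target Ct for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  bad <- !is.finite(df$ct_reference)
  if (any(bad))
    stop("missing/non-finite reference Ct for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("qpcr_plate", "data.frame"))
}

#' Read a qPCR plate from TSV
#'
#' @param path tab-separated file with the [qpcr_plate()] header.
#' @return A `qpcr_plate`.
#' @export
read_qpcr_plate <- function(path) {
  raw <- read_tsv_strict(path, c("sample_id", "group", "assay_id",
                                 "ct_target", "ct_reference",
                                 "reference_assay"))
  qpcr_plate(raw)
}

#' Write a qPCR plate to TSV
#'
#' @param x a [qpcr_plate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qpcr_plate <- function(x, path) {
  stopifnot(inherits(x, "qpcr_plate"))
  write_tsv_plain(as.data.frame(x), path)
}

#' 2^-ddCt relative expression
#'
#' Per assay: `dct = ct_target - ct_reference`; `ddct = dct - mean(dct)` over
#' the control group's samples of that assay; `fold = 2^-ddct`. Centering on
#' the control-group mean (rather than a single calibrator sample) makes the
#' control group's geometric-mean fold exactly one.
#'
#' @param plate a [qpcr_plate()].
#' @param control_group calibrator group label (default `"Nw"`).
#' @return A `relative_expression` data.frame: `sample_id, group, assay_id,
#'   dct, ddct, fold`, with attribute `control_group`.
#' @export
ddct_fold <- function(plate, control_group = "Nw") {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (!control_group %in% plate$group)
    stop("control group '", control_group, "' absent from plate")
  out <- lapply(split(plate, plate$assay_id), function(pp) {
    ctrl <- pp$group == control_group
    if (!any(ctrl))
      stop("assay ", pp$assay_id[1], " has no ", control_group, " sample")
    dct <- pp$ct_target - pp$ct_reference
    ddct <- dct - mean(dct[ctrl])
    data.frame(sample_id = pp$sample_id, group = pp$group,
               assay_id = pp$assay_id, dct = dct, ddct = ddct,
               fold = 2^(-ddct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, control_group = control_group,
            class = c("relative_expression", "data.frame"))
}

#' Per-group summary of relative expression
#'
#' @param rel a [ddct_fold()] result.
#' @return data.frame `assay_id, group, n, mean_fold, sd_fold, geomean_fold`.
#' @export
summarize_folds <- function(rel) {
  stopifnot(inherits(rel, "relative_expression"))
  sp <- split(rel, list(rel$assay_id, rel$group), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(x) data.frame(
    assay_id = x$assay_id[1], group = x$group[1], n = nrow(x),
    mean_fold = mean(x$fold), sd_fold = stats::sd(x$fold),
    geomean_fold = exp(mean(log(x$fold))), stringsAsFactors = FALSE)))
  out <- out[order(out$assay_id, out$group), ]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Fisher's LSD post hoc against a control group
#'
#' The omnibus F uses the standard one-way decomposition; LSD pairwise tests
#' use t statistics on the pooled within-group mean square with its residual
#' degrees of freedom, unadjusted (Fisher's protected-LSD convention).
#' Unbalanced groups are supported. Significance stars follow the reporting
#' convention `*` for p <= 0.05 and `**` for p <= 0.005.
#'
#' @param values numeric response (one observation per sample); ddCt values
#'   by default upstream, see [qpcr_validate()].
#' @param groups group label per observation; every group needs >= 2 samples.
#' @param control_group reference group for the pairwise comparisons.
#' @param alpha omnibus significance level (default 0.05; recorded only).
#' @return list with `f`, `p_omnibus`, `df`, and `pairwise` (data.frame
#'   `group, diff, t, p, stars` vs the control).
#' @export
anova_lsd <- function(values, groups, control_group, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    stop("group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!control_group %in% groups)
    stop("unknown control group: ", control_group)
  means <- tapply(values, groups, mean)
  nN <- length(values); kk <- length(sizes)
  ss_within <- sum((values - means[groups])^2)
  ss_between <- sum(sizes * (means[names(sizes)] - mean(values))^2)
  df1 <- kk - 1; df2 <- nN - kk
  mse <- ss_within / df2
  if (mse < .Machine$double.eps * max(1, mean(values)^2)) {
    # degenerate: zero within-group variance
    f <- if (ss_between < 1e-12) 0 else Inf
    p_omni <- if (f == 0) 1 else 0
  } else {
    f <- (ss_between / df1) / mse
    p_omni <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  others <- setdiff(names(sizes), control_group)
  pw <- do.call(rbind, lapply(others, function(g) {
    diff <- means[[g]] - means[[control_group]]
    se <- sqrt(mse * (1 / sizes[[g]] + 1 / sizes[[control_group]]))
    tt <- if (se == 0) (if (diff == 0) 0 else sign(diff) * Inf) else diff / se
    p <- 2 * stats::pt(-abs(tt), df2)
    data.frame(group = g, diff = diff, t = tt, p = p,
               stars = if (p <= 0.005) "**" else if (p <= 0.05) "*" else "",
               stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  list(f = f, p_omnibus = p_omni, df = c(df1 = df1, df2 = df2),
       pairwise = pw, alpha = alpha)
}

#' Per-assay qPCR validation
#'
#' Runs [ddct_fold()] and, for each assay, [anova_lsd()] against the control
#' group. The ANOVA response is the ddCt (log2) scale by default -- Ct-space
#' noise is closer to additive there -- with the fold scale available.
#'
#' @param plate a [qpcr_plate()].
#' @param control_group calibrator group (default `"Nw"`).
#' @param scale `"ddct"` (default) or `"fold"`.
#' @return list with `relative` (the [ddct_fold()] table), `group_summary`,
#'   and `tests` (named per-assay list of [anova_lsd()] results).
#' @export
qpcr_validate <- function(plate, control_group = "Nw",
                          scale = c("ddct", "fold")) {
  scale <- match.arg(scale)
  rel <- ddct_fold(plate, control_group)
  tests <- lapply(split(rel, rel$assay_id), function(x) {
    v <- if (scale == "ddct") x$ddct else x$fold
    anova_lsd(v, x$group, control_group)
  })
  list(relative = rel, group_summary = summarize_folds(rel), tests = tests)
}

#' Spearman rank concordance between two platforms
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties). The
#' p-value uses the t approximation with n - 2 degrees of freedom, except for
#' n <= 8 paired observations where the exact permutation distribution over
#' all n! rank orders is enumerated.
#'
#' @param x,y paired numeric vectors (>= 3 observations, non-constant).
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_concordance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all n! permutations of 1..n as a matrix (rows); n <= 8 keeps this small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}
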