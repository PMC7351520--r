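# shared helpers: tiny builders used across test files

# minimal valid contrast table
toy_contrast <- function(genes, lfc, contrast_id = "Ob_vs_Nw",
                         biotype = "lncRNA_known", fdr = 0.01,
                         ids = NULL) {
  n <- length(genes)
  contrast_table(data.frame(
    feature_id = if (is.null(ids)) make.unique(genes) else ids,
    gene_name = genes, biotype = rep(biotype, length.out = n),
    log2fc = lfc, fdr = rep(fdr, length.out = n),
    stringsAsFactors = FALSE), contrast_id)
}

toy_set <- function(genes, lfc = rep(1, length(genes)),
                    contrast_id = "Ob_vs_Nw", biotype = "lncRNA_known") {
  build_contrast_set(toy_contrast(genes, lfc, contrast_id, biotype))
}

# evidence-table row builder
evid_rows <- function(...) interaction_table(rbind(...))
erow <- function(src, scls, tgt, tcls, ev, score = NA_real_) {
  data.frame(source_id = src, source_class = scls, target_id = tgt,
             target_class = tcls, evidence = ev, score = score,
             stringsAsFactors = FALSE)
}

# independent BH step-up oracle (straight from the definition)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(m * sorted[i:m] / (i:m), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent hypergeometric two-sided oracle by full draw enumeration
hyper_oracle <- function(k, K, n, N) {
  term <- seq_len(K)
  draws <- utils::combn(N, n)
  ks <- apply(draws, 2, function(d) sum(d %in% term))
  upper <- mean(ks >= k)
  lower <- mean(ks <= k)
  min(1, 2 * min(upper, lower))
}
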