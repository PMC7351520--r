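test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(seed = 99, n_mirna = 50, n_lncrna = 10,
                      library_size = 1e4)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  i1 <- simulate_interactions(cfg)
  i2 <- simulate_interactions(cfg)
  expect_identical(as.data.frame(i1$evidence), as.data.frame(i2$evidence))
  # byte-identical files
  f1 <- tempfile(); f2 <- tempfile()
  write_interaction_table(i1$evidence, f1)
  write_interaction_table(i2$evidence, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_counts(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero dispersion degenerates to Poisson counts", {
  cfg <- synth_config(seed = 7, n_mirna = 2000, n_lncrna = 0, phi = 0,
                      de_fraction = c(mirna = 0, lncrna = 0),
                      library_size = 2e5, depth_range = c(1, 1),
                      groups = c("A", "B"), n_per_group = 6)
  sim <- simulate_counts(cfg)
  cm <- sim$counts$counts
  # variance/mean ratio across samples, averaged over well-expressed features
  mu <- rowMeans(cm)
  keep <- mu > 20
  ratio <- apply(cm[keep, ], 1, stats::var) / mu[keep]
  expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("no planted DE means no nonzero true fold changes", {
  cfg <- synth_config(seed = 5, n_mirna = 100, n_lncrna = 20,
                      de_fraction = c(mirna = 0, lncrna = 0),
                      library_size = 1e4)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$lfc == 0))
  expect_equal(nrow(sim$truth$per_contrast[[1]]), 0)
})

test_that("planted on/off lncRNAs are absent on one side of their contrast", {
  cfg <- synth_config(seed = 21, n_mirna = 0, n_lncrna = 100,
                      de_fraction = c(mirna = 0, lncrna = 0.3),
                      onoff_fraction = 0.5, library_size = 1e5,
                      groups = c("Nw", "Ob"), n_per_group = 6)
  sim <- simulate_counts(cfg)
  tr <- sim$truth$per_contrast[["Ob_vs_Nw"]]
  oo <- tr[tr$onoff, ]
  expect_gt(nrow(oo), 0)
  cm <- sim$counts$counts
  nw <- sim$counts$groups == "Nw"
  for (i in seq_len(nrow(oo))) {
    f <- oo$feature_id[i]
    if (oo$direction[i] == "down") {
      expect_equal(sum(cm[f, !nw]), 0)   # silenced in disease
    } else {
      expect_equal(sum(cm[f, nw]), 0)    # absent from control
    }
  }
  # pipeline survives presence/absence features without overflow
  res <- de_analysis(sim$counts, "Nw", "Ob", min_reads = 10)
  expect_true(all(is.finite(res$log2fc)))
})

test_that("planted interaction structure matches its specification", {
  cfg <- synth_config(seed = 13)
  si <- simulate_interactions(cfg)
  ev <- si$evidence
  # XIST-like lncRNA carries exactly the prescribed validated mRNA target rows
  xl <- si$truth$xist_like
  n_rows <- sum(ev$source_id == xl & ev$target_class == "mRNA" &
                ev$evidence == "validated")
  expect_equal(n_rows, cfg$hub_spec$xist_like_degree)
  # a point-mass score below the cutoff leaves no surviving predicted edges
  cfg2 <- synth_config(seed = 13, score_range = c(0.5, 0.5))
  si2 <- simulate_interactions(cfg2)
  l2 <- build_del_dem_layer(si2$sets$del, si2$sets$dem, si2$evidence, 0.6)
  expect_true(all(l2$evidence == "validated"))
})

test_that("emitted artifacts are valid inputs to the readers", {
  cfg <- synth_config(seed = 3, n_mirna = 40, n_lncrna = 5,
                      library_size = 5e3)
  sim <- simulate_counts(cfg)
  cpath <- tempfile(); gpath <- tempfile()
  write_count_matrix(sim$counts, cpath, gpath)
  back <- read_count_matrix(cpath, gpath)
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$groups, sim$counts$groups)

  si <- simulate_interactions(cfg)
  epath <- tempfile()
  write_interaction_table(si$evidence, epath)
  expect_equal(read_interaction_table(epath), si$evidence)

  universe <- si$sets$det$gene_name
  pw <- simulate_pathways(cfg, universe, universe[1:30])
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(pw$collection, gmt)
  expect_equal(unclass(read_gmt(gmt))[names(pw$collection)],
               unclass(pw$collection)[names(pw$collection)],
               ignore_attr = TRUE)

  plate <- simulate_qpcr(cfg, data.frame(assay_id = "A1", group = "Ob",
                                         fold = 2))
  ppath <- tempfile()
  write_qpcr_plate(plate, ppath)
  expect_equal(read_qpcr_plate(ppath), plate, tolerance = 1e-12)
})

test_that("noisy qPCR plates recover planted folds within tolerance", {
  # noiseless inversion is exact
  p0 <- simulate_qpcr(synth_config(seed = 2, qpcr_sigma = 0),
                      data.frame(assay_id = "A", group = "Ob", fold = 4))
  rel0 <- ddct_fold(p0, "Nw")
  expect_equal(unique(rel0$fold[rel0$group == "Ob"]), 4)
  # sigma = 0.2, n = 6: mean recovered fold close to the planted value
  means <- sapply(1:20, function(s) {
    p <- simulate_qpcr(synth_config(seed = s, qpcr_sigma = 0.2),
                       data.frame(assay_id = "A", group = "Ob", fold = 2))
    rel <- ddct_fold(p, "Nw")
    mean(rel$fold[rel$group == "Ob"])
  })
  expect_gte(mean(means), 1.7)
  expect_lte(mean(means), 2.3)
})

test_that("end-to-end DE recovery on planted synthetic data", {
  perf <- sapply(1:5, function(s) {
    cfg <- synth_config(seed = s, n_mirna = 500, n_lncrna = 0,
                        de_fraction = c(mirna = 0.1, lncrna = 0),
                        lfc_range_mirna = c(1.5, 1.5), phi = 0.15,
                        library_size = 2e5, groups = c("Nw", "Ob"),
                        n_per_group = 6)
    sim <- simulate_counts(cfg)
    res <- de_analysis(sim$counts, "Nw", "Ob", fdr_threshold = 0.06)
    truth <- sim$truth$per_contrast[[1]]
    called <- res[res$call != "ns", ]
    sens <- mean(truth$feature_id %in% called$feature_id)
    # called directions must match the planted signs
    dir_ok <- all(called$call[match(truth$feature_id, called$feature_id,
                                    nomatch = 0)] ==
                  truth$direction[truth$feature_id %in% called$feature_id])
    c(sens = sens, fdr = if (nrow(called)) mean(!called$feature_id %in%
                                                truth$feature_id) else 0,
      dir = dir_ok)
  })
  expect_gte(median(perf["sens", ]), 0.5)
  expect_lte(median(perf["fdr", ]), 0.10)
  expect_true(all(perf["dir", ] == 1))
})
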