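mk_sets <- function() {
  list(dem = toy_set(paste0("m", 1:5), biotype = "miRNA"),
       del = toy_set(paste0("L", 1:3), biotype = "lncRNA_known"),
       det = toy_set(paste0("G", 1:20), lfc = rep(c(1, -1), 10),
                     biotype = "mRNA"))
}

test_that("miRNA-mRNA layer applies the DET filter and validated-only rule", {
  s <- mk_sets()
  ev <- evid_rows(erow("m1", "miRNA", "OFFLIST", "mRNA", "validated"),
                  erow("m1", "miRNA", "G1", "mRNA", "validated"),
                  erow("m2", "miRNA", "G2", "mRNA", "predicted", 0.99),
                  erow("mX", "miRNA", "G3", "mRNA", "validated"))
  l <- build_dem_det_layer(s$dem, s$det, ev)
  expect_equal(nrow(l), 1)               # DET filter, predicted and non-DEM dropped
  expect_equal(l$source, "m1")
  expect_equal(l$target, "G1")
  expect_equal(nrow(build_dem_det_layer(s$dem, s$det,
                                        evid_rows(erow("x", "miRNA", "y",
                                                       "mRNA", "validated")))), 0)
  # planted 5 DEM x 4 validated DET targets each -> 20 edges
  rows <- do.call(rbind, lapply(1:5, function(i)
    erow(paste0("m", i), "miRNA", paste0("G", (i - 1) * 4 + 1:4), "mRNA",
         "validated")))
  expect_equal(nrow(build_dem_det_layer(s$dem, s$det,
                                        interaction_table(rows))), 20)
})

test_that("lncRNA-miRNA layer applies the inclusive score cutoff and dedup", {
  s <- mk_sets()
  ev <- evid_rows(erow("L1", "lncRNA", "m1", "miRNA", "predicted", 0.59),
                  erow("L1", "lncRNA", "m2", "miRNA", "predicted", 0.60),
                  erow("L2", "lncRNA", "m3", "miRNA", "predicted", 0.90),
                  erow("L2", "lncRNA", "m3", "miRNA", "validated"))
  l <- build_del_dem_layer(s$del, s$dem, ev)
  expect_equal(nrow(l), 2)
  expect_false(any(l$source == "L1" & l$target == "m1"))  # 0.59 excluded
  expect_true(any(l$source == "L1" & l$target == "m2"))   # 0.60 included
  dup <- l[l$source == "L2", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$evidence, "validated")
  # raising the cutoff never adds edges
  for (cut in c(0, 0.3, 0.6, 0.9, 1)) {
    n_lo <- nrow(build_del_dem_layer(s$del, s$dem, ev, cut))
    n_hi <- nrow(build_del_dem_layer(s$del, s$dem, ev, min(cut + 0.2, 1)))
    expect_lte(n_hi, n_lo)
  }
  expect_equal(nrow(build_del_dem_layer(toy_set(character(),
                                                biotype = "lncRNA_known"),
                                        s$dem, ev)), 0)
})

test_that("lncRNA-mRNA layer admits verified evidence only", {
  s <- mk_sets()
  ev <- evid_rows(erow("L1", "lncRNA", "G1", "mRNA", "predicted", 0.99),
                  erow("L1", "lncRNA", "G2", "mRNA", "validated"),
                  erow("L2", "lncRNA", "OFFLIST", "mRNA", "validated"))
  l <- build_del_det_layer(s$del, s$det, ev)
  expect_equal(nrow(l), 1)
  expect_equal(l$target, "G2")
  expect_false("L2" %in% l$source)   # all targets outside DET: node omitted
})

test_that("integration yields a consistent annotated tripartite graph", {
  s <- mk_sets()
  empty <- integrate_layers(list(), s$del, s$dem, s$det)
  expect_equal(igraph::vcount(empty$graph), 0)

  ev <- evid_rows(erow("m1", "miRNA", "G1", "mRNA", "validated"),
                  erow("m1", "miRNA", "G2", "mRNA", "validated"),
                  erow("L1", "lncRNA", "m1", "miRNA", "predicted", 0.8),
                  erow("L1", "lncRNA", "G1", "mRNA", "validated"))
  layers <- list(build_dem_det_layer(s$dem, s$det, ev),
                 build_del_dem_layer(s$del, s$dem, ev),
                 build_del_det_layer(s$del, s$det, ev))
  net <- integrate_layers(layers, s$del, s$dem, s$det)
  g <- net$graph
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  # handshake lemma
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  # direction copied from the contrast sets
  expect_equal(igraph::V(g)$direction[igraph::V(g)$name == "G2"],
               s$det$direction[s$det$gene_name == "G2"])
  # endpoint absent from every set is an error
  bad <- layers
  bad[[1]] <- rbind(bad[[1]],
                    data.frame(source = "mZ", target = "G1", layer = "dem_det",
                               evidence = "validated", score = NA_real_))
  expect_error(integrate_layers(bad, s$del, s$dem, s$det), "missing")
})

test_that("hub identification follows the degree threshold exactly", {
  star <- lapply(1:7, function(i) erow("m1", "miRNA", paste0("G", i), "mRNA",
                                       "validated"))
  ev <- interaction_table(do.call(rbind, star))
  dem <- toy_set("m1", biotype = "miRNA")
  det <- toy_set(paste0("G", 1:7), biotype = "mRNA")
  del <- toy_set(character(), biotype = "lncRNA_known")
  net <- integrate_layers(list(build_dem_det_layer(dem, det, ev)),
                          del, dem, det)
  h6 <- identify_hubs(net, 6)
  expect_equal(h6$hubs$id, "m1")
  expect_equal(h6$by_class$miRNA, "m1")
  h1 <- identify_hubs(net, 1)
  expect_equal(nrow(h1$hubs), 8)   # every non-isolated node
})

test_that("display filter uses full-network degrees and is idempotent", {
  ev <- evid_rows(erow("m1", "miRNA", "G1", "mRNA", "validated"),
                  erow("m1", "miRNA", "G2", "mRNA", "validated"))
  dem <- toy_set("m1", biotype = "miRNA")
  det <- toy_set(c("G1", "G2"), biotype = "mRNA")
  del <- toy_set(character(), biotype = "lncRNA_known")
  net <- integrate_layers(list(build_dem_det_layer(dem, det, ev)), del, dem, det)
  # path G1 - m1 - G2: threshold 2 keeps only the centre, no edges survive
  sub <- display_subgraph(net, 2)
  expect_equal(igraph::V(sub$graph)$name, "m1")
  expect_equal(igraph::ecount(sub$graph), 0)
  # identity at 0 and idempotence at fixed threshold
  id0 <- display_subgraph(net, 0)
  expect_equal(igraph::vcount(id0$graph), 3)
  twice <- display_subgraph(sub, 2)
  expect_equal(igraph::V(twice$graph)$name, igraph::V(sub$graph)$name)
})

test_that("SIF and GraphML exports round trip", {
  si <- simulate_interactions(synth_config(seed = 4))
  layers <- list(build_dem_det_layer(si$sets$dem, si$sets$det, si$evidence),
                 build_del_dem_layer(si$sets$del, si$sets$dem, si$evidence),
                 build_del_det_layer(si$sets$del, si$sets$det, si$evidence))
  net <- integrate_layers(layers, si$sets$del, si$sets$dem, si$sets$det)
  sif <- tempfile(fileext = ".sif")
  export_graph(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, igraph::ecount(net$graph))
  expect_true(all(grepl("^\\S+ (dem_det|del_dem|del_det) \\S+$", lines)))
  gml <- tempfile(fileext = ".graphml")
  export_graph(net, gml, "graphml")
  back <- import_graphml(gml)
  g1 <- net$graph; g2 <- back$graph
  expect_equal(igraph::vcount(g2), igraph::vcount(g1))
  expect_equal(igraph::ecount(g2), igraph::ecount(g1))
  o1 <- order(igraph::V(g1)$name); o2 <- order(igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$name[o2], igraph::V(g1)$name[o1])
  expect_equal(igraph::V(g2)$node_class[o2], igraph::V(g1)$node_class[o1])
  expect_equal(igraph::V(g2)$direction[o2], igraph::V(g1)$direction[o1])
  ek <- function(g) {
    el <- igraph::as_edgelist(g)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                 igraph::E(g)$layer, igraph::E(g)$evidence,
                 ifelse(is.na(igraph::E(g)$score), "-",
                        sprintf("%.6f", igraph::E(g)$score)))
    sort(key)
  }
  expect_equal(ek(g2), ek(g1))
  # single-edge SIF line format and empty network documents
  s <- mk_sets()
  ev1 <- evid_rows(erow("m1", "miRNA", "G1", "mRNA", "validated"))
  net1 <- integrate_layers(list(build_dem_det_layer(s$dem, s$det, ev1)),
                           s$del, s$dem, s$det)
  export_graph(net1, sif, "sif")
  expect_equal(readLines(sif), "m1 dem_det G1")
  net0 <- integrate_layers(list(), s$del, s$dem, s$det)
  export_graph(net0, sif, "sif")
  expect_length(readLines(sif), 0)
  export_graph(net0, gml, "graphml")
  expect_equal(igraph::vcount(import_graphml(gml)$graph), 0)
  expect_error(export_graph(net0, sif, "dot"), "arg")
})

test_that("planted synthetic networks are recovered exactly", {
  for (seed in 1:20) {
    si <- simulate_interactions(synth_config(seed = seed))
    l1 <- build_dem_det_layer(si$sets$dem, si$sets$det, si$evidence)
    l2 <- build_del_dem_layer(si$sets$del, si$sets$dem, si$evidence)
    l3 <- build_del_det_layer(si$sets$del, si$sets$det, si$evidence)
    expect_equal(nrow(l1), nrow(si$truth$layers$dem_det))
    expect_equal(nrow(l2), nrow(si$truth$layers$del_dem))
    expect_equal(nrow(l3), nrow(si$truth$layers$del_det))
    net <- integrate_layers(list(l1, l2, l3), si$sets$del, si$sets$dem,
                            si$sets$det)
    d <- node_degrees(net)
    expect_equal(sum(d), 2 * igraph::ecount(net$graph))
    # degrees equal the generator's tabulated ground truth
    truth_d <- si$truth$degrees
    expect_equal(as.numeric(d[names(truth_d)]), as.numeric(truth_d))
    hubs <- identify_hubs(net, 6)
    expect_setequal(hubs$hubs$id, si$truth$hubs_min6)
    # XIST-like emulation: the planted lncRNA has its 264 verified targets
    xl <- si$truth$xist_like
    expect_equal(sum(l3$source == xl), si$truth$xist_like_degree_del_det)
  }
})

test_that("class-pair invariants hold on random evidence tables", {
  set.seed(77)
  ids <- list(mir = paste0("m", 1:8), lnc = paste0("L", 1:5),
              gen = paste0("G", 1:15))
  dem <- toy_set(ids$mir, biotype = "miRNA")
  del <- toy_set(ids$lnc, biotype = "lncRNA_known")
  det <- toy_set(ids$gen, biotype = "mRNA")
  cls <- stats::setNames(c(rep("miRNA", 8), rep("lncRNA", 5), rep("mRNA", 15)),
                         unlist(ids))
  for (i in 1:200) {
    n <- sample(5:25, 1)
    pair_type <- sample(1:3, n, replace = TRUE)
    src <- ifelse(pair_type == 1, sample(ids$mir, n, replace = TRUE),
                  sample(ids$lnc, n, replace = TRUE))
    tgt <- ifelse(pair_type == 1, sample(ids$gen, n, replace = TRUE),
                  ifelse(pair_type == 2, sample(ids$mir, n, replace = TRUE),
                         sample(ids$gen, n, replace = TRUE)))
    ev <- sample(c("validated", "predicted"), n, replace = TRUE)
    sc <- ifelse(ev == "predicted", round(runif(n), 3), NA_real_)
    df <- data.frame(source_id = src, source_class = unname(cls[src]),
                     target_id = tgt, target_class = unname(cls[tgt]),
                     evidence = ev, score = sc, stringsAsFactors = FALSE)
    df <- df[!duplicated(paste(df$source_id, df$target_id, df$evidence)), ]
    tab <- interaction_table(df)
    layers <- list(build_dem_det_layer(dem, det, tab),
                   build_del_dem_layer(del, dem, tab),
                   build_del_det_layer(del, det, tab))
    net <- integrate_layers(layers, del, dem, det)
    expect_true(ncnet:::validate_tripartite(net$graph))
  }
})
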