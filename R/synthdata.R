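#' @title Seeded synthetic-data generators with ground truth
#' @name ncnet-synthdata
#' @description Generators for every input the pipeline consumes -- small-RNA
#'   count matrices with planted differential expression, interaction-evidence
#'   tables with planted tripartite structure and hubs, pathway collections
#'   with a planted enriched term, and qPCR plates with planted fold changes --
#'   together with the ground truth needed to score recovery. Generation is a
#'   pure function of the configuration: the same seed yields byte-identical
#'   outputs. Each generator draws from its own stream, derived as
#'   `seed + stage offset` (counts +1, interactions +2, qPCR +3, pathways +4).
NULL

#' Synthetic-data configuration
#'
#' Defaults emulate the study design the package targets: four subject groups
#' (Nw control, Ob, NwCRC, ObCRC) with six replicates each; miRNA fold-change
#' magnitudes spanning the published differential-miRNA table (|log2FC| in
#' [0.48, 1.56]); lncRNAs with a separate regime including on/off
#' (presence/absence) features; NB dispersion 0.15; 5e5 assigned reads per
#' sample.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default field (see the function body).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    groups = c("Nw", "Ob", "NwCRC", "ObCRC"),
    control_group = NULL,
    n_per_group = 6L,
    n_mirna = 500L, n_lncrna = 60L,
    de_fraction = c(mirna = 0.1, lncrna = 0.2),
    lfc_range_mirna = c(0.48, 1.56),
    lfc_range_lncrna = c(1, 8),
    onoff_fraction = 0.25,            # of planted DE lncRNAs
    phi = 0.15,
    library_size = 5e5,
    depth_range = c(0.7, 1.3),        # per-sample depth multipliers
    # interaction-structure settings (one contrast)
    n_dem = 15L, n_del = 10L, n_det = 400L,
    n_decoy_mirna = 10L, n_decoy_lncrna = 5L, n_decoy_mrna = 50L,
    hub_spec = list(n_mirna_hubs = 5L, mirna_hub_degree = 20L,
                    n_lncrna_hubs = 3L, lncrna_hub_degree = 8L,
                    xist_like_degree = 264L),
    score_range = c(0.05, 1),
    score_cutoff = 0.6,
    qpcr_sigma = 0.2
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$control_group)) cfg$control_group <- cfg$groups[1]
  stopifnot(cfg$control_group %in% cfg$groups,
            cfg$n_per_group >= 2, cfg$phi >= 0, cfg$library_size > 0,
            all(cfg$de_fraction >= 0 & cfg$de_fraction <= 1),
            cfg$onoff_fraction >= 0, cfg$onoff_fraction <= 1)
  structure(cfg, class = "synth_config")
}

# evaluate expr under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate a small-RNA count matrix with planted differential expression
#'
#' Counts are negative-binomial: `NB(mean = rate x depth x library_size,
#' dispersion phi)`; `phi = 0` degenerates to Poisson. Planted DE features
#' receive group-specific rate multipliers `2^log2fc`; planted on/off lncRNAs
#' have rate exactly zero on one side of their contrast, yielding the extreme
#' presence/absence fold changes real lncRNA tables show.
#'
#' @param cfg a [synth_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`: `lfc`
#'   (features x disease-groups matrix of planted log2 fold changes, `Inf`
#'   magnitude encoded for on/off features), `per_contrast` (named list of
#'   data.frames `feature_id, log2fc, direction, onoff` restricted to planted
#'   DE features).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 1L, {
    groups <- cfg$groups
    disease <- setdiff(groups, cfg$control_group)
    feat <- c(if (cfg$n_mirna) sprintf("mir%03d", seq_len(cfg$n_mirna)),
              if (cfg$n_lncrna) sprintf("lnc%03d", seq_len(cfg$n_lncrna)))
    cls <- rep(c("mirna", "lncrna"), c(cfg$n_mirna, cfg$n_lncrna))
    nf <- length(feat)
    ab <- rgamma(nf, shape = 0.5, rate = 1) + 1e-6
    ab <- ab / sum(ab)
    lfc <- matrix(0, nf, length(disease), dimnames = list(feat, disease))
    onoff <- matrix(FALSE, nf, length(disease), dimnames = list(feat, disease))
    rate <- matrix(ab, nf, length(groups), dimnames = list(feat, groups))
    for (g in disease) {
      for (klass in c("mirna", "lncrna")) {
        idx <- which(cls == klass)
        if (!length(idx)) next
        nde <- round(cfg$de_fraction[[klass]] * length(idx))
        if (!nde) next
        de <- sample(idx, nde)
        sgn <- sample(c(-1, 1), nde, replace = TRUE)
        rng <- if (klass == "mirna") cfg$lfc_range_mirna else cfg$lfc_range_lncrna
        mag <- runif(nde, rng[1], rng[2])
        lfc[de, g] <- sgn * mag
        if (klass == "lncrna" && cfg$onoff_fraction > 0) {
          noo <- round(cfg$onoff_fraction * nde)
          if (noo) {
            oo <- de[seq_len(noo)]
            onoff[oo, g] <- TRUE
            lfc[oo, g] <- sign(lfc[oo, g]) * Inf
          }
        }
      }
      mult <- 2^lfc[, g]
      mult[lfc[, g] == Inf] <- NA   # handled below
      rate[, g] <- ab * ifelse(is.na(mult), 0, mult)
      # on/off up: expressed in disease only -> silence the control side by
      # giving the disease group a plain expressed rate and zeroing control
      up_oo <- onoff[, g] & lfc[, g] > 0
      rate[up_oo, g] <- ab[up_oo] * 4      # clearly expressed in disease
      down_oo <- onoff[, g] & lfc[, g] < 0
      rate[down_oo, g] <- 0
    }
    # on/off "up" features must be absent from control
    any_up_oo <- apply(onoff & lfc > 0, 1, any)
    rate[any_up_oo, cfg$control_group] <- 0
    for (g in disease) {
      silent <- any_up_oo & lfc[, g] == 0   # not DE in g: follows control
      rate[silent, g] <- 0
    }
    samples <- paste0(rep(groups, each = cfg$n_per_group), "_",
                      seq_len(cfg$n_per_group))
    depth <- runif(length(samples), cfg$depth_range[1], cfg$depth_range[2])
    counts <- matrix(0, nf, length(samples), dimnames = list(feat, samples))
    for (j in seq_along(samples)) {
      g <- rep(groups, each = cfg$n_per_group)[j]
      mu <- rate[, g] * depth[j] * cfg$library_size
      counts[, j] <- if (cfg$phi == 0) rpois(nf, mu)
                     else rnbinom(nf, mu = mu, size = 1 / cfg$phi)
    }
    per_contrast <- lapply(disease, function(g) {
      de <- which(lfc[, g] != 0)
      data.frame(feature_id = feat[de], log2fc = lfc[de, g],
                 direction = ifelse(lfc[de, g] > 0, "up", "down"),
                 onoff = onoff[de, g], stringsAsFactors = FALSE)
    })
    names(per_contrast) <- paste0(disease, "_vs_", cfg$control_group)
    list(counts = count_matrix(counts,
                               rep(groups, each = cfg$n_per_group)),
         truth = list(lfc = lfc, onoff = onoff, per_contrast = per_contrast))
  })
}

#' Simulate interaction evidence with planted tripartite structure
#'
#' Generates, for one contrast, differential miRNA/lncRNA/mRNA sets, an
#' evidence table emulating TarBase/miRTarBase (validated miRNA-mRNA),
#' DIANA-LncBase (scored predicted lncRNA-miRNA), and ENCORI (verified
#' lncRNA-miRNA and lncRNA-mRNA) exports, and the ground-truth network.
#' Planted structure includes miRNA hubs of prescribed degree and one
#' high-degree lncRNA with `hub_spec$xist_like_degree` verified mRNA targets
#' (the XIST-like pattern). Decoy rows exercise every filter: edges touching
#' non-differential molecules, predicted miRNA-mRNA rows, predicted
#' lncRNA-mRNA rows, and predicted lncRNA-miRNA rows below the score cutoff.
#'
#' @param cfg a [synth_config()].
#' @return list with `sets` (contrast sets `del`, `dem`, `det`), `evidence`
#'   (an [interaction_table()]), and `truth`: per-layer expected edge
#'   data.frames, expected node degrees, expected hub ids at `min_degree = 6`,
#'   and the XIST-like lncRNA id.
#' @export
simulate_interactions <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 2L, {
    hub <- cfg$hub_spec
    stopifnot(cfg$n_det >= hub$xist_like_degree)
    dem_ids <- sprintf("miR-s%02d", seq_len(cfg$n_dem))
    del_ids <- sprintf("LNC-S%02d", seq_len(cfg$n_del))
    det_ids <- sprintf("GENE%03d", seq_len(cfg$n_det))
    dx_mir <- sprintf("miR-x%02d", seq_len(cfg$n_decoy_mirna))
    dx_lnc <- sprintf("LNC-X%02d", seq_len(cfg$n_decoy_lncrna))
    dx_gen <- sprintf("GENX%03d", seq_len(cfg$n_decoy_mrna))

    mk_set <- function(ids, biotype) {
      lfc <- sample(c(-1, 1), length(ids), replace = TRUE) *
        runif(length(ids), 0.5, 3)
      build_contrast_set(contrast_table(data.frame(
        feature_id = ids, gene_name = ids, biotype = biotype,
        log2fc = lfc, fdr = 0.01, stringsAsFactors = FALSE),
        "synthetic_vs_control"))
    }
    dem <- mk_set(dem_ids, "miRNA")
    del <- mk_set(del_ids, "lncRNA_known")
    det <- mk_set(det_ids, "mRNA")

    rows <- list()
    truth_edges <- list(dem_det = list(), del_dem = list(), del_det = list())
    add <- function(src, scls, tgt, tcls, ev, score = NA_real_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        source_id = src, source_class = scls, target_id = tgt,
        target_class = tcls, evidence = ev, score = score,
        stringsAsFactors = FALSE)
    }

    # --- miRNA-mRNA layer: hubs then background ---------------------------
    deg <- integer(0)
    for (i in seq_along(dem_ids)) {
      d <- if (i <= hub$n_mirna_hubs) hub$mirna_hub_degree
           else sample(1:4, 1)
      tg <- sample(det_ids, d)
      add(dem_ids[i], "miRNA", tg, "mRNA", "validated")
      truth_edges$dem_det[[i]] <- data.frame(source = dem_ids[i], target = tg,
                                             stringsAsFactors = FALSE)
    }
    # decoys: validated edges to non-DET genes, from non-DEM miRNAs, and
    # predicted miRNA-mRNA rows (all must be excluded downstream)
    add(dem_ids[1], "miRNA", sample(dx_gen, 5), "mRNA", "validated")
    add(dx_mir[1], "miRNA", sample(det_ids, 5), "mRNA", "validated")
    add(dem_ids[2], "miRNA", sample(det_ids, 3), "mRNA", "predicted",
        runif(3, 0.7, 1))

    # --- lncRNA-miRNA layer ----------------------------------------------
    for (i in seq_along(del_ids)) {
      d <- if (i <= hub$n_lncrna_hubs) hub$lncrna_hub_degree
           else sample(1:3, 1)
      d <- min(d, length(dem_ids))
      tg <- sample(dem_ids, d)
      ev <- sample(c("validated", "predicted"), d, replace = TRUE)
      sc <- ifelse(ev == "predicted",
                   runif(d, cfg$score_range[1], cfg$score_range[2]), NA_real_)
      add(del_ids[i], "lncRNA", tg, "miRNA", ev, sc)
      keep <- ev == "validated" | (!is.na(sc) & sc >= cfg$score_cutoff)
      if (any(keep))
        truth_edges$del_dem[[i]] <- data.frame(source = del_ids[i],
                                               target = tg[keep],
                                               stringsAsFactors = FALSE)
    }
    # decoys: non-DEL source; predicted rows to non-DEM targets
    add(dx_lnc[1], "lncRNA", sample(dem_ids, 3), "miRNA", "validated")
    add(del_ids[1], "lncRNA", sample(dx_mir, 3), "miRNA", "predicted",
        runif(3, 0.7, 1))

    # --- lncRNA-mRNA layer: the XIST-like high-degree node ---------------
    xist_like <- del_ids[1]
    xtg <- sample(det_ids, hub$xist_like_degree)
    add(xist_like, "lncRNA", xtg, "mRNA", "validated")
    truth_edges$del_det[[1]] <- data.frame(source = xist_like, target = xtg,
                                           stringsAsFactors = FALSE)
    for (i in seq_along(del_ids)[-1]) {
      d <- sample(0:4, 1)
      if (!d) next
      tg <- sample(det_ids, d)
      add(del_ids[i], "lncRNA", tg, "mRNA", "validated")
      truth_edges$del_det[[i]] <- data.frame(source = del_ids[i], target = tg,
                                             stringsAsFactors = FALSE)
    }
    # decoys: predicted lncRNA-mRNA (verified-only layer must drop them)
    add(del_ids[2], "lncRNA", sample(det_ids, 3), "mRNA", "predicted",
        runif(3, 0.7, 1))

    evidence <- interaction_table(do.call(rbind, rows))
    truth_layers <- lapply(truth_edges, function(l)
      if (length(l)) do.call(rbind, l) else
        data.frame(source = character(), target = character()))
    all_e <- do.call(rbind, truth_layers)
    degv <- table(unlist(all_e))
    hubs6 <- sort(names(degv)[degv >= 6])
    list(sets = list(del = del, dem = dem, det = det),
         evidence = evidence,
         truth = list(layers = truth_layers,
                      degrees = degv,
                      hubs_min6 = hubs6,
                      xist_like = xist_like,
                      xist_like_degree_del_det = hub$xist_like_degree))
  })
}

#' Simulate a pathway collection with one planted enriched term
#'
#' The planted term's members are drawn entirely from the query, so it is
#' strongly over-represented; the remaining terms are random draws from the
#' universe.
#'
#' @param cfg a [synth_config()].
#' @param universe background gene symbols.
#' @param query query gene symbols (subset of `universe`).
#' @param n_random number of random terms (default 50).
#' @param planted_size members of the planted term (default 10).
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `planted_term` (its id, `"PLANTED"`).
#' @export
simulate_pathways <- function(cfg, universe, query, n_random = 50L,
                              planted_size = 10L) {
  stopifnot(inherits(cfg, "synth_config"), all(query %in% universe),
            planted_size <= length(query))
  with_seed(cfg$seed + 4L, {
    sets <- list(PLANTED = sample(query, planted_size))
    for (i in seq_len(n_random)) {
      sz <- sample(10:40, 1)
      sets[[sprintf("RAND%03d", i)]] <- sample(universe, min(sz, length(universe)))
    }
    list(collection = gene_set_collection(sets), planted_term = "PLANTED")
  })
}

#' Simulate a qPCR plate from planted group fold changes
#'
#' For each assay, target Ct is a per-assay baseline minus `log2(fold)` of the
#' sample's group plus Gaussian noise; reference Ct is a stable baseline plus
#' noise. With zero noise, [ddct_fold()] inverts the planted folds exactly
#' (up to control-group centering).
#'
#' @param cfg a [synth_config()]; `qpcr_sigma` is the Ct noise SD in cycles.
#' @param folds data.frame `assay_id, group, fold` of planted fold changes
#'   relative to the control group (control rows may be omitted; fold 1
#'   assumed).
#' @param reference_assay reference-assay label recorded on the plate
#'   (default "GUSB").
#' @return A [qpcr_plate()].
#' @export
simulate_qpcr <- function(cfg, folds, reference_assay = "GUSB") {
  stopifnot(inherits(cfg, "synth_config"),
            all(c("assay_id", "group", "fold") %in% names(folds)))
  with_seed(cfg$seed + 3L, {
    assays <- unique(folds$assay_id)
    base <- stats::setNames(runif(length(assays), 22, 30), assays)
    rows <- list()
    for (a in assays) {
      for (g in cfg$groups) {
        f <- folds$fold[folds$assay_id == a & folds$group == g]
        f <- if (length(f)) f[1] else 1
        for (i in seq_len(cfg$n_per_group)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste0(g, "_", i), group = g, assay_id = a,
            ct_target = base[[a]] - log2(f) + rnorm(1, 0, cfg$qpcr_sigma),
            ct_reference = 20 + rnorm(1, 0, cfg$qpcr_sigma),
            reference_assay = reference_assay, stringsAsFactors = FALSE)
        }
      }
    }
    qpcr_plate(do.call(rbind, rows))
  })
}
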