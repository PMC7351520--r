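#' @title Pipeline orchestration
#' @name ncnet-pipeline
#' @description Runs the full analysis in dependency order -- contrast tables
#'   (shipped fixtures, user files, or DE called from a count matrix), overlap
#'   analysis, per-contrast tripartite network with hubs, enrichment, qPCR --
#'   and writes per-stage outputs plus a machine-readable `summary.json`.
#'   All referenced files are checked before any computation (fail-fast);
#'   re-running on the same inputs and seed reproduces `summary.json`
#'   byte-for-byte.
NULL

#' Assemble and validate a pipeline configuration
#'
#' @param del,dem named character vectors of per-contrast table paths (names
#'   are contrast ids), or `"fixtures"` to use the shipped curated tables.
#' @param det optional named character vector of per-contrast mRNA (DET)
#'   table paths; required for the network stage.
#' @param evidence optional interaction-evidence TSV path.
#' @param gmt optional pathway GMT path (enrichment stage).
#' @param plate optional qPCR plate TSV path.
#' @param counts,groups optional count-matrix and group-map TSVs; when given,
#'   miRNA contrast tables are called from counts instead of read from `dem`.
#' @param out_dir output directory (created if needed).
#' @param fdr_lncrna,fdr_mirna,min_reads,score_cutoff,hub_min_degree,enrich_alpha
#'   stage thresholds (defaults 0.05, 0.06, 10, 0.6, 6, 0.05).
#' @param control_group control group label (default "Nw").
#' @param seed integer seed recorded in the summary and used for any
#'   randomised stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(del = "fixtures", dem = "fixtures", det = NULL,
                            evidence = NULL, gmt = NULL, plate = NULL,
                            counts = NULL, groups = NULL,
                            out_dir = "ncnet_run",
                            fdr_lncrna = 0.05, fdr_mirna = 0.06,
                            min_reads = 10L, score_cutoff = 0.6,
                            hub_min_degree = 6L, enrich_alpha = 0.05,
                            control_group = "Nw", seed = 1L) {
  cfg <- list(del = del, dem = dem, det = det, evidence = evidence,
              gmt = gmt, plate = plate, counts = counts, groups = groups,
              out_dir = out_dir,
              thresholds = list(fdr_lncrna = fdr_lncrna,
                                fdr_mirna = fdr_mirna,
                                min_reads = as.integer(min_reads),
                                score_cutoff = score_cutoff,
                                hub_min_degree = as.integer(hub_min_degree),
                                enrich_alpha = enrich_alpha),
              control_group = control_group, seed = as.integer(seed))
  th <- cfg$thresholds
  stopifnot(th$fdr_lncrna > 0, th$fdr_lncrna < 1, th$fdr_mirna > 0,
            th$fdr_mirna < 1, th$min_reads >= 0, th$score_cutoff >= 0,
            th$score_cutoff <= 1, th$hub_min_degree >= 1,
            th$enrich_alpha > 0, th$enrich_alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("del", "dem", "det"))
    if (is.list(y[[k]])) y[[k]] <- unlist(y[[k]])
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Stages (in dependency order): load or call the contrast tables; gene-level
#' overlap analysis; per-contrast network construction with hub report and
#' GraphML export (when `det` + `evidence` configured); enrichment of the
#' network's mRNA targets against the DET universe (when `gmt` configured);
#' qPCR validation (when `plate` configured). Any missing input file aborts
#' before computation; any stage error aborts with the stage named.
#'
#' @param cfg a [pipeline_config()] or path to a YAML file.
#' @return The summary list (also written to `out_dir/summary.json`),
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  th <- cfg$thresholds

  # fail fast: every referenced file must exist before any work starts
  paths <- c(if (!identical(cfg$del, "fixtures")) cfg$del,
             if (!identical(cfg$dem, "fixtures") && is.null(cfg$counts)) cfg$dem,
             cfg$det, cfg$evidence, cfg$gmt, cfg$plate, cfg$counts, cfg$groups)
  paths <- as.character(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  del_tables <- stage("load_del", {
    if (identical(cfg$del, "fixtures")) load_del_tables()
    else mapply(read_contrast_table, cfg$del, names(cfg$del),
                SIMPLIFY = FALSE)
  })
  dem_tables <- stage("load_dem", {
    if (!is.null(cfg$counts)) {
      m <- read_count_matrix(cfg$counts, cfg$groups)
      disease <- setdiff(unique(m$groups), cfg$control_group)
      tabs <- lapply(disease, function(g) {
        de <- de_analysis(m, cfg$control_group, g,
                          min_reads = th$min_reads,
                          fdr_threshold = th$fdr_mirna)
        de <- de[de$call != "ns", , drop = FALSE]
        cid <- paste0(g, "_vs_", cfg$control_group)
        write_tsv_plain(de, file.path(cfg$out_dir, paste0("de_", cid, ".tsv")))
        contrast_table(data.frame(feature_id = de$feature_id,
                                  gene_name = de$feature_id,
                                  biotype = "miRNA", log2fc = de$log2fc,
                                  fdr = de$fdr), cid)
      })
      stats::setNames(tabs, paste0(disease, "_vs_", cfg$control_group))
    } else if (identical(cfg$dem, "fixtures")) load_dem_tables()
    else mapply(read_contrast_table, cfg$dem, names(cfg$dem),
                SIMPLIFY = FALSE)
  })

  summary <- list(parameters = th, seed = cfg$seed)

  if (length(del_tables) == 3L && length(dem_tables) == 3L) {
    ov <- stage("overlaps", overlap_summary(del_tables, dem_tables))
    summary$overlaps <- list(
      del_regions = as.list(ov$del$venn$region_counts),
      dem_regions = as.list(ov$dem$venn$region_counts),
      del_tallies = ov$del$tallies,
      dem_tallies = ov$dem$tallies,
      n_del_triple = length(venn_region(ov$del$venn,
                                        ov$del$venn$contrast_ids)),
      n_dem_triple = length(venn_region(ov$dem$venn,
                                        ov$dem$venn$contrast_ids)),
      shared_obesity_cancer = ov$shared_obesity_cancer,
      n_shared_obesity_cancer = length(ov$shared_obesity_cancer),
      n_novel_lncrna = ov$n_novel_lncrna)
    jsonlite::write_json(summary$overlaps,
                         file.path(cfg$out_dir, "venn.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  if (!is.null(cfg$det) && !is.null(cfg$evidence)) {
    nets <- stage("network", {
      evid <- read_interaction_table(cfg$evidence)
      lapply(names(cfg$det), function(cid) {
        det <- build_contrast_set(read_contrast_table(cfg$det[[cid]], cid))
        dem <- build_contrast_set(dem_tables[[cid]])
        del <- build_contrast_set(del_tables[[cid]])
        layers <- list(build_dem_det_layer(dem, det, evid),
                       build_del_dem_layer(del, dem, evid, th$score_cutoff),
                       build_del_det_layer(del, det, evid))
        net <- integrate_layers(layers, del, dem, det)
        export_graph(net, file.path(cfg$out_dir, paste0("net_", cid, ".graphml")))
        list(cid = cid, net = net, det = det,
             hubs = identify_hubs(net, th$hub_min_degree))
      })
    })
    summary$networks <- lapply(nets, function(x) list(
      contrast = x$cid,
      n_nodes = igraph::vcount(x$net$graph),
      n_edges = igraph::ecount(x$net$graph),
      hubs = x$hubs$by_class))

    if (!is.null(cfg$gmt)) {
      enr <- stage("enrich", {
        terms <- read_gmt(cfg$gmt)
        lapply(nets, function(x) {
          g <- x$net$graph
          targets <- igraph::V(g)$name[igraph::V(g)$node_class == "mRNA"]
          universe <- x$det$gene_name
          dirs <- stats::setNames(x$det$direction, x$det$gene_name)
          res <- enrich_collection(targets, universe, terms,
                                   directions = dirs, alpha = th$enrich_alpha)
          res <- kappa_group_terms(res, targets)
          write_tsv_plain(as.data.frame(res),
                          file.path(cfg$out_dir,
                                    paste0("enrich_", x$cid, ".tsv")))
          list(contrast = x$cid,
               significant_terms = res$term_id[res$significant])
        })
      })
      summary$enrichment <- enr
    }
  }

  if (!is.null(cfg$plate)) {
    qp <- stage("qpcr", {
      plate <- read_qpcr_plate(cfg$plate)
      qpcr_validate(plate, cfg$control_group)
    })
    summary$qpcr <- lapply(names(qp$tests), function(a) {
      tt <- qp$tests[[a]]
      list(assay = a, f = tt$f, p_omnibus = tt$p_omnibus,
           pairwise = tt$pairwise)
    })
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(summary)
}
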