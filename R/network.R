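#' @title Tripartite lncRNA-miRNA-mRNA network construction and hub analysis
#' @name ncnet-network
#' @description Builds the three evidence layers of a competing-endogenous-RNA
#'   network -- validated miRNA-mRNA targets, scored/verified lncRNA-miRNA
#'   interactions, verified lncRNA-mRNA interactions -- restricted to the
#'   differentially expressed molecules of one contrast, integrates them into
#'   one undirected tripartite graph, identifies hub nodes by degree, filters
#'   for display, and exports SIF/GraphML for Cytoscape.
NULL

LAYER_PAIRS <- list(dem_det = c("miRNA", "mRNA"),
                    del_dem = c("lncRNA", "miRNA"),
                    del_det = c("lncRNA", "mRNA"))

empty_layer <- function(layer) {
  data.frame(source = character(), target = character(),
             layer = character(), evidence = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

make_layer <- function(source, target, layer, evidence, score) {
  data.frame(source = source, target = target, layer = layer,
             evidence = evidence, score = score, stringsAsFactors = FALSE)
}

#' Build the miRNA-mRNA (DEM-DET) evidence layer
#'
#' An edge (m, g) is included iff `m` is a differential miRNA, `g` a
#' differential transcript, and a *validated* miRNA-to-mRNA evidence row
#' exists. Predicted miRNA-mRNA rows are ignored: this layer emulates
#' TarBase/miRTarBase exports, which are experimentally validated.
#'
#' @param dem,det [build_contrast_set()]s of the differential miRNAs and
#'   transcripts of one contrast.
#' @param evidence an [interaction_table()].
#' @return Edge data.frame `source, target, layer, evidence, score`.
#' @export
build_dem_det_layer <- function(dem, det, evidence) {
  stopifnot(inherits(dem, "contrast_set"), inherits(det, "contrast_set"),
            inherits(evidence, "interaction_table"))
  e <- evidence[evidence$source_class == "miRNA" &
                evidence$target_class == "mRNA" &
                evidence$evidence == "validated" &
                evidence$source_id %in% dem$gene_name &
                evidence$target_id %in% det$gene_name, , drop = FALSE]
  if (!nrow(e)) return(empty_layer("dem_det"))
  e <- e[!duplicated(paste(e$source_id, e$target_id, sep = "\r")), ]
  make_layer(e$source_id, e$target_id, "dem_det", e$evidence, NA_real_)
}

#' Build the lncRNA-miRNA (DEL-DEM) evidence layer
#'
#' An edge (l, m) is included iff both molecules are differential and the
#' evidence is either verified, or predicted with score at or above the
#' cutoff (boundary inclusive: 0.60 passes the default cutoff, 0.59 does
#' not). Predicted and verified sources are unioned; when a pair occurs in
#' both, the stored evidence is `"validated"`.
#'
#' @param del,dem [build_contrast_set()]s of one contrast.
#' @param evidence an [interaction_table()].
#' @param score_cutoff minimum prediction score (default 0.6).
#' @return Edge data.frame as in [build_dem_det_layer()].
#' @export
build_del_dem_layer <- function(del, dem, evidence, score_cutoff = 0.6) {
  stopifnot(inherits(del, "contrast_set"), inherits(dem, "contrast_set"),
            inherits(evidence, "interaction_table"))
  e <- evidence[evidence$source_class == "lncRNA" &
                evidence$target_class == "miRNA" &
                evidence$source_id %in% del$gene_name &
                evidence$target_id %in% dem$gene_name, , drop = FALSE]
  keep <- e$evidence == "validated" |
          (e$evidence == "predicted" & e$score >= score_cutoff)
  e <- e[keep, , drop = FALSE]
  if (!nrow(e)) return(empty_layer("del_dem"))
  # validated precedence on duplicate pairs
  e <- e[order(e$source_id, e$target_id, e$evidence != "validated"), ]
  e <- e[!duplicated(paste(e$source_id, e$target_id, sep = "\r")), ]
  score <- ifelse(e$evidence == "validated", NA_real_, e$score)
  make_layer(e$source_id, e$target_id, "del_dem", e$evidence, score)
}

#' Build the lncRNA-mRNA (DEL-DET) evidence layer
#'
#' Verified interactions only (the ENCORI convention); predicted lncRNA-mRNA
#' rows are never admitted.
#'
#' @param del,det [build_contrast_set()]s of one contrast.
#' @param evidence an [interaction_table()].
#' @return Edge data.frame as in [build_dem_det_layer()].
#' @export
build_del_det_layer <- function(del, det, evidence) {
  stopifnot(inherits(del, "contrast_set"), inherits(det, "contrast_set"),
            inherits(evidence, "interaction_table"))
  e <- evidence[evidence$source_class == "lncRNA" &
                evidence$target_class == "mRNA" &
                evidence$evidence == "validated" &
                evidence$source_id %in% del$gene_name &
                evidence$target_id %in% det$gene_name, , drop = FALSE]
  if (!nrow(e)) return(empty_layer("del_det"))
  e <- e[!duplicated(paste(e$source_id, e$target_id, sep = "\r")), ]
  make_layer(e$source_id, e$target_id, "del_det", e$evidence, NA_real_)
}

#' Integrate the three evidence layers into one tripartite network
#'
#' Nodes are the union of edge endpoints (no isolated nodes); each node
#' carries its molecule class (from the layer semantics) and regulation
#' direction (copied from the contrast sets). The graph is undirected; "degree"
#' throughout the package is the count of incident edges across all layers.
#'
#' @param layers list of edge data.frames from the three `build_*_layer()`
#'   functions (any subset; may be empty).
#' @param del,dem,det the [build_contrast_set()]s the layers were built from,
#'   used to annotate node directions.
#' @return A `tripartite_network` (an igraph graph with vertex attributes
#'   `node_class`, `direction` and edge attributes `layer`, `evidence`,
#'   `score`).
#' @export
integrate_layers <- function(layers, del, dem, det) {
  stopifnot(is.list(layers))
  edges <- do.call(rbind, lapply(layers, function(l) {
    stopifnot(is.data.frame(l))
    l
  }))
  if (is.null(edges) || !nrow(edges)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::V(g)$name <- character()
    return(structure(list(graph = g), class = "tripartite_network"))
  }
  classes <- c(mRNA = "mRNA", miRNA = "miRNA", lncRNA = "lncRNA")
  src_class <- vapply(edges$layer, function(l) LAYER_PAIRS[[l]][1], "")
  tgt_class <- vapply(edges$layer, function(l) LAYER_PAIRS[[l]][2], "")
  nodes <- unique(data.frame(
    id = c(edges$source, edges$target),
    node_class = c(src_class, tgt_class), stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$id))
    stop("node(s) assigned conflicting classes: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  dir_lookup <- function(cls, id) {
    s <- switch(cls, miRNA = dem, lncRNA = del, mRNA = det)
    d <- s$direction[match(id, s$gene_name)]
    d
  }
  nodes$direction <- mapply(dir_lookup, nodes$node_class, nodes$id)
  if (any(is.na(nodes$direction)))
    stop("edge endpoint(s) missing from every contrast set: ",
         paste(nodes$id[is.na(nodes$direction)], collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "layer", "evidence", "score")],
    directed = FALSE, vertices = nodes)
  validate_tripartite(g)
  structure(list(graph = g), class = "tripartite_network")
}

# invariant checks: legal class pair per layer, no self loops, no duplicate
# pairs within a layer
validate_tripartite <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(TRUE))
  el <- igraph::as_edgelist(g)
  layer <- igraph::E(g)$layer
  cls <- stats::setNames(igraph::V(g)$node_class, igraph::V(g)$name)
  for (i in seq_len(nrow(el))) {
    want <- LAYER_PAIRS[[layer[i]]]
    got <- sort(unname(cls[el[i, ]]))
    if (!identical(got, sort(want)))
      stop("edge ", el[i, 1], "--", el[i, 2], " violates layer ", layer[i])
  }
  if (any(el[, 1] == el[, 2])) stop("self edge in network")
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), layer)
  if (anyDuplicated(key)) stop("duplicate edge within a layer")
  invisible(TRUE)
}

#' Node degrees of a tripartite network
#'
#' @param net a [integrate_layers()] result.
#' @return Named integer vector: incident-edge count per node over all layers.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  igraph::degree(net$graph)
}

#' Identify hub nodes by degree
#'
#' Hubs are nodes whose degree in the full integrated network meets the
#' threshold; the default of 6 encodes the "degree exceeding 5" key-player
#' criterion. Reported per molecule class, sorted by degree descending then id
#' ascending.
#'
#' @param net a `tripartite_network`.
#' @param min_degree minimum degree (default 6).
#' @return A `hub_report`: list with `hubs` (data.frame `id, node_class,
#'   degree`), `by_class` (named list of id vectors), `min_degree`.
#' @export
identify_hubs <- function(net, min_degree = 6L) {
  stopifnot(inherits(net, "tripartite_network"), min_degree >= 1)
  d <- igraph::degree(net$graph)
  g <- net$graph
  df <- data.frame(id = igraph::V(g)$name,
                   node_class = igraph::V(g)$node_class,
                   degree = as.integer(d), stringsAsFactors = FALSE)
  df <- df[df$degree >= min_degree, , drop = FALSE]
  df <- df[order(-df$degree, df$id), , drop = FALSE]
  rownames(df) <- NULL
  by_class <- lapply(c(lncRNA = "lncRNA", miRNA = "miRNA", mRNA = "mRNA"),
                     function(cl) df$id[df$node_class == cl])
  structure(list(hubs = df, by_class = by_class,
                 min_degree = as.integer(min_degree)),
            class = "hub_report")
}

#' Display filter: keep only well-connected nodes
#'
#' Keeps the nodes whose degree in the *full* network meets `min_degree`
#' (figure-legend semantics: low-degree nodes of the full network are hidden,
#' degrees are not recomputed after removal), plus every edge whose both
#' endpoints are kept. Idempotent for a fixed threshold.
#'
#' @param net a `tripartite_network`.
#' @param min_degree minimum full-network degree (>= 0; 0 is the identity).
#' @return The filtered `tripartite_network`; the pre-filter degrees of the
#'   kept nodes are stored in vertex attribute `full_degree`.
#' @export
display_subgraph <- function(net, min_degree) {
  stopifnot(inherits(net, "tripartite_network"), min_degree >= 0)
  g <- net$graph
  full <- igraph::V(g)$full_degree
  if (is.null(full)) full <- as.integer(igraph::degree(g))
  igraph::V(g)$full_degree <- full
  keep <- full >= min_degree
  sub <- igraph::induced_subgraph(g, which(keep))
  structure(list(graph = sub), class = "tripartite_network")
}

#' Export a tripartite network for Cytoscape
#'
#' SIF: one line per edge, `source <layer> target`. GraphML: vertex attributes
#' `node_class` and `direction`, edge attributes `layer`, `evidence`, `score`;
#' re-importing with [import_graphml()] reproduces the network exactly.
#'
#' @param net a `tripartite_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "sif")) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(format)
  g <- net$graph
  if (format == "sif") {
    if (igraph::ecount(g) == 0) {
      writeLines(character(), path)
    } else {
      el <- igraph::as_edgelist(g)
      writeLines(paste(el[, 1], igraph::E(g)$layer, el[, 2]), path)
    }
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' @param path a file written by [export_graph()] with `format = "graphml"`.
#' @return A `tripartite_network`.
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # igraph stores NA numeric attributes as NaN in GraphML
  if ("score" %in% igraph::edge_attr_names(g))
    igraph::E(g)$score[is.nan(igraph::E(g)$score)] <- NA_real_
  if ("id" %in% igraph::vertex_attr_names(g) &&
      !"name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name <- igraph::V(g)$id
  net <- structure(list(graph = g), class = "tripartite_network")
  validate_tripartite(g)
  net
}

#' @export
print.tripartite_network <- function(x, ...) {
  g <- x$graph
  tab <- table(factor(igraph::V(g)$node_class,
                      c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "tripartite_network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
    igraph::vcount(g), tab[["lncRNA"]], tab[["miRNA"]], tab[["mRNA"]],
    igraph::ecount(g)))
  invisible(x)
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub_report (degree >= %d): %d hub(s)\n",
              x$min_degree, nrow(x$hubs)))
  print(x$hubs)
  invisible(x)
}
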