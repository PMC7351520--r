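#' @title Gene-level contrast sets and multi-contrast overlap analysis
#' @name ncnet-setops
#' @description Collapses per-transcript contrast tables to gene-level
#'   direction-annotated sets and computes the three-set Venn partition and
#'   derived overlap statistics. Overlap counting is at gene-symbol level: a
#'   gene whose transcripts are inversely modulated ("mixed") still counts
#'   once, mirroring how the source study counts e.g. NUTM2A-AS1 as one DEL.
NULL

#' Collapse a contrast table to a gene-level direction-annotated set
#'
#' One entry per distinct gene symbol. A gene is `"up"` or `"down"` when all
#' its transcript rows share the fold-change sign, `"mixed"` when at least two
#' rows disagree. Every differential row must have a sign; a zero log2 fold
#' change is a validation error.
#'
#' @param t a [contrast_table()].
#' @return A `contrast_set`: data.frame `gene_name, direction, n_transcripts,
#'   biotype` with attribute `contrast_id`.
#' @export
build_contrast_set <- function(t) {
  stopifnot(inherits(t, "contrast_table"))
  if (any(t$log2fc == 0))
    stop("differential rows must have a nonzero log2fc (feature ",
         paste(t$feature_id[t$log2fc == 0], collapse = ", "), ")")
  if (nrow(t) == 0L) {
    out <- data.frame(gene_name = character(), direction = character(),
                      n_transcripts = integer(), biotype = character(),
                      stringsAsFactors = FALSE)
  } else {
    sp <- split(seq_len(nrow(t)), t$gene_name)
    out <- data.frame(
      gene_name = names(sp),
      direction = vapply(sp, function(i) {
        s <- sign(t$log2fc[i])
        if (all(s > 0)) "up" else if (all(s < 0)) "down" else "mixed"
      }, ""),
      n_transcripts = lengths(sp),
      biotype = vapply(sp, function(i) t$biotype[i][1L], ""),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
  }
  structure(out, contrast_id = attr(t, "contrast_id"),
            class = c("contrast_set", "data.frame"))
}

#' Tally a contrast set by regulation direction
#'
#' @param s a [build_contrast_set()] result.
#' @return list with `n_up`, `n_down`, `n_mixed` (summing to `nrow(s)`).
#' @export
direction_tally <- function(s) {
  stopifnot(inherits(s, "contrast_set"))
  list(n_up    = sum(s$direction == "up"),
       n_down  = sum(s$direction == "down"),
       n_mixed = sum(s$direction == "mixed"))
}

#' Exact three-set Venn partition of contrast sets
#'
#' Partitions the union of gene symbols into the seven non-empty regions of a
#' three-set Venn diagram. Regions are keyed by the sorted contrast ids joined
#' with `"&"`, so the partition is equivariant under permuting the arguments.
#'
#' @param a,b,c three [build_contrast_set()]s from distinct contrasts.
#' @return A `venn_partition`: list with `region_members` (named list of gene
#'   vectors over all 7 region keys), `region_counts`, and `contrast_ids`.
#' @export
venn_partition <- function(a, b, c) {
  sets <- list(a, b, c)
  stopifnot(all(vapply(sets, inherits, TRUE, "contrast_set")))
  ids <- vapply(sets, attr, "", "contrast_id")
  if (anyDuplicated(ids))
    stop("venn_partition requires three distinct contrast_ids")
  genes <- lapply(sets, `[[`, "gene_name")
  names(genes) <- ids
  ids_sorted <- sort(ids, method = "radix")   # locale-independent key order
  keys <- unlist(lapply(1:3, function(k)
    utils::combn(ids_sorted, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  members <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) members[[k]] <- character()
  universe <- sort(unique(unlist(genes)))
  for (g in universe) {
    inset <- ids[vapply(genes, function(v) g %in% v, TRUE)]
    key <- paste(sort(inset, method = "radix"), collapse = "&")
    members[[key]] <- append(members[[key]], g)  # (`c` is masked by an argument)
  }
  structure(list(region_members = members,
                 region_counts  = lengths(members),
                 contrast_ids   = ids_sorted),
            class = "venn_partition")
}

#' Members of one Venn region
#'
#' @param v a [venn_partition()].
#' @param contrasts character vector of the contrast ids defining the region
#'   (1 to 3 ids; genes in exactly these contrasts).
#' @return Character vector of gene symbols.
#' @export
venn_region <- function(v, contrasts) {
  stopifnot(inherits(v, "venn_partition"))
  key <- paste(sort(contrasts, method = "radix"), collapse = "&")
  if (!key %in% names(v$region_members)) stop("unknown region: ", key)
  v$region_members[[key]]
}

#' ncRNAs shared by obesity and cancer conditions
#'
#' Union of the two triple-intersection regions of the lncRNA (DEL) and miRNA
#' (DEM) Venn partitions: symbols differential in all three disease contrasts
#' on either molecule class. The two partitions must be over the same three
#' contrasts; lncRNA and miRNA namespaces do not collide, so the result is the
#' disjoint union of the class-wise triple overlaps.
#'
#' @param del_venn,dem_venn [venn_partition()]s over the same contrasts.
#' @return Character vector of shared ncRNA symbols.
#' @export
shared_obesity_cancer <- function(del_venn, dem_venn) {
  stopifnot(inherits(del_venn, "venn_partition"),
            inherits(dem_venn, "venn_partition"))
  if (!identical(del_venn$contrast_ids, dem_venn$contrast_ids))
    stop("venn partitions built over different contrasts")
  triple <- paste(del_venn$contrast_ids, collapse = "&")
  sort(union(del_venn$region_members[[triple]],
             dem_venn$region_members[[triple]]))
}

#' Summarise the full overlap analysis of three DEL and three DEM tables
#'
#' Convenience wrapper producing every headline overlap statistic in one list:
#' per-contrast direction tallies, Venn region counts for both molecule
#' classes, the combined obesity/cancer shared set, and the novel-lncRNA count.
#'
#' @param del_tables,dem_tables named lists of three [contrast_table()]s.
#' @return list with elements `del`, `dem` (each: `sets`, `tallies`, `venn`),
#'   `shared_obesity_cancer`, `n_novel_lncrna`.
#' @export
overlap_summary <- function(del_tables, dem_tables) {
  del_sets <- lapply(del_tables, build_contrast_set)
  dem_sets <- lapply(dem_tables, build_contrast_set)
  del_venn <- venn_partition(del_sets[[1]], del_sets[[2]], del_sets[[3]])
  dem_venn <- venn_partition(dem_sets[[1]], dem_sets[[2]], dem_sets[[3]])
  novel <- unique(unlist(lapply(del_tables, function(t)
    t$gene_name[t$biotype == "lncRNA_novel"])))
  list(
    del = list(sets = del_sets, tallies = lapply(del_sets, direction_tally),
               venn = del_venn),
    dem = list(sets = dem_sets, tallies = lapply(dem_sets, direction_tally),
               venn = dem_venn),
    shared_obesity_cancer = shared_obesity_cancer(del_venn, dem_venn),
    n_novel_lncrna = length(novel)
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over:", paste(x$contrast_ids, collapse = ", "), "\n")
  print(x$region_counts)
  invisible(x)
}
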