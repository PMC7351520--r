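#' @title Tabular I/O for contrast tables, interaction evidence, gene sets and
#'   qPCR plates
#' @name ncnet-io
#' @description Readers and writers for every flat-file artifact the pipeline
#'   consumes or emits. All files are UTF-8, tab-separated, "." decimal mark,
#'   Unix newlines. Missing values are encoded by row absence, never by
#'   sentinels: a feature that is not differential in a contrast simply has no
#'   row in that contrast's table.
NULL

CONTRAST_IDS <- c("NwCRC_vs_Nw", "Ob_vs_Nw", "ObCRC_vs_Nw")
BIOTYPES     <- c("mRNA", "lncRNA_known", "lncRNA_novel", "miRNA")
LEGAL_PAIRS  <- c("miRNA>mRNA", "lncRNA>miRNA", "lncRNA>mRNA")

#' Construct and validate a contrast table
#'
#' A contrast table holds the differential features of one disease-vs-control
#' comparison: one row per transcript or miRNA, with its gene symbol, biotype,
#' log2 fold change and BH-adjusted p-value. A gene symbol may map to several
#' feature rows (multi-transcript genes); feature ids must be unique.
#'
#' @param df data.frame with columns feature_id, gene_name, biotype, log2fc, fdr.
#' @param contrast_id label of the comparison (e.g. "Ob_vs_Nw").
#' @return A `contrast_table`: validated data.frame with attribute
#'   `contrast_id`.
#' @export
contrast_table <- function(df, contrast_id) {
  stopifnot(is.character(contrast_id), length(contrast_id) == 1L)
  need <- c("feature_id", "gene_name", "biotype", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("contrast table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$feature_id <- as.character(df$feature_id)
  df$gene_name  <- as.character(df$gene_name)
  df$biotype    <- as.character(df$biotype)
  df$log2fc     <- as.numeric(df$log2fc)
  df$fdr        <- as.numeric(df$fdr)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id in contrast table: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  bad <- !df$biotype %in% BIOTYPES
  if (any(bad))
    stop("unknown biotype: ", paste(unique(df$biotype[bad]), collapse = ", "))
  if (any(!is.finite(df$log2fc)))
    stop("non-finite log2fc in contrast table")
  if (any(is.na(df$fdr) | df$fdr < 0 | df$fdr > 1))
    stop("fdr must lie in [0, 1]")
  rownames(df) <- NULL
  structure(df, contrast_id = contrast_id,
            class = c("contrast_table", "data.frame"))
}

#' Read a contrast table from TSV
#'
#' @param path path to a tab-separated file with header
#'   `feature_id gene_name biotype log2fc fdr`.
#' @param contrast_id label to attach to the table.
#' @return A [contrast_table()].
#' @export
read_contrast_table <- function(path, contrast_id) {
  raw <- read_tsv_strict(path, c("feature_id", "gene_name", "biotype",
                                 "log2fc", "fdr"))
  for (col in c("log2fc", "fdr")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("%s: malformed numeric field '%s' in column %s at line %d",
                   path, raw[[col]][bad[1]], col, bad[1] + 1L))
    raw[[col]] <- v
  }
  contrast_table(raw, contrast_id)
}

#' Write a contrast table to TSV
#'
#' @param x a [contrast_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contrast_table <- function(x, path) {
  stopifnot(inherits(x, "contrast_table"))
  write_tsv_plain(as.data.frame(x), path)
}

#' Construct and validate an interaction-evidence table
#'
#' Typed regulatory evidence edges in the shape of TarBase/miRTarBase
#' (validated miRNA-to-mRNA), DIANA-LncBase (scored predicted lncRNA-miRNA) and
#' ENCORI (verified lncRNA-miRNA and lncRNA-mRNA) exports. Only the class pairs
#' miRNA>mRNA, lncRNA>miRNA and lncRNA>mRNA are legal; a prediction score in
#' [0, 1] is present exactly when `evidence == "predicted"`.
#'
#' @param df data.frame with columns source_id, source_class, target_id,
#'   target_class, evidence, score.
#' @return An `interaction_table` data.frame.
#' @export
interaction_table <- function(df) {
  need <- c("source_id", "source_class", "target_id", "target_class",
            "evidence", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("interaction table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (col in need[1:5]) df[[col]] <- as.character(df[[col]])
  df$score <- as.numeric(df$score)
  pair <- paste0(df$source_class, ">", df$target_class)
  bad <- !pair %in% LEGAL_PAIRS
  if (any(bad))
    stop("illegal regulator/target class pair: ",
         paste(unique(pair[bad]), collapse = ", "))
  if (any(!df$evidence %in% c("validated", "predicted")))
    stop("evidence must be 'validated' or 'predicted'")
  pred <- df$evidence == "predicted"
  if (any(pred & is.na(df$score)))
    stop("predicted rows must carry a score")
  if (any(!pred & !is.na(df$score)))
    stop("validated rows must not carry a score")
  if (any(pred & (df$score < 0 | df$score > 1)))
    stop("score outside [0, 1]")
  key <- paste(df$source_id, df$target_id, df$evidence, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (source_id, target_id, evidence) triple in interaction table")
  rownames(df) <- NULL
  structure(df, class = c("interaction_table", "data.frame"))
}

#' Read an interaction-evidence table from TSV
#'
#' @param path tab-separated file with header `source_id source_class
#'   target_id target_class evidence score`; empty score cells mean absent.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path) {
  raw <- read_tsv_strict(path, c("source_id", "source_class", "target_id",
                                 "target_class", "evidence", "score"))
  raw$score[!nzchar(trimws(ifelse(is.na(raw$score), "", raw$score)))] <- NA
  v <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(v) & !is.na(raw$score))
  if (length(bad))
    stop(sprintf("%s: malformed numeric score '%s' at line %d",
                 path, raw$score[bad[1]], bad[1] + 1L))
  raw$score <- v
  interaction_table(raw)
}

#' Write an interaction-evidence table to TSV
#'
#' @param x an [interaction_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(x, path) {
  stopifnot(inherits(x, "interaction_table"))
  write_tsv_plain(as.data.frame(x), path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `term_id TAB description TAB gene1
#' TAB gene2 ...`. Duplicate member symbols within a line are deduplicated;
#' duplicate term ids across lines are an error.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: named list of character member vectors,
#'   with attribute `term_names` (named descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, short[1]))
  ids   <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  sets  <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (anyDuplicated(ids))
    stop("duplicate term_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  names(descs) <- ids
  gene_set_collection(sets, descs)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param term_names named character vector of human-readable descriptions
#'   (same names as `sets`); defaults to the term ids.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, term_names = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("gene sets must be named by term_id")
    if (anyDuplicated(names(sets))) stop("duplicate term_id")
    if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
    sets <- lapply(sets, function(s) unique(as.character(s)))
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(sets), names(sets))
  }
  structure(sets, term_names = term_names, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param x a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  tn <- attr(x, "term_names")
  lines <- vapply(names(x), function(id) {
    paste(c(id, unname(tn[id]), x[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Curated differential lncRNA (DEL) contrast tables
#'
#' Loads the three per-contrast differentially-expressed-lncRNA tables shipped
#' with the package, compiled from a published RNA-seq study of visceral
#' adipocytes from normal-weight (Nw), obese (Ob) and colorectal-cancer
#' (NwCRC, ObCRC) subjects, each contrast against the Nw control at
#' FDR <= 0.05. A handful of cells absent from the printed source table were
#' restored from that study's explicit shared-gene listings (signs confirmed by
#' its narrative; magnitudes mirrored from the adjacent contrast column), so
#' the tables reproduce its stated per-contrast tallies and overlaps. Per-row
#' adjusted p-values were not published; the tables carry the 0.05 bound.
#'
#' @return Named list of three [contrast_table()]s
#'   (`NwCRC_vs_Nw`, `Ob_vs_Nw`, `ObCRC_vs_Nw`).
#' @export
load_del_tables <- function() load_fixture_tables("del", 0.05)

#' Curated differential miRNA (DEM) contrast tables
#'
#' Loads the three per-contrast differentially-expressed-miRNA tables shipped
#' with the package (same cohorts as [load_del_tables()]), each contrast
#' against the Nw control at FDR <= 0.06.
#'
#' @return Named list of three [contrast_table()]s.
#' @export
load_dem_tables <- function() load_fixture_tables("dem", 0.06)

load_fixture_tables <- function(prefix, fdr_bound) {
  out <- lapply(CONTRAST_IDS, function(cid) {
    path <- system.file("extdata", sprintf("%s_%s.tsv", prefix, cid),
                        package = "ncnet", mustWork = TRUE)
    read_contrast_table(path, cid)
  })
  stats::setNames(out, CONTRAST_IDS)
}

# strict TSV reader: exact header, all-character columns, no quoting
read_tsv_strict <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           blank.lines.skip = TRUE)
  if (!identical(names(raw), header))
    stop(sprintf("%s: expected header '%s', found '%s'", path,
                 paste(header, collapse = "\t"),
                 paste(names(raw), collapse = "\t")))
  raw
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("contrast_table '%s': %d feature(s), %d gene(s)\n",
              attr(x, "contrast_id"), nrow(x), length(unique(x$gene_name))))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
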