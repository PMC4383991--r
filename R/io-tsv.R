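HITS_COLS <- c("query_id", "subject_id", "raw_score", "pct_identity",
               "aln_len", "q_start", "q_end", "s_start", "s_end")
CLUSTER_COLS <- c("level_id", "og_id", "gene_id", "genome_id")
REFOG_COLS <- c("refog_id", "gene_id")
COLLAPSE_COLS <- c("genome_id", "representative_id", "absorbed_id")

#' Read an all-vs-all hits table
#'
#' BLAST-tabular-like TSV with one '#' header line and columns
#' `query_id, subject_id, raw_score, pct_identity, aln_len, q_start,
#' q_end, s_start, s_end`; coordinates are 1-based inclusive on the
#' unaligned sequences. Hits may come from [all_vs_all()] or from any
#' external aligner emitting the same columns.
#'
#' @param path hits TSV.
#' @return `data.table` of directed similarity hits.
#' @export
read_hits_tsv <- function(path) {
  df <- read_pipeline_tsv(path, HITS_COLS)
  dt <- as.data.table(df)
  for (col in c("raw_score", "aln_len", "q_start", "q_end",
                "s_start", "s_end"))
    set(dt, j = col, value = as_int_strict(dt[[col]], col, path))
  set(dt, j = "pct_identity", value = as.numeric(dt[["pct_identity"]]))
  if (any(!is.finite(dt$pct_identity)))
    stop("non-numeric pct_identity in ", path)
  if (any(dt$query_id == dt$subject_id))
    stop("self-hit in ", path)
  if (any(dt$raw_score < 0L)) stop("negative raw_score in ", path)
  dt[]
}

#' Write an all-vs-all hits table
#' @param hits hits `data.table`/`data.frame` (see [read_hits_tsv()]).
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  hits <- as.data.frame(hits)[, HITS_COLS]
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  hits$pct_identity <- formatC(hits$pct_identity, digits = 4, format = "f")
  write_pipeline_tsv(hits, path, HITS_COLS)
}

#' Write orthologous groups to the clusters TSV
#'
#' One row per (level, group, gene), sorted by `(level_id, og_id,
#' gene_id)` so output is byte-deterministic.
#'
#' @param groups cluster table with columns `level_id, og_id, gene_id,
#'   genome_id` (as produced by [cluster_all_levels()]).
#' @param path output path.
#' @export
write_clusters_tsv <- function(groups, path) {
  df <- as.data.frame(groups)[, CLUSTER_COLS]
  df <- df[order(df$level_id, df$og_id, df$gene_id), , drop = FALSE]
  write_pipeline_tsv(df, path, CLUSTER_COLS)
}

#' Read orthologous groups from the clusters TSV
#'
#' Enforces the partition invariant: a gene may belong to at most one
#' group per level.
#'
#' @param path clusters TSV.
#' @return `data.frame` with columns `level_id, og_id, gene_id, genome_id`.
#' @export
read_clusters_tsv <- function(path) {
  df <- read_pipeline_tsv(path, CLUSTER_COLS)
  key <- paste(df$level_id, df$gene_id)
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("gene ", bad$gene_id, " appears in two groups at level ",
         bad$level_id, " in ", path)
  }
  df[order(df$level_id, df$og_id, df$gene_id), , drop = FALSE]
}

#' Read a reference clustering for benchmarking
#' @param path TSV with columns `refog_id, gene_id`.
#' @return `data.frame` with those columns.
#' @export
read_refogs_tsv <- function(path) {
  df <- read_pipeline_tsv(path, REFOG_COLS)
  if (anyDuplicated(df$gene_id))
    stop("gene assigned to two reference groups in ", path)
  df
}

#' @rdname read_refogs_tsv
#' @param refogs reference table to write.
#' @export
write_refogs_tsv <- function(refogs, path) {
  df <- as.data.frame(refogs)[, REFOG_COLS]
  df <- df[order(df$refog_id, df$gene_id), , drop = FALSE]
  write_pipeline_tsv(df, path, REFOG_COLS)
}

#' Read/write the similar-copy collapse map
#'
#' One row per absorbed gene: `genome_id, representative_id, absorbed_id`.
#' @param path collapse-map TSV.
#' @export
read_collapse_tsv <- function(path) {
  read_pipeline_tsv(path, COLLAPSE_COLS)
}

#' @rdname read_collapse_tsv
#' @param cmap collapse map table.
#' @export
write_collapse_tsv <- function(cmap, path) {
  df <- as.data.frame(cmap)[, COLLAPSE_COLS]
  df <- df[order(df$genome_id, df$representative_id, df$absorbed_id),
           , drop = FALSE]
  write_pipeline_tsv(df, path, COLLAPSE_COLS)
}

#' Assign deterministic group identifiers
#'
#' Groups at a level are numbered `OG<level_id>_<zero-padded ordinal>`
#' by descending size, ties toward the group whose lexicographically
#' smallest member sorts first.
#'
#' @param members list of character vectors of gene ids.
#' @param level_id the level label.
#' @return character vector of og_ids, parallel to `members`.
#' @export
assign_og_ids <- function(members, level_id) {
  if (length(members) == 0L) return(character(0))
  sizes <- lengths(members)
  mins <- vapply(members, min, character(1))
  ord <- order(-sizes, mins)
  ids <- character(length(members))
  ids[ord] <- paste0("OG", level_id, "_", pad_ordinal(seq_along(members)))
  ids
}
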