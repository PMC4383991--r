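#' Alignment parameters
#'
#' Defaults follow the standard protein-BLAST setting: BLOSUM62 with an
#' affine gap of cost `gap_open + L * gap_extend` (11/1). `min_score` is
#' the raw-score floor below which a hit is not reported; `min_overlap`
#' requires the local alignment to span at least that fraction of the
#' shorter sequence, which suppresses short domain-only matches that
#' would otherwise seed spurious reciprocal hits.
#'
#' @param matrix_name substitution matrix name (see
#'   [substitution_matrix()]).
#' @param gap_open gap opening penalty (positive integer).
#' @param gap_extend gap extension penalty per residue (positive
#'   integer, `<= gap_open`).
#' @param min_score minimum raw alignment score for a hit to be kept.
#' @param min_overlap minimum fraction (0, 1] of the shorter sequence
#'   the alignment must cover.
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(matrix_name = "blosum62", gap_open = 11L,
                             gap_extend = 1L, min_score = 50L,
                             min_overlap = 0.5) {
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            min_overlap > 0, min_overlap <= 1)
  structure(list(matrix_name = matrix_name, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score),
                 min_overlap = min_overlap),
            class = "alignment_params")
}

#' Similar-copy collapsing parameters
#'
#' @param identity_threshold minimum percent identity (0, 100] for a
#'   gene to be absorbed by a representative.
#' @param coverage_threshold minimum fraction of the shorter sequence
#'   the alignment must cover.
#' @return a list of class `collapse_params`.
#' @export
collapse_params <- function(identity_threshold = 97, coverage_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold),
            class = "collapse_params")
}

# fraction of the shorter sequence covered by the aligned spans
overlap_fraction <- function(hit_df, len_a, len_b) {
  span_q <- hit_df$q_end - hit_df$q_start + 1L
  span_s <- hit_df$s_end - hit_df$s_start + 1L
  ifelse(len_a <= len_b, span_q / len_a, span_s / len_b)
}

#' Optimal local alignment of two protein sequences
#'
#' Full Smith-Waterman with affine gaps (Gotoh). Returns `NULL` when the
#' optimal score falls below `min_score` or the alignment covers less
#' than `min_overlap` of the shorter sequence.
#'
#' @param seq_a,seq_b non-empty amino-acid strings (20 canonical
#'   residues + X; other letters are masked to X).
#' @param params an [alignment_params()] object.
#' @return one-row `data.frame` with `raw_score`, `pct_identity`
#'   (identities / alignment columns x 100), `aln_len` and the 1-based
#'   inclusive coordinates `q_start, q_end, s_start, s_end`, or `NULL`.
#' @export
smith_waterman <- function(seq_a, seq_b, params = alignment_params()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  seq_a <- suppressWarnings(clean_sequences(seq_a))
  seq_b <- suppressWarnings(clean_sequences(seq_b))
  # co-optimal alignments are resolved by a fixed scan order; aligning
  # the lexicographically smaller sequence as query and mirroring back
  # makes the reported alignment independent of argument order
  swap <- seq_b < seq_a
  qa <- if (swap) seq_b else seq_a
  qb <- if (swap) seq_a else seq_b
  lk <- score_lookup(substitution_matrix(params$matrix_name))
  r <- .sw_align_pairs(qa, qb, lk, params$gap_open, params$gap_extend)
  if (r$raw_score[[1L]] < params$min_score) return(NULL)
  cov <- overlap_fraction(r, nchar(qa), nchar(qb))
  if (cov < params$min_overlap) return(NULL)
  out <- data.frame(raw_score = r$raw_score,
                    pct_identity = 100 * r$n_ident / r$aln_len,
                    aln_len = r$aln_len, q_start = r$q_start,
                    q_end = r$q_end, s_start = r$s_start, s_end = r$s_end)
  if (swap)
    out[c("q_start", "q_end", "s_start", "s_end")] <-
      out[c("s_start", "s_end", "q_start", "q_end")]
  out
}

#' All-vs-all local alignment over a gene table
#'
#' Aligns every unordered pair of distinct genes (both inter- and
#' intra-genome) and emits directed hits in both orientations for pairs
#' passing the score and overlap thresholds. Local alignment under a
#' symmetric substitution matrix is symmetric, so each pair is computed
#' once and mirrored. Output is sorted by `(query_id, subject_id)`.
#'
#' @param genes gene table with `gene_id`, `genome_id`, `sequence`
#'   (see [read_genome_dir()]).
#' @param params an [alignment_params()] object.
#' @return `data.table` of directed hits with the hits-TSV columns.
#' @export
all_vs_all <- function(genes, params = alignment_params()) {
  stopifnot(nrow(genes) >= 1L)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  lk <- score_lookup(substitution_matrix(params$matrix_name))
  raw <- .sw_align_all(genes$sequence, lk, params$gap_open,
                       params$gap_extend, params$min_score)
  raw <- as.data.table(raw)
  empty <- data.table(query_id = character(0), subject_id = character(0),
                      raw_score = integer(0), pct_identity = numeric(0),
                      aln_len = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0))
  if (nrow(raw) == 0L) return(empty)
  len <- genes$protein_length
  cov <- overlap_fraction(raw, len[raw$i], len[raw$j])
  raw <- raw[cov >= params$min_overlap]
  if (nrow(raw) == 0L) return(empty)
  ids <- genes$gene_id
  fwd <- data.table(query_id = ids[raw$i], subject_id = ids[raw$j],
                    raw_score = raw$raw_score,
                    pct_identity = 100 * raw$n_ident / raw$aln_len,
                    aln_len = raw$aln_len, q_start = raw$q_start,
                    q_end = raw$q_end, s_start = raw$s_start,
                    s_end = raw$s_end)
  rev <- data.table(query_id = ids[raw$j], subject_id = ids[raw$i],
                    raw_score = raw$raw_score,
                    pct_identity = fwd$pct_identity,
                    aln_len = raw$aln_len, q_start = raw$s_start,
                    q_end = raw$s_end, s_start = raw$q_start,
                    s_end = raw$q_end)
  hits <- rbind(fwd, rev)
  setorder(hits, query_id, subject_id)
  hits[]
}

#' Collapse near-identical gene copies within one genome
#'
#' Greedy longest-first clustering in the style of CD-HIT: genes are
#' visited by descending length (ties by gene id); each gene is absorbed
#' by the first already-chosen representative to which it has a stored
#' intra-genome hit with identity `>= identity_threshold` covering
#' `>= coverage_threshold` of the shorter sequence, otherwise it becomes
#' a new representative. Downstream clustering sees representatives
#' only; absorbed genes are re-attached to the representative's final
#' group.
#'
#' @param genes gene table restricted to (or containing) the genome.
#' @param genome_id which genome to collapse.
#' @param hits directed hits table containing intra-genome hits.
#' @param cparams a [collapse_params()] object.
#' @return list with `representatives` (character vector of gene ids)
#'   and `expansion` (a `data.frame` `genome_id, representative_id,
#'   absorbed_id`, one row per absorbed gene).
#' @export
collapse_similar_copies <- function(genes, genome_id, hits,
                                    cparams = collapse_params()) {
  g <- genes[genes$genome_id == genome_id, , drop = FALSE]
  empty <- data.frame(genome_id = character(0),
                      representative_id = character(0),
                      absorbed_id = character(0), stringsAsFactors = FALSE)
  if (nrow(g) == 0L)
    return(list(representatives = character(0), expansion = empty))
  hits <- as.data.table(hits)
  ingenome <- hits[query_id %in% g$gene_id & subject_id %in% g$gene_id]
  len <- setNames(g$protein_length, g$gene_id)
  # identity/coverage per unordered pair: mean identity of the two
  # directions, coverage from the query-side direction
  pair_ok <- new.env(hash = TRUE)
  if (nrow(ingenome)) {
    ingenome[, cov := overlap_fraction(.SD, len[query_id], len[subject_id])]
    ag <- ingenome[, .(ident = mean(pct_identity), cov = max(cov)),
                   by = .(a = pmin(query_id, subject_id),
                          b = pmax(query_id, subject_id))]
    ok <- ag[ident >= cparams$identity_threshold &
               cov >= cparams$coverage_threshold]
    if (nrow(ok))
      for (k in seq_len(nrow(ok)))
        assign(paste(ok$a[[k]], ok$b[[k]]), TRUE, envir = pair_ok)
  }
  ord <- order(-g$protein_length, g$gene_id)
  reps <- character(0)
  exp_rep <- character(0); exp_abs <- character(0)
  for (gi in g$gene_id[ord]) {
    joined <- FALSE
    for (r in reps) {
      key <- paste(min(gi, r), max(gi, r))
      if (!is.null(pair_ok[[key]])) {
        exp_rep <- c(exp_rep, r); exp_abs <- c(exp_abs, gi)
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, gi)
  }
  expansion <- data.frame(genome_id = rep(genome_id, length(exp_abs)),
                          representative_id = exp_rep, absorbed_id = exp_abs,
                          stringsAsFactors = FALSE)
  list(representatives = sort(reps), expansion = expansion)
}

#' Collapse all genomes of a gene table
#'
#' @inheritParams collapse_similar_copies
#' @return list with `representatives` and the combined `expansion` map.
#' @export
collapse_all_genomes <- function(genes, hits, cparams = collapse_params()) {
  per <- lapply(sort(unique(genes$genome_id)), function(gm)
    collapse_similar_copies(genes, gm, hits, cparams))
  list(representatives = sort(unlist(lapply(per, `[[`, "representatives"))),
       expansion = do.call(rbind, lapply(per, `[[`, "expansion")))
}
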