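#' Read one genome's proteome from FASTA, keeping the longest isoform
#'
#' Each FASTA record's header is parsed as `gene_id` or
#' `gene_id|isoform_id` (first whitespace-delimited token). When several
#' isoforms share a `gene_id` only the longest sequence is kept; equal
#' lengths are resolved toward the lexicographically smallest
#' `isoform_id` so the choice does not depend on file order. Sequences
#' are normalized onto the 20-residue + X alphabet.
#'
#' @param path FASTA file with protein sequences.
#' @param genome_id identifier of the genome; must match the taxonomy
#'   leaf label used later.
#' @return a `data.frame` of gene records with columns `gene_id`,
#'   `genome_id`, `sequence`, `protein_length`.
#' @export
read_genome_fasta <- function(path, genome_id) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  headers <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  parts <- strsplit(headers, "|", fixed = TRUE)
  gene_id <- vapply(parts, `[[`, character(1), 1L)
  isoform_id <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "",
                       character(1))
  seqs <- clean_sequences(as.character(ss))
  df <- data.frame(gene_id = gene_id, isoform_id = isoform_id,
                   sequence = seqs, protein_length = nchar(seqs),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, -df$protein_length, df$isoform_id), ]
  keep <- !duplicated(df$gene_id)
  # equal-length records that are not distinguishable by isoform id must
  # agree on sequence, otherwise the input is ambiguous
  dup <- df[!keep, , drop = FALSE]
  top <- df[keep, , drop = FALSE]
  if (nrow(dup)) {
    m <- match(dup$gene_id, top$gene_id)
    conflict <- dup$protein_length == top$protein_length[m] &
      dup$isoform_id == top$isoform_id[m] &
      dup$sequence != top$sequence[m]
    if (any(conflict))
      stop("conflicting equal-length sequences for gene ",
           dup$gene_id[which(conflict)[1L]], " in ", path)
  }
  data.frame(gene_id = top$gene_id, genome_id = genome_id,
             sequence = top$sequence, protein_length = top$protein_length,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a directory of per-genome FASTA files
#'
#' File basenames (minus extension) become genome ids.
#'
#' @param dir directory containing `<genome_id>.fasta`/`.fa`/`.faa` files.
#' @return a single gene table covering all genomes, with unique gene ids.
#' @export
read_genome_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|faa|fasta)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files in ", dir)
  tabs <- lapply(files, function(f)
    read_genome_fasta(f, tools::file_path_sans_ext(basename(f))))
  genes <- do.call(rbind, tabs)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("gene id appears in more than one genome: ", dup[[1L]])
  genes[order(genes$genome_id, genes$gene_id), , drop = FALSE]
}

#' Read per-gene metadata (lengths, exon counts, domain architectures)
#'
#' The TSV has one '#' header line and columns `gene_id`, `genome_id`,
#' `protein_length`, `exon_count` (may be `NA`) and `domains`
#' (semicolon-separated InterPro-style identifiers ordered from N- to
#' C-terminus; may be empty).
#'
#' @param path metadata TSV.
#' @return `data.frame` with columns `gene_id`, `genome_id`,
#'   `protein_length` (integer), `exon_count` (integer, `NA` allowed) and
#'   `domains` (semicolon-joined string, `""` for none).
#' @export
read_metadata_tsv <- function(path) {
  cols <- c("gene_id", "genome_id", "protein_length", "exon_count", "domains")
  df <- read_pipeline_tsv(path, cols)
  df$protein_length <- as_int_strict(df$protein_length, "protein_length", path)
  if (anyNA(df$protein_length))
    stop("missing protein_length in ", path)
  df$exon_count <- as_int_strict(df$exon_count, "exon_count", path)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicate gene_id in metadata: ", dup[[1L]])
  df
}

#' Write the metadata TSV
#' @param meta metadata table as returned by [read_metadata_tsv()].
#' @param path output path.
#' @export
write_metadata_tsv <- function(meta, path) {
  cols <- c("gene_id", "genome_id", "protein_length", "exon_count", "domains")
  out <- meta[, cols]
  out$exon_count <- ifelse(is.na(out$exon_count), "NA",
                           as.character(out$exon_count))
  write_pipeline_tsv(out, path, cols)
}

#' Split semicolon-joined domain strings into ordered identifier vectors
#' @param domains character vector of semicolon-joined domain ids.
#' @return list of character vectors (empty vector for `""`).
#' @export
split_domains <- function(domains) {
  lapply(domains, function(d)
    if (is.na(d) || !nzchar(d)) character(0)
    else strsplit(d, ";", fixed = TRUE)[[1L]])
}
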