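#' Amino-acid alphabet used throughout the pipeline
#'
#' Twenty canonical residues plus X for anything else.
#' @keywords internal
#' @noRd
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Load a protein substitution matrix by name
#'
#' Looks the matrix up in the standard collection shipped with Biostrings
#' (BLOSUM and PAM series). Names are case-insensitive.
#'
#' @param name matrix name, e.g. `"blosum62"`.
#' @return integer matrix with residue row/column names.
#' @export
substitution_matrix <- function(name = "blosum62") {
  nm <- toupper(name)
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!nm %in% known)
    stop("unknown substitution matrix: ", name)
  env <- new.env()
  utils::data(list = nm, package = "Biostrings", envir = env)
  m <- get(nm, envir = env)
  storage.mode(m) <- "integer"
  m
}

# 26x26 lookup indexed by (letter - 'A') for the C++ aligner. Letters
# outside the matrix (and outside the 20+X alphabet) score as X.
score_lookup <- function(mat) {
  letters26 <- LETTERS
  idx <- ifelse(letters26 %in% rownames(mat), letters26, "X")
  lk <- mat[idx, idx]
  dimnames(lk) <- list(letters26, letters26)
  storage.mode(lk) <- "integer"
  lk
}

#' Normalize a protein sequence onto the pipeline alphabet
#'
#' Uppercases and maps any letter outside the 20 canonical residues to X.
#' A warning reports how many residues were masked.
#'
#' @param seqs character vector of amino-acid sequences.
#' @return character vector over the 20+X alphabet.
#' @export
clean_sequences <- function(seqs) {
  seqs <- toupper(seqs)
  pattern <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  n_bad <- sum(vapply(gregexpr(pattern, seqs),
                      function(m) sum(m > 0L), integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-canonical residue(s) mapped to X")
    seqs <- gsub(pattern, "X", seqs)
  }
  seqs
}
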