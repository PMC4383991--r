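`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pad_ordinal <- function(i, width = 6L) {
  formatC(i, width = width, flag = "0", format = "d")
}

# All pipeline TSVs carry a single '#'-prefixed header line naming the
# columns; readers check it, writers emit it.
read_pipeline_tsv <- function(path, expected_cols) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  if (!startsWith(lines[[1L]], "#"))
    stop("missing '#' header line in ", path)
  header <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  if (!identical(header, expected_cols))
    stop("unexpected columns in ", path, ": ",
         paste(header, collapse = ","), " (expected ",
         paste(expected_cols, collapse = ","), ")")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(expected_cols)),
                                 expected_cols))
    return(df)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty field (e.g. empty domains column) is dropped by strsplit
  short <- nf == length(expected_cols) - 1L
  if (any(short))
    parts[short] <- lapply(parts[short], function(p) c(p, ""))
  bad <- which(lengths(parts) != length(expected_cols))
  if (length(bad))
    stop("malformed row at line ", bad[[1L]] + 1L, " in ", path)
  mat <- do.call(rbind, parts)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- expected_cols
  df
}

write_pipeline_tsv <- function(df, path, cols) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(df))
    write.table(df[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_int_strict <- function(x, what, path = NULL) {
  y <- suppressWarnings(as.integer(x))
  num <- suppressWarnings(as.numeric(x))
  bad <- is.na(y) & !(toupper(trimws(x)) %in% c("NA", ""))
  bad <- bad | (!is.na(y) & num != y)
  if (any(bad))
    stop("non-integer ", what, if (!is.null(path)) paste0(" in ", path),
         ": '", x[which(bad)[1L]], "'")
  y
}
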