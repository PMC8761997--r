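#' Read a FASTA file into a named character vector
#'
#' Record ids are truncated at the first whitespace, matching the convention
#' of alignment tools.  Duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write sequences as wrapped FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names", call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

alignment_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")

#' Read a 12-column tabular alignment file
#'
#' Accepts the standard tab-separated alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, E-value, bit score), with or without a header row.
#' Malformed rows are rejected with their line numbers.
#'
#' @param path File path.
#' @return Data frame with the 12 standard columns.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      replicate(12, character(0), simplify = FALSE), alignment_columns))
    return(coerce_alignment(out))
  }
  has_header <- identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1],
                          "qseqid")
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop("alignment file ", path, ": line ", bad + offset, " has ",
         nf[bad], " columns (expected 12)", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- alignment_columns
  coerce_alignment(out)
}

coerce_alignment <- function(df) {
  num <- c("pident", "evalue", "bitscore")
  int <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart",
           "send")
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in int) df[[cc]] <- as.integer(as.numeric(df[[cc]]))
  if (nrow(df)) {
    if (any(is.na(df$pident)) || any(df$pident < 0 | df$pident > 100)) {
      stop("percent identity outside [0, 100]", call. = FALSE)
    }
    if (any(is.na(df$evalue)) || any(df$evalue < 0)) {
      stop("E-value must be >= 0", call. = FALSE)
    }
  }
  df
}

#' Write/read a plain tab-separated table with a header row
#' @param df Data frame.
#' @param path File path.
#' @return Invisibly `path` (writer) / the data frame (reader).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write/read a numeric matrix as TSV with sample ids in the first column
#' @param m Numeric matrix (samples x clades) with dimnames.
#' @param path File path.
#' @return Invisibly `path` (writer) / the matrix (reader).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(m,
                   check.names = FALSE), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (anyDuplicated(df[[1]])) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop("non-numeric cell in ", path, " at row ", badrow, ", column ",
         names(df)[bad + 1], call. = FALSE)
  }
  rownames(m) <- df[[1]]
  m
}
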