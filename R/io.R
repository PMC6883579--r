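# Sequence I/O: thin wrappers around Biostrings readers/writers with
# format autodetection (FASTA vs FASTQ from the first byte of the
# decompressed stream) and transparent gzip support.

#' Read sequences from FASTA or FASTQ
#'
#' The format is autodetected from the first character of the
#' (decompressed) stream: `>` means FASTA, `@` means FASTQ.  Multi-line
#' FASTA records are concatenated; CRLF line endings are tolerated; empty
#' records are rejected.
#'
#' @param path file path, optionally gzip-compressed.
#' @return data.frame with `id`, `desc`, `seq`, and (for FASTQ) `qual`.
#' @export
read_sequences <- function(path) {
  con <- gzfile(path, "rb")
  first <- rawToChar(readBin(con, "raw", 1))
  close(con)
  if (first == ">") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- NULL
  } else if (first == "@") {
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    stop("cannot autodetect format of '", path,
         "': first byte is neither '>' nor '@'")
  }
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- gsub("\r", "", as.character(x), fixed = TRUE)
  if (any(nchar(seqs) == 0)) {
    bad <- which(nchar(seqs) == 0)[1]
    stop("empty sequence in record ", bad, " ('", id[bad], "') of '",
         path, "'")
  }
  if (!is.null(qual) && any(nchar(qual) != nchar(seqs))) {
    bad <- which(nchar(qual) != nchar(seqs))[1]
    stop("quality length mismatch in record ", bad, " ('", id[bad],
         "') of '", path, "'")
  }
  out <- data.frame(id = id, desc = desc, seq = unname(seqs),
                    stringsAsFactors = FALSE)
  if (!is.null(qual)) out$qual <- unname(qual)
  out
}

#' Write sequences to FASTA / FASTQ
#'
#' @param records data.frame with `id`, `seq` (and `qual` for FASTQ;
#'   a constant placeholder is generated when missing).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return invisibly, the number of records written.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(length(x))
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  qual <- if ("qual" %in% names(records)) records$qual
          else strrep("I", nchar(records$seq))
  x <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path))
  invisible(length(x))
}
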