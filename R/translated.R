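# Translated search: six-frame translation of DNA queries into a
# 16-symbol reduced amino-acid alphabet, then classification against a
# protein-mode minimizer database.  Reduced symbols pack 4 bits each, so
# protein-mode minimizers of up to 15 characters fit a 64-bit word; no
# canonicalization is performed (proteins have no reverse complement).

#' Default reduced amino-acid alphabet
#'
#' A 15-group partition of the 20 standard amino acids obtained by merging
#' five physico-chemically similar pairs (D/E, I/V, K/R, L/M, S/T), plus a
#' 16th symbol shared by selenocysteine (U), pyrrolysine (O), and
#' translation stop (`*`).  The ambiguity codes B, Z, J map to the group of
#' their most common resolution; X and any other letter act as k-mer
#' breakers and are deliberately absent from the table.  The mapping is a
#' configuration value: it is recorded in a protein database's manifest so
#' that build and classification always agree, and any 15-group partition
#' yields a functioning system.
#'
#' @return named integer vector mapping letters to symbol indices 0..15.
#' @export
reduced_alphabet <- function() {
  c(A = 0L, C = 1L, D = 2L, E = 2L, B = 2L, `F` = 3L, G = 4L, H = 5L,
    I = 6L, V = 6L, K = 7L, R = 7L, L = 8L, M = 8L, J = 8L, N = 9L,
    P = 10L, Q = 11L, Z = 11L, S = 12L, `T` = 12L, W = 13L, Y = 14L,
    U = 15L, O = 15L, `*` = 15L)
}

db_alphabet <- function(db) {
  a <- attr(db$scheme, "alphabet")
  if (is.null(a)) reduced_alphabet() else a
}

#' Map amino acids onto reduced symbols
#'
#' Valid symbols come out as the letters `A`..`P` (symbol indices 0..15);
#' letters outside the alphabet (notably X) come out as `?`, which breaks
#' k-mers downstream.
#'
#' @param aa character vector of amino-acid strings.
#' @param alphabet a [reduced_alphabet()]-style named integer vector.
#' @return character vector of reduced-symbol strings.
#' @export
reduce_protein <- function(aa, alphabet = reduced_alphabet()) {
  vapply(as.character(aa), .reduce_protein_cpp, "",
         letters = names(alphabet), groups = unname(alphabet),
         USE.NAMES = FALSE)
}

codon_table_cache <- new.env(parent = emptyenv())

# 64-character codon table in ACGT order (index 16*b1 + 4*b2 + b3),
# derived from the standard genetic code shipped with Biostrings.
codon_table <- function() {
  if (is.null(codon_table_cache$tab)) {
    bases <- c("A", "C", "G", "T")
    idx <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
    codons <- paste0(bases[idx$b1 + 1], bases[idx$b2 + 1], bases[idx$b3 + 1])
    codon_table_cache$tab <-
      paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  codon_table_cache$tab
}

#' Six-frame translation into the reduced alphabet
#'
#' Frames +1, +2, +3 read the sequence at offsets 0, 1, 2; frames -1, -2,
#' -3 read the reverse complement the same way.  The standard genetic code
#' is used, trailing partial codons are dropped, and codons containing an
#' ambiguous base become the k-mer-breaking `?` symbol.
#'
#' @param dna character scalar.
#' @param alphabet a [reduced_alphabet()]-style mapping.
#' @return character vector of six reduced-symbol strings, named
#'   `+1`,`+2`,`+3`,`-1`,`-2`,`-3`.
#' @examples
#' six_frame_translate("ATGAAA")[["+1"]]
#' @export
six_frame_translate <- function(dna, alphabet = reduced_alphabet()) {
  tab <- codon_table()
  rc <- .revcomp_dna_cpp(dna)
  frames <- c(vapply(0:2, function(o) .translate_frame_cpp(dna, o, tab), ""),
              vapply(0:2, function(o) .translate_frame_cpp(rc, o, tab), ""))
  names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  vapply(frames, .reduce_protein_cpp, "", letters = names(alphabet),
         groups = unname(alphabet))
}

#' Classify a DNA fragment against a protein database
#'
#' Each mate is translated in all six frames; every frame's reduced-symbol
#' k-mers feed the same minimizer/table machinery as nucleotide search, and
#' hit counts from all frames of both mates are pooled before the
#' root-to-leaf resolution.
#'
#' @param db a protein-mode [build_database()] result.
#' @param mate1 DNA read (character scalar).
#' @param mate2 optional second mate.
#' @param fragment_id identifier carried into the output.
#' @return a `read_classification` (see [classify_fragment()]).
#' @export
classify_fragment_translated <- function(db, mate1, mate2 = NULL,
                                         fragment_id = "fragment") {
  if (!db$scheme$protein)
    stop("database is in nucleotide mode; use classify_fragment()")
  alphabet <- db_alphabet(db)
  mate_parts <- function(dna) {
    frames <- six_frame_translate(dna, alphabet)
    parts <- lapply(unname(frames), function(fr) collect_hits(db, fr))
    pooled_counts <- integer(0)
    runs <- list()
    total <- 0L; lookups <- 0L
    for (p in parts) {
      for (nm in names(p$hit_counts))
        pooled_counts[nm] <-
          (if (nm %in% names(pooled_counts)) pooled_counts[[nm]] else 0L) +
          p$hit_counts[[nm]]
      runs[[length(runs) + 1L]] <- p$runs
      total <- total + p$total_kmers
      lookups <- lookups + p$n_lookups
    }
    list(hit_counts = pooled_counts, runs = do.call(rbind, runs),
         total_kmers = total, n_lookups = lookups)
  }
  parts <- list(mate_parts(mate1))
  if (!is.null(mate2)) parts <- c(parts, list(mate_parts(mate2)))
  finalize_classification(db, parts, fragment_id,
                          lengths = c(nchar(mate1),
                                      if (!is.null(mate2)) nchar(mate2)),
                          paired = !is.null(mate2))
}
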