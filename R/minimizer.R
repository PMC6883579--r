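# Minimizer extraction: 2-bit DNA encoding, canonicalization, spaced-seed
# masking, XOR shuffling, and the sliding-window minimum.  The value a
# downstream hash table stores and queries is the fully processed candidate
# value (canonical -> masked -> XOR toggle), so "distinct minimizer" means
# the same thing at build time and at classification time.

#' Minimizer scheme
#'
#' Bundles the parameters that decide which substrings of a sequence are
#' stored in and queried against a database: the window length `k`, the
#' minimizer length `l`, the number of spaced-seed masked positions
#' `spaces`, the XOR toggle constant, and the sequence mode.
#'
#' Nucleotide defaults are `k = 35`, `l = 31`, `spaces = 7`; protein-mode
#' defaults are `k = 15`, `l = 12`, `spaces = 0`.  Bases pack 2 bits each
#' (so `l <= 31`); reduced amino-acid symbols pack 4 bits (so `l <= 15`).
#'
#' @param k integer window (k-mer) length.
#' @param l integer minimizer length, `1 <= l <= k`.
#' @param spaces integer number of masked positions `s`; starting at the
#'   next-to-rightmost position of the minimizer, every other position is
#'   masked until `s` positions are masked, so `2 * spaces <= l`.
#' @param toggle 64-bit XOR constant as a hex string.
#' @param protein logical; `TRUE` for a reduced amino-acid alphabet scheme
#'   (no canonicalization).
#' @return an object of class `minimizer_scheme`.
#' @examples
#' minimizer_scheme()
#' minimizer_scheme(protein = TRUE)
#' @export
minimizer_scheme <- function(k = if (protein) 15L else 35L,
                             l = if (protein) 12L else 31L,
                             spaces = if (protein) 0L else 7L,
                             toggle = DEFAULT_TOGGLE,
                             protein = FALSE) {
  k <- as.integer(k); l <- as.integer(l); spaces <- as.integer(spaces)
  max_l <- if (protein) 15L else 31L
  if (l < 1L || l > k) stop("need 1 <= l <= k")
  if (l > max_l)
    stop("l must be <= ", max_l,
         if (protein) " in protein mode (4 bits per symbol)"
         else " (2 bits per base in a 64-bit word)")
  if (k > 63L) stop("k must be <= 63")
  if (spaces < 0L || 2L * spaces > l)
    stop("need 2 * spaces <= l")
  bits <- if (protein) 4L else 2L
  structure(
    list(k = k, l = l, spaces = spaces,
         toggle = tolower(toggle),
         mask = .spaced_mask_cpp(l, spaces, bits),
         bits_per_char = bits, protein = protein),
    class = "minimizer_scheme")
}

#' @export
print.minimizer_scheme <- function(x, ...) {
  cat(sprintf(
    "minimizer scheme: k=%d l=%d spaces=%d mode=%s\n  mask=%s toggle=%s\n",
    x$k, x$l, x$spaces, if (x$protein) "protein" else "nucleotide",
    x$mask, x$toggle))
  invisible(x)
}

#' Pack a DNA window into a 2-bit code
#'
#' A, C, G, T (case-insensitive) map to 0..3, most significant first.  Any
#' other character sets the `ambiguous` flag; ambiguity is reported, not an
#' error, because the scanning machinery simply skips k-mers that overlap
#' ambiguous bases.
#'
#' @param sequence character scalar.
#' @param start 1-based window start.
#' @param length window length, at most 31.
#' @return list with `code` (hex string) and `ambiguous` (logical).
#' @examples
#' encode_window("ACGT", 1, 4)  # code 0x1b
#' @export
encode_window <- function(sequence, start = 1L, length = nchar(sequence)) {
  .encode_window_cpp(sequence, as.integer(start), as.integer(length))
}

#' Canonical form of an l-mer code
#'
#' The numerically smaller of a code and its reverse complement, which under
#' the 2-bit packing is the lexicographically smaller of the two strings
#' (A < C < G < T).  Makes the strand of origin irrelevant.
#'
#' @param code 2l-bit code as hex string.
#' @param l l-mer length in bases.
#' @return hex string of the canonical code.
#' @export
canonical_code <- function(code, l) {
  vapply(as.character(code), .canonical_code_cpp, "", l = as.integer(l),
         USE.NAMES = FALSE)
}

#' Reverse complement of an l-mer code
#' @inheritParams canonical_code
#' @return hex string.
#' @export
revcomp_code <- function(code, l) {
  vapply(as.character(code), .revcomp_code_cpp, "", l = as.integer(l),
         USE.NAMES = FALSE)
}

#' Spaced-seed mask
#'
#' Builds the 2l-bit (or 4l-bit in protein mode) mask that zeroes `s` masked
#' character positions: beginning with the next-to-rightmost position, every
#' other position is masked until `s` positions have been masked.  With
#' `l = 12`, `s = 3` the position pattern is `111111010101`.
#'
#' @param l minimizer length in characters.
#' @param s number of masked positions, `2 * s <= l`.
#' @param bits_per_char 2 for nucleotide codes, 4 for reduced protein
#'   symbols.
#' @return hex string of the mask.
#' @export
spaced_seed_mask <- function(l, s, bits_per_char = 2L) {
  .spaced_mask_cpp(as.integer(l), as.integer(s), as.integer(bits_per_char))
}

#' Candidate ordering value of a canonical l-mer
#'
#' The value inserted into the sliding-window deque and, for the winning
#' candidate, stored in and queried against the hash table:
#' `(canonical_code AND mask) XOR toggle`.
#'
#' @param code canonical l-mer code (hex string).
#' @param scheme a [minimizer_scheme()].
#' @return hex string.
#' @export
candidate_value <- function(code, scheme) {
  vapply(as.character(code), .candidate_value_cpp, "",
         mask_hex = scheme$mask, toggle_hex = scheme$toggle,
         USE.NAMES = FALSE)
}

#' Minimizers of every k-mer of a sequence
#'
#' Slides a window of `k - l + 1` candidate l-mers over the sequence with a
#' double-ended queue, emitting the minimum candidate value for each k-mer
#' in amortized O(1) per base.  K-mers overlapping an ambiguous character
#' are omitted entirely.  Ties within a window keep the leftmost occurrence.
#'
#' @param sequence character scalar (DNA, or reduced protein symbols
#'   `A`..`P` when the scheme is in protein mode).
#' @param scheme a [minimizer_scheme()].
#' @return data.frame with `pos` (1-based k-mer start) and `value`
#'   (minimizer value, hex string), one row per unambiguous k-mer.
#' @examples
#' minimizers_of("ACGTACGTACGT", minimizer_scheme(k = 6, l = 4, spaces = 0))
#' @export
minimizers_of <- function(sequence, scheme) {
  res <- .minimizers_cpp(sequence, scheme$k, scheme$l, scheme$mask,
                         scheme$toggle, scheme$protein)
  data.frame(pos = res$pos, value = res$value, stringsAsFactors = FALSE)
}

#' Hash-based subsampling threshold
#'
#' To keep an expected fraction `f` of minimizers, only those whose hash
#' `fmix64(m)` is at least `v = (1 - f) * M` are retained, where `M` is the
#' maximum 64-bit hash value.  The same threshold is applied when building a
#' database and when classifying, so sub-threshold minimizers are never
#' looked up.
#'
#' @param f fraction in (0, 1].
#' @return list with `f`, `v` (minimum allowable hash value, hex string) and
#'   `M` (maximum hash value, hex string).
#' @examples
#' subsample_threshold(1)    # v = 0, everything retained
#' subsample_threshold(0.25)
#' @export
subsample_threshold <- function(f) {
  list(f = as.numeric(f), v = .subsample_threshold_cpp(as.numeric(f)),
       M = "ffffffffffffffff")
}

#' Which minimizer values pass the subsampling threshold?
#'
#' @param values character vector of minimizer values (hex strings).
#' @param config a [subsample_threshold()] result.
#' @return logical vector: `fmix64(value) >= v`.
#' @export
minimizer_retained <- function(values, config) {
  h <- fmix64(values)
  # hex strings of equal width compare like the underlying integers
  h >= config$v
}
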