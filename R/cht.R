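# The probabilistic compact hash table (CHT): a fixed array of 32-bit
# cells, each split into a compact hash code (the most significant
# `32 - value_bits` bits of the key's fmix64 hash) and a taxon value.
# Collision resolution is linear probing with wrap-around.  A zero cell
# means empty, so value 0 is reserved and a legitimate all-zero compact
# code is remapped to 1.  Because only a truncated hash survives, the table
# can report false presences and confuse the values of two keys; both
# failure modes only ever elevate an LCA, never invent a disjoint taxon for
# an inserted key.

#' Create a compact hash table
#'
#' @param cell_count number of 32-bit cells (fixed for the table's
#'   lifetime; the structure cannot be resized).
#' @param value_bits number of low-order bits per cell reserved for the
#'   taxon value, in 1..31; the remaining `32 - value_bits` bits store the
#'   compact hash code.
#' @return an object of class `compact_hash_table`.
#' @examples
#' tab <- cht_create(64, 17)
#' @export
cht_create <- function(cell_count, value_bits) {
  structure(list(ptr = .cht_create_cpp(as.numeric(cell_count),
                                       as.integer(value_bits))),
            class = "compact_hash_table")
}

#' @export
print.compact_hash_table <- function(x, ...) {
  info <- cht_info(x)
  cat(sprintf(
    "compact hash table: %s cells, %d value bits (%d key bits), %s occupied (load %.3f)\n",
    format(info$cell_count, big.mark = ","), info$value_bits, info$key_bits,
    format(info$occupied, big.mark = ","), info$load))
  invisible(x)
}

#' Table metadata
#' @param table a [cht_create()] object.
#' @return list with `cell_count`, `value_bits`, `key_bits`, `occupied`,
#'   `load`, and `probes` (number of lookups performed so far, useful for
#'   instrumentation).
#' @export
cht_info <- function(table) {
  info <- .cht_info_cpp(table$ptr)
  info$load <- info$occupied / info$cell_count
  info
}

#' Look up keys
#'
#' Probes cells linearly from `fmix64(key) mod cell_count`, wrapping at the
#' end of the array; the first cell whose compact code matches yields the
#' stored value, the first empty cell (or a full cycle) yields 0 (absent).
#'
#' @param table a [cht_create()] object.
#' @param keys character vector of 64-bit minimizer values (hex strings).
#' @return integer vector of stored taxon values, 0 where absent.
#' @export
cht_find <- function(table, keys) .cht_find_cpp(table$ptr, as.character(keys))

#' Insert a key with LCA merging
#'
#' If the key's probe path reaches an empty cell first, the pair is written
#' there.  If a matching compact code is found first, the stored value is
#' replaced by the LCA of the stored taxon and the new taxon, so repeated
#' identical inserts are idempotent and insertion order never matters.  A
#' table with no room left raises an error (build sizing keeps load at
#' about 0.7, so this signals misuse).
#'
#' @param table a [cht_create()] object (modified in place).
#' @param keys character vector of hex keys.
#' @param taxa integer internal taxon IDs (recycled if scalar).
#' @param tax an `internal_taxonomy` supplying the parent array for LCA
#'   computation.
#' @return invisibly, the table.
#' @export
cht_set_lca <- function(table, keys, taxa, tax) {
  keys <- as.character(keys)
  taxa <- rep_len(as.integer(taxa), length(keys))
  .cht_set_lca_cpp(table$ptr, keys, taxa, as.integer(tax$parent))
  invisible(table)
}

#' Raw cells of a table
#' @param table a [cht_create()] object.
#' @return numeric vector of 32-bit cell words (0 = empty).
#' @export
cht_cells <- function(table) .cht_cells_cpp(table$ptr)

#' Probe target of a key
#'
#' The compact code and 0-based starting cell a key would use; exposed so
#' that adversarial key pairs (same compact code, adjacent probe paths) can
#' be constructed when studying the table's false-positive mode.
#'
#' @param key hex key.
#' @param cell_count,value_bits table geometry.
#' @return list with `code` and `index0`.
#' @export
cht_slot <- function(key, cell_count, value_bits) {
  .hash_slot_cpp(as.character(key), as.numeric(cell_count),
                 as.integer(value_bits))
}

#' Serialize / deserialize a table
#'
#' Binary layout: 8-byte magic `MINLCA01`, `cell_count` (uint64),
#' `occupied` (uint64), `value_bits` (uint32), 4 reserved bytes, then the
#' cells as little-endian uint32 words.  The round trip is bit-exact; a bad
#' magic, corrupt header, or truncated payload is a hard error.
#'
#' @param table a [cht_create()] object.
#' @param path file path.
#' @return `cht_save`: invisibly, the table; `cht_load`: a
#'   `compact_hash_table`.
#' @export
cht_save <- function(table, path) {
  .cht_save_cpp(table$ptr, path.expand(path))
  invisible(table)
}

#' @rdname cht_save
#' @export
cht_load <- function(path) {
  structure(list(ptr = .cht_load_cpp(path.expand(path))),
            class = "compact_hash_table")
}
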