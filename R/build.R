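# Database construction: sketch-based capacity estimation, table sizing at
# a 70% load factor, the library scan populating LCA values, and the
# analytic size models for the legacy sorted-list index and the compact
# hash table.

normalize_library <- function(library) {
  if (is.data.frame(library)) {
    stopifnot(all(c("id", "seq") %in% names(library)))
    setNames(as.character(library$seq), as.character(library$id))
  } else if (is.character(library)) {
    if (is.null(names(library)))
      names(library) <- paste0("seq", seq_along(library))
    library
  } else stop("library must be a named character vector or data.frame(id, seq)")
}

#' Estimate the number of distinct minimizers in a library
#'
#' Zeroth-frequency-moment estimation: only distinct minimizer values `m`
#' with `fmix64(m) mod F < E` are kept in a small set `Q`; the estimate is
#' `D = |Q| * F / E`.  Memory is proportional to `|Q|` (about `E/F` of the
#' distinct minimizers).  `E = F` degenerates to the exact distinct count.
#'
#' @param library named character vector of sequences, or data.frame with
#'   `id` and `seq` columns.
#' @param scheme a [minimizer_scheme()].
#' @param E,F sketch parameters, `1 <= E <= F`; defaults `E = 4`,
#'   `F = 1024`.
#' @return list with `D` (the estimate), `Q_size`, `E`, `F`.
#' @export
estimate_capacity <- function(library, scheme, E = 4, F = 1024) {
  seqs <- unname(normalize_library(library))
  q <- .capacity_sketch_cpp(seqs, scheme$k, scheme$l, scheme$mask,
                            scheme$toggle, scheme$protein, E, F)
  list(D = q * F / E, Q_size = q, E = E, F = F)
}

#' Exact distinct-minimizer count of a library
#' @inheritParams estimate_capacity
#' @return numeric count.
#' @export
count_distinct_minimizers <- function(library, scheme) {
  seqs <- unname(normalize_library(library))
  .distinct_minimizers_cpp(seqs, scheme$k, scheme$l, scheme$mask,
                           scheme$toggle, scheme$protein)
}

#' Build a minimizer-LCA database
#'
#' Prunes the taxonomy to the taxa carrying sequences, renumbers it
#' breadth-first, estimates the distinct-minimizer count `D`, allocates a
#' compact hash table of `ceiling(D / 0.7)` cells (a 70% target load
#' factor) with just enough value bits for the renumbered taxonomy, and
#' scans the library inserting every retained minimizer with LCA merging.
#'
#' If `max_cells` is smaller than the required capacity, hash-based
#' subsampling kicks in with `f = max_cells * 0.7 / D` and the
#' corresponding minimum hash threshold, at both build and classify time.
#'
#' Sequences without a taxon mapping are skipped with a warning.  For small
#' libraries (sketch `|Q| < 100`) the capacity is counted exactly instead
#' of estimated, since the sketch's variance would dominate.
#'
#' @param library named character vector of sequences (names are sequence
#'   IDs), or data.frame with `id`, `seq`.
#' @param taxon_map named integer vector mapping sequence ID to external
#'   taxon ID, or data.frame with `id`, `taxid`.
#' @param tree a [taxonomy_tree()] covering all mapped taxa.
#' @param scheme a [minimizer_scheme()].
#' @param max_cells optional cap on the number of hash cells.
#' @param E,F capacity-sketch parameters.
#' @return an object of class `minimizer_db` with fields `scheme`, `table`,
#'   `taxonomy`, `subsample`, `metadata`.
#' @export
build_database <- function(library, taxon_map, tree, scheme,
                           max_cells = NULL, E = 4, F = 1024) {
  seqs <- normalize_library(library)
  if (length(seqs) == 0) stop("empty reference library")
  if (is.data.frame(taxon_map)) {
    stopifnot(all(c("id", "taxid") %in% names(taxon_map)))
    taxon_map <- setNames(as.integer(taxon_map$taxid),
                          as.character(taxon_map$id))
  }
  taxids <- taxon_map[names(seqs)]
  if (anyNA(taxids)) {
    skipped <- names(seqs)[is.na(taxids)]
    warning("skipping ", length(skipped),
            " sequence(s) without a taxon mapping: ",
            paste(head(skipped, 5), collapse = ", "))
    seqs <- seqs[!is.na(taxids)]
    taxids <- taxids[!is.na(taxids)]
  }
  if (length(seqs) == 0) stop("no sequences with taxon mappings remain")

  if (scheme$protein) {
    # protein libraries arrive as amino-acid letters; the scan machinery
    # works on reduced 4-bit symbols, so reduce once here and record the
    # alphabet on the scheme (and hence in the manifest)
    alphabet <- attr(scheme, "alphabet") %||% reduced_alphabet()
    attr(scheme, "alphabet") <- alphabet
    seqs[] <- reduce_protein(unname(seqs), alphabet)
  }

  pruned <- prune_minimal(tree, unique(taxids))
  tax <- assign_internal_ids(pruned)
  value_bits <- max(1L, ceiling(log2(tax$n_nodes + 1)))
  if (value_bits > 31L) stop("taxonomy too large for 31 value bits")

  est <- estimate_capacity(seqs, scheme, E = E, F = F)
  if (est$Q_size < 100) {
    D <- count_distinct_minimizers(seqs, scheme)
    capacity_mode <- "exact"
  } else {
    D <- est$D
    capacity_mode <- "sketch"
  }
  if (D == 0) stop("library yields no minimizers (sequences shorter than k?)")

  cells <- ceiling(D / 0.7)
  f <- 1
  if (!is.null(max_cells) && max_cells < cells) {
    cells <- as.numeric(max_cells)
    f <- min(1, cells * 0.7 / D)
  }
  sub <- subsample_threshold(f)

  table <- cht_create(cells, value_bits)
  internal_taxa <- unname(tax$external_to_internal[as.character(taxids)])
  .build_cht_cpp(table$ptr, unname(seqs), as.integer(internal_taxa),
                 scheme$k, scheme$l, scheme$mask, scheme$toggle,
                 scheme$protein, sub$v, as.integer(tax$parent))

  structure(list(scheme = scheme, table = table, taxonomy = tax,
                 subsample = sub,
                 metadata = list(format_version = 1L,
                                 n_sequences = length(seqs),
                                 capacity_estimate = D,
                                 capacity_mode = capacity_mode,
                                 value_bits = value_bits)),
            class = "minimizer_db")
}

#' @export
print.minimizer_db <- function(x, ...) {
  info <- cht_info(x$table)
  cat(sprintf(
    paste0("minimizer database: k=%d l=%d spaces=%d (%s)\n",
           "  taxonomy: %d nodes; value bits: %d\n",
           "  table: %s cells, %s occupied (load %.3f); subsample f=%g\n"),
    x$scheme$k, x$scheme$l, x$scheme$spaces,
    if (x$scheme$protein) "protein" else "nucleotide",
    x$taxonomy$n_nodes, info$value_bits,
    format(info$cell_count, big.mark = ","),
    format(info$occupied, big.mark = ","), info$load, x$subsample$f))
  invisible(x)
}

#' Save / load a database directory
#'
#' A database is a directory holding the binary hash table (`hash.bin`),
#' the human-readable taxonomy sidecar TSV (`taxonomy.tsv`), and a JSON
#' manifest echoing the scheme, subsampling threshold, and build metadata.
#'
#' @param db a [build_database()] result.
#' @param dir directory path (created if needed).
#' @return `save_database`: invisibly, `dir`; `load_database`: a
#'   `minimizer_db`.
#' @export
save_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cht_save(db$table, file.path(dir, "hash.bin"))
  write_taxonomy_sidecar(db$taxonomy, file.path(dir, "taxonomy.tsv"))
  manifest <- list(format_version = db$metadata$format_version,
                   k = db$scheme$k, l = db$scheme$l,
                   spaces = db$scheme$spaces, toggle = db$scheme$toggle,
                   protein = db$scheme$protein,
                   subsample_f = db$subsample$f, subsample_v = db$subsample$v,
                   metadata = db$metadata,
                   alphabet = if (db$scheme$protein)
                     as.list(attr(db$scheme, "alphabet") %||%
                               reduced_alphabet()) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_database
#' @export
load_database <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  scheme <- minimizer_scheme(k = man$k, l = man$l, spaces = man$spaces,
                             toggle = man$toggle,
                             protein = isTRUE(man$protein))
  if (isTRUE(man$protein) && !is.null(man$alphabet))
    attr(scheme, "alphabet") <- unlist(man$alphabet)
  structure(list(scheme = scheme,
                 table = cht_load(file.path(dir, "hash.bin")),
                 taxonomy = read_taxonomy_sidecar(file.path(dir,
                                                            "taxonomy.tsv")),
                 subsample = list(f = man$subsample_f, v = man$subsample_v,
                                  M = "ffffffffffffffff"),
                 metadata = man$metadata),
            class = "minimizer_db")
}

#' Size model for a first-generation sorted k-mer/LCA list database
#'
#' With `X` distinct k-mers, the pair file is `1072 + 12 X` bytes (a
#' 1072-byte header plus 12 bytes per k-mer/LCA pair) and the minimizer
#' offset index is `8 * (4^idx_minimizer_len + 2)` bytes; at the default
#' index minimizer length of 15 the index alone is 8,589,934,608 bytes.
#'
#' @param X number of distinct k-mers.
#' @param idx_minimizer_len index minimizer length (default 15).
#' @return named numeric vector with `kdb`, `idx`, `total` (bytes).
#' @export
k1_db_size <- function(X, idx_minimizer_len = 15) {
  stopifnot(X >= 0)
  kdb <- 1072 + 12 * X
  idx <- 8 * (4^idx_minimizer_len + 2)
  c(kdb = kdb, idx = idx, total = kdb + idx)
}

#' Size model for a compact-hash-table database
#'
#' With `Y` distinct minimizers and a 0.7 load factor, the table file is
#' `32 + floor(4 Y / 0.7)` bytes (32 bytes of metadata, 4 bytes per cell).
#'
#' @param Y number of distinct minimizers.
#' @return size in bytes.
#' @export
k2_db_size <- function(Y) {
  stopifnot(Y >= 0)
  32 + floor(4 * Y / 0.7)
}

#' Per-entry size ratio of the two database layouts
#'
#' The linear-term coefficients are `4/0.7` bytes per distinct minimizer
#' versus `12` bytes per distinct k-mer; with `ratio` distinct k-mers per
#' distinct minimizer the compact layout is `(4/0.7) / (12 * ratio)` of the
#' sorted-list layout.
#'
#' @param kmer_minimizer_ratio distinct k-mers per distinct minimizer
#'   (about 3.1 at default parameters on real libraries).
#' @return numeric ratio.
#' @export
db_size_ratio <- function(kmer_minimizer_ratio = 3.1) {
  (4 / 0.7) / (12 * kmer_minimizer_ratio)
}
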