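# Fragment classification: per-k-mer minimizer lookups with a depth-1
# cache, hit-count accumulation over the taxonomy, and resolution by the
# maximally scoring root-to-leaf path.  Output follows the k-mer
# classifier community's established dialect
# (one TSV row per fragment, plus an indented clade-rollup report).

#' Collect per-k-mer LCA hits for one sequence
#'
#' Every k-mer contributes one count to the taxon its minimizer maps to
#' (0 for no hit).  Consecutive k-mers sharing a minimizer reuse the
#' previous lookup without re-probing the table; k-mers overlapping an
#' ambiguous character are recorded as an ambiguous run and never looked
#' up; minimizers below the hash-subsampling threshold count as no-hit
#' without a probe.
#'
#' @param db a [build_database()] result.
#' @param sequence character scalar (DNA for nucleotide databases, reduced
#'   protein symbols for protein databases).
#' @return list with `hit_counts` (named integer, internal taxon ->
#'   k-mer count, taxa >= 1 only), `runs` (data.frame `taxon`, `count`;
#'   taxon -1 marks ambiguous runs, 0 no-hit runs), `total_kmers`, and
#'   `n_lookups` (table probes actually performed).
#' @export
collect_hits <- function(db, sequence) {
  res <- .collect_hits_cpp(db$table$ptr, sequence, db$scheme$k, db$scheme$l,
                           db$scheme$mask, db$scheme$toggle,
                           db$scheme$protein, db$subsample$v)
  runs <- data.frame(taxon = res$run_taxa, count = res$run_lens)
  hit <- runs$taxon >= 1L
  counts <- integer(0)
  if (any(hit))
    counts <- vapply(split(runs$count[hit], runs$taxon[hit]), sum, 0L)
  list(hit_counts = counts, runs = runs,
       total_kmers = res$total_kmers, n_lookups = res$n_lookups)
}

#' Resolve pooled hit counts to a taxon
#'
#' Builds the tree of taxa with nonzero counts plus their ancestors, scores
#' every leaf of that tree by the sum of counts along its root-to-leaf
#' path, and returns the maximally scoring leaf.  Ties go to the LCA of all
#' tied leaves; all-zero counts yield 0 (unclassified).
#'
#' @param hit_counts named integer vector (names = internal taxon IDs).
#' @param tax an `internal_taxonomy`.
#' @return internal taxon ID, or 0.
#' @export
resolve_hits <- function(hit_counts, tax) {
  hit_counts <- hit_counts[hit_counts > 0]
  if (length(hit_counts) == 0) return(0L)
  taxa <- as.integer(names(hit_counts))
  paths <- lapply(taxa, function(t) {
    p <- t
    while (t != 1L) { t <- tax$parent[t]; p <- c(p, t) }
    p
  })
  # leaves of the pruned tree: counted taxa that are on no other counted
  # taxon's strict ancestor path
  strict_anc <- unique(unlist(lapply(paths, `[`, -1L)))
  leaves <- taxa[!(taxa %in% strict_anc)]
  scores <- vapply(seq_along(taxa), function(i) {
    sum(hit_counts[as.character(intersect(paths[[i]], taxa))])
  }, 0)
  names(scores) <- taxa
  leaf_scores <- scores[as.character(leaves)]
  best <- leaves[leaf_scores == max(leaf_scores)]
  if (length(best) == 1L) best else lca_all(tax, best)
}

#' Classify a fragment (single- or paired-end)
#'
#' Mates are processed independently for hits; their counts are pooled
#' before resolution, and the reported hit runs keep a mate-boundary
#' marker between the two mates.
#'
#' @param db a nucleotide-mode [build_database()] result.
#' @param mate1 character scalar, the (first) read.
#' @param mate2 optional second mate.
#' @param fragment_id identifier carried into the output.
#' @return an object of class `read_classification`: fields `classified`,
#'   `external_taxon` (0 if unclassified), `internal_taxon`, `fragment_id`,
#'   `lengths`, `hit_runs` (data.frame `taxon` external ID with -1 =
#'   ambiguous and -2 = mate boundary, `count`), `total_kmers`.
#' @export
classify_fragment <- function(db, mate1, mate2 = NULL,
                              fragment_id = "fragment") {
  if (db$scheme$protein)
    stop("database is in protein mode; use classify_fragment_translated()")
  h1 <- collect_hits(db, mate1)
  parts <- list(h1)
  if (!is.null(mate2)) parts <- c(parts, list(collect_hits(db, mate2)))
  finalize_classification(db, parts, fragment_id,
                          lengths = c(nchar(mate1),
                                      if (!is.null(mate2)) nchar(mate2)),
                          paired = !is.null(mate2))
}

# Pool hit counts from the mates/frames in `parts`, resolve, and map back
# to external IDs.  `parts` is a list of collect_hits() results; a mate
# boundary (-2) separates consecutive parts when paired.
finalize_classification <- function(db, parts, fragment_id, lengths,
                                    paired) {
  pooled <- integer(0)
  for (p in parts) {
    for (nm in names(p$hit_counts))
      pooled[nm] <- (if (nm %in% names(pooled)) pooled[[nm]] else 0L) +
        p$hit_counts[[nm]]
  }
  internal <- resolve_hits(pooled, db$taxonomy)
  external <- if (internal > 0)
    db$taxonomy$internal_to_external[internal] else 0L
  runs <- list()
  for (i in seq_along(parts)) {
    r <- parts[[i]]$runs
    if (nrow(r) > 0) {
      ext <- r$taxon
      pos <- ext >= 1L
      ext[pos] <- db$taxonomy$internal_to_external[r$taxon[pos]]
      r$taxon <- ext
    }
    runs[[length(runs) + 1L]] <- r
    if (paired && i < length(parts))
      runs[[length(runs) + 1L]] <- data.frame(taxon = -2L, count = 0L)
  }
  runs <- do.call(rbind, runs)
  structure(list(classified = internal > 0,
                 external_taxon = as.integer(external),
                 internal_taxon = as.integer(internal),
                 fragment_id = fragment_id, lengths = lengths,
                 hit_runs = runs,
                 total_kmers = sum(vapply(parts, `[[`, 0L, "total_kmers"))),
            class = "read_classification")
}

#' @export
print.read_classification <- function(x, ...) {
  cat(sprintf("%s\t%s -> taxon %d (%d k-mers)\n",
              if (x$classified) "C" else "U", x$fragment_id,
              x$external_taxon, x$total_kmers))
  invisible(x)
}

#' Classify a batch of reads
#'
#' @param db a [build_database()] result.
#' @param reads1 data.frame with `id` and `seq` (e.g. from
#'   [read_sequences()]).
#' @param reads2 optional data.frame of second mates, same order.
#' @return list of `read_classification` objects.
#' @export
classify_reads <- function(db, reads1, reads2 = NULL) {
  translated <- db$scheme$protein
  lapply(seq_len(nrow(reads1)), function(i) {
    m2 <- if (!is.null(reads2)) reads2$seq[i]
    if (translated)
      classify_fragment_translated(db, reads1$seq[i], m2,
                                   fragment_id = reads1$id[i])
    else
      classify_fragment(db, reads1$seq[i], m2, fragment_id = reads1$id[i])
  })
}

format_hit_runs <- function(runs) {
  if (is.null(runs) || nrow(runs) == 0) return("0:0")
  parts <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    t <- runs$taxon[i]
    parts[i] <- if (t == -2L) "|:|"
    else if (t == -1L) paste0("A:", runs$count[i])
    else paste0(t, ":", runs$count[i])
  }
  paste(parts, collapse = " ")
}

#' Write per-fragment classification output
#'
#' One TSV row per fragment: `C`/`U`, fragment ID, external taxon, length
#' (`len1|len2` for pairs), and the space-separated hit runs as
#' `taxid:count` with `A:count` for ambiguous runs and `|:|` at the mate
#' boundary.
#'
#' @param classifications list of `read_classification` objects.
#' @param path output file path or connection.
#' @return invisibly, the number of rows written.
#' @export
write_output <- function(classifications, path) {
  lines <- vapply(classifications, function(x) {
    paste(if (x$classified) "C" else "U", x$fragment_id, x$external_taxon,
          paste(x$lengths, collapse = "|"), format_hit_runs(x$hit_runs),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(length(lines))
}

rank_code <- function(rank) {
  codes <- c(root = "R", domain = "D", superkingdom = "D", kingdom = "K",
             phylum = "P", class = "C", order = "O", family = "F",
             genus = "G", species = "S", subspecies = "S", strain = "S")
  out <- codes[rank]
  out[is.na(out)] <- "-"
  unname(out)
}

#' Write a clade-rollup report
#'
#' One row per taxon with percentage of fragments, clade count (taxon plus
#' all descendants), direct count, rank code, external ID, and the name
#' indented two spaces per tree depth; an `unclassified` row comes first.
#'
#' @param classifications list of `read_classification` objects.
#' @param tax an `internal_taxonomy`.
#' @param path output file path or connection.
#' @return invisibly, a data.frame of the report.
#' @export
write_report <- function(classifications, tax, path) {
  n <- length(classifications)
  direct <- integer(tax$n_nodes)
  unclassified <- 0L
  for (x in classifications) {
    if (x$internal_taxon > 0)
      direct[x$internal_taxon] <- direct[x$internal_taxon] + 1L
    else unclassified <- unclassified + 1L
  }
  clade <- direct
  for (i in rev(seq_len(tax$n_nodes))) {
    if (i > 1L) clade[tax$parent[i]] <- clade[tax$parent[i]] + clade[i]
  }
  depth <- integer(tax$n_nodes)
  for (i in seq_len(tax$n_nodes))
    if (i > 1L) depth[i] <- depth[tax$parent[i]] + 1L
  keep <- which(clade > 0)
  df <- data.frame(
    pct = round(100 * c(unclassified, clade[keep]) / max(1L, n), 2),
    clade_count = c(unclassified, clade[keep]),
    direct_count = c(unclassified, direct[keep]),
    rank = c("U", rank_code(tax$rank_of[keep])),
    external_id = c(0L, tax$internal_to_external[keep]),
    name = c("unclassified",
             paste0(strrep("  ", depth[keep]), tax$name_of[keep])),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(df)
}
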