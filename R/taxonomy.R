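# Taxonomy handling: NCBI-dump-dialect parsing, pruning to the minimal node
# set covering a reference library, breadth-first internal renumbering
# (ancestors always get smaller IDs than descendants), and LCA queries that
# exploit that numbering.

#' Construct a taxonomy tree from a node table
#'
#' @param nodes data.frame with integer columns `external_id`,
#'   `parent_external`, plus character `rank` and `name`.  The root is the
#'   node whose parent equals itself (the NCBI convention).
#' @return an object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("external_id", "parent_external", "rank", "name") %in%
                  names(nodes)))
  nodes$external_id <- as.integer(nodes$external_id)
  nodes$parent_external <- as.integer(nodes$parent_external)
  if (anyDuplicated(nodes$external_id)) {
    dup <- nodes$external_id[duplicated(nodes$external_id)][1]
    stop("duplicate node row for taxon ", dup)
  }
  root <- nodes$external_id[nodes$external_id == nodes$parent_external]
  if (length(root) != 1L)
    stop("expected exactly one root (parent == self), found ", length(root))
  missing_parent <- setdiff(nodes$parent_external, nodes$external_id)
  if (length(missing_parent) > 0)
    stop("node references missing parent taxon ", missing_parent[1])
  nodes <- nodes[order(nodes$external_id), , drop = FALSE]
  rownames(nodes) <- NULL
  tree <- structure(list(nodes = nodes, root = root),
                    class = "taxonomy_tree")
  # cycle check: every node must reach the root
  for (id in tree$nodes$external_id) ancestors_of(tree, id)
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy tree: %d nodes, root external ID %d\n",
              nrow(x$nodes), x$root))
  invisible(x)
}

parent_lookup <- function(tree) {
  setNames(tree$nodes$parent_external, tree$nodes$external_id)
}

#' Ancestors of a node (external IDs)
#'
#' Root-to-node path excluding nothing: the node itself is included, the
#' root is last.
#'
#' @param tree a [taxonomy_tree()].
#' @param external_id node to start from.
#' @return integer vector, node first, root last.
#' @export
ancestors_of <- function(tree, external_id) {
  par <- parent_lookup(tree)
  id <- as.integer(external_id)
  if (is.na(par[as.character(id)]))
    stop("taxon ", external_id, " not in tree")
  out <- integer(0)
  n <- length(par)
  for (i in seq_len(n + 1L)) {
    out <- c(out, id)
    if (id == tree$root) return(out)
    id <- par[[as.character(id)]]
  }
  stop("cycle detected walking parents from taxon ", external_id)
}

parse_dmp <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else source
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load an NCBI-dump-style taxonomy
#'
#' Parses the `nodes.dmp` dialect (fields separated by `"\t|\t"`, records
#' terminated by `"\t|"`): field 1 is the taxon ID, field 2 its parent,
#' field 3 its rank.  The optional names source contributes only rows whose
#' name class is `"scientific name"`; absent names default to
#' `"taxid <id>"`.
#'
#' @param nodes_source path to a nodes file, or a character vector of its
#'   lines.
#' @param names_source optional path or lines of a names file.
#' @return a [taxonomy_tree()].
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  recs <- parse_dmp(nodes_source)
  if (any(lengths(recs) < 3L))
    stop("malformed nodes record (fewer than 3 fields)")
  ext <- as.integer(vapply(recs, `[[`, "", 1L))
  par <- as.integer(vapply(recs, `[[`, "", 2L))
  rank <- trimws(vapply(recs, `[[`, "", 3L))
  name <- paste("taxid", ext)
  if (!is.null(names_source)) {
    nrecs <- parse_dmp(names_source)
    keep <- vapply(nrecs, function(r)
      length(r) >= 4L && trimws(r[[4L]]) == "scientific name", logical(1))
    nrecs <- nrecs[keep]
    nm_id <- as.integer(vapply(nrecs, `[[`, "", 1L))
    nm_txt <- trimws(vapply(nrecs, `[[`, "", 2L))
    hit <- match(ext, nm_id)
    name[!is.na(hit)] <- nm_txt[hit[!is.na(hit)]]
  }
  taxonomy_tree(data.frame(external_id = ext, parent_external = par,
                           rank = rank, name = name,
                           stringsAsFactors = FALSE))
}

#' Write a taxonomy in the NCBI dump dialect
#'
#' Emits `nodes.dmp`- and `names.dmp`-style files that [load_taxonomy()]
#' reads back identically (structure, ranks, scientific names).
#'
#' @param tree a [taxonomy_tree()].
#' @param nodes_path,names_path output file paths.
#' @return invisibly, the tree.
#' @export
write_taxonomy_dump <- function(tree, nodes_path, names_path = NULL) {
  n <- tree$nodes
  writeLines(paste0(n$external_id, "\t|\t", n$parent_external, "\t|\t",
                    n$rank, "\t|"), nodes_path)
  if (!is.null(names_path))
    writeLines(paste0(n$external_id, "\t|\t", n$name, "\t|\t", "", "\t|\t",
                      "scientific name", "\t|"), names_path)
  invisible(tree)
}

#' Prune a taxonomy to the minimal set covering assigned taxa
#'
#' Keeps exactly the assigned nodes plus all of their ancestors; parent
#' links are preserved, so the result is again a tree rooted at the original
#' root.
#'
#' @param tree a [taxonomy_tree()].
#' @param assigned integer vector of external taxon IDs that carry reference
#'   sequences.
#' @return a pruned [taxonomy_tree()].
#' @export
prune_minimal <- function(tree, assigned) {
  assigned <- unique(as.integer(assigned))
  missing <- setdiff(assigned, tree$nodes$external_id)
  if (length(missing) > 0)
    stop("assigned taxon ", missing[1], " not in tree")
  keep <- unique(unlist(lapply(assigned, function(a) ancestors_of(tree, a))))
  taxonomy_tree(tree$nodes[tree$nodes$external_id %in% keep, , drop = FALSE])
}

#' Assign BFS internal IDs
#'
#' Numbers the nodes breadth-first from the root (internal ID 1), siblings
#' in ascending external-ID order so the numbering is deterministic.  The
#' BFS guarantees `parent[i] < i` for every non-root node, which is what
#' makes the [lca()] walk valid.  Internal ID 0 is reserved for "no taxon".
#'
#' @param tree a (typically pruned) [taxonomy_tree()].
#' @return an object of class `internal_taxonomy` with fields `n_nodes`,
#'   `parent` (integer vector, `parent[1] = 0`), `internal_to_external`,
#'   `external_to_internal` (named integer vector), `rank_of`, `name_of`.
#' @export
assign_internal_ids <- function(tree) {
  n <- tree$nodes
  children <- split(n$external_id, n$parent_external)
  order_ext <- integer(nrow(n))
  parent_int <- integer(nrow(n))
  order_ext[1] <- tree$root
  int_of <- c(setNames(1L, as.character(tree$root)))
  head_i <- 1L; tail_i <- 1L
  while (head_i <= tail_i) {
    cur <- order_ext[head_i]
    kids <- sort(setdiff(children[[as.character(cur)]], cur))
    for (kid in kids) {
      tail_i <- tail_i + 1L
      order_ext[tail_i] <- kid
      parent_int[tail_i] <- head_i
      int_of[as.character(kid)] <- tail_i
    }
    head_i <- head_i + 1L
  }
  stopifnot(tail_i == nrow(n))
  idx <- match(order_ext, n$external_id)
  structure(list(n_nodes = nrow(n), parent = parent_int,
                 internal_to_external = order_ext,
                 external_to_internal = int_of,
                 rank_of = n$rank[idx], name_of = n$name[idx]),
            class = "internal_taxonomy")
}

#' @export
print.internal_taxonomy <- function(x, ...) {
  cat(sprintf("internal taxonomy: %d nodes (BFS-numbered, root = 1)\n",
              x$n_nodes))
  invisible(x)
}

#' Lowest common ancestor of two internal taxa
#'
#' Because BFS numbering guarantees that every ancestor has a smaller
#' internal ID than its descendants, the LCA is found by repeatedly
#' replacing the larger of the two IDs with its parent until they meet.
#'
#' @param tax an [assign_internal_ids()] result.
#' @param a,b internal taxon IDs in `1..n_nodes`.
#' @return internal ID of the lowest common ancestor.
#' @examples
#' tr <- taxonomy_tree(data.frame(external_id = 1:3,
#'   parent_external = c(1, 1, 2), rank = "no rank", name = "n"))
#' tax <- assign_internal_ids(tr)
#' lca(tax, 2, 3)
#' @export
lca <- function(tax, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (a < 1L || b < 1L || a > tax$n_nodes || b > tax$n_nodes)
    stop("internal IDs must be in 1..", tax$n_nodes)
  while (a != b) {
    if (a < b) { tmp <- a; a <- b; b <- tmp }
    a <- tax$parent[a]
  }
  a
}

#' Fold [lca()] over a set of internal taxa
#' @param tax an [assign_internal_ids()] result.
#' @param ids integer vector of internal IDs (length >= 1).
#' @return internal ID of their common LCA.
#' @export
lca_all <- function(tax, ids) Reduce(function(a, b) lca(tax, a, b), ids)

#' Write / read the taxonomy sidecar
#'
#' The sidecar is a plain TSV (`internal_id`, `external_id`,
#' `parent_internal_id`, `rank`, `name`) stored alongside the hash table in
#' a database directory, keeping the taxonomy human-inspectable.
#'
#' @param tax an `internal_taxonomy`.
#' @param path TSV path.
#' @return `write_taxonomy_sidecar`: invisibly, `tax`;
#'   `read_taxonomy_sidecar`: an `internal_taxonomy`.
#' @export
write_taxonomy_sidecar <- function(tax, path) {
  df <- data.frame(internal_id = seq_len(tax$n_nodes),
                   external_id = tax$internal_to_external,
                   parent_internal_id = tax$parent,
                   rank = tax$rank_of, name = tax$name_of,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tax)
}

#' @rdname write_taxonomy_sidecar
#' @export
read_taxonomy_sidecar <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  stopifnot(identical(df$internal_id, seq_len(nrow(df))))
  structure(list(n_nodes = nrow(df), parent = df$parent_internal_id,
                 internal_to_external = df$external_id,
                 external_to_internal = setNames(df$internal_id,
                                                 as.character(df$external_id)),
                 rank_of = as.character(df$rank),
                 name_of = as.character(df$name)),
            class = "internal_taxonomy")
}
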