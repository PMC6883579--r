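# Shared fixtures and independent oracles.  Oracles are deliberately
# written as plain R over strings / ancestor sets so they share no code
# path with the deque / BFS / hash-table implementations they check.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# nibble-wise bitwise AND of two 16-digit hex strings
hex_and <- function(a, b) {
  na <- strtoi(strsplit(a, "")[[1]], 16L)
  nb <- strtoi(strsplit(b, "")[[1]], 16L)
  paste(sprintf("%x", bitwAnd(na, nb)), collapse = "")
}

hex_not <- function(a) {
  na <- strtoi(strsplit(a, "")[[1]], 16L)
  paste(sprintf("%x", 15L - na), collapse = "")
}

# random rooted tree as a taxonomy_tree: node i's parent drawn among
# earlier nodes; external IDs shuffled so BFS order != insertion order
rand_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ext <- sample(2:(10 * n), n - 1)
  ext <- c(1L, ext)  # root external ID 1
  parent <- c(1L, vapply(2:n, function(i) ext[sample(i - 1L, 1)], 0L))
  taxonomy_tree(data.frame(external_id = ext, parent_external = parent,
                           rank = "no rank", name = paste("node", ext),
                           stringsAsFactors = FALSE))
}

# ancestor set of an internal ID by parent-walking (oracle for lca)
anc_set <- function(tax, i) {
  out <- i
  while (i != 1L) { i <- tax$parent[i]; out <- c(out, i) }
  out
}

# depth of an internal node by parent-walking
int_depth <- function(tax, i) length(anc_set(tax, i)) - 1L

# brute-force minimizer oracle: recompute each window minimum from
# scratch over all l-mer candidate values (no deque, no rolling codes)
brute_minimizers <- function(seq, scheme) {
  k <- scheme$k; l <- scheme$l
  n <- nchar(seq) - k + 1
  if (n < 1) return(data.frame(pos = integer(0), value = character(0)))
  pos <- integer(0); val <- character(0)
  for (q in seq_len(n)) {
    kmer <- substr(seq, q, q + k - 1)
    if (grepl("[^ACGTacgt]", kmer)) next
    cands <- vapply(seq_len(k - l + 1), function(j) {
      code <- encode_window(kmer, j, l)$code
      candidate_value(canonical_code(code, l), scheme)
    }, "")
    pos <- c(pos, q)
    val <- c(val, min(cands))
  }
  data.frame(pos = pos, value = val, stringsAsFactors = FALSE)
}

# small fixed taxonomy in dump dialect: root -> 2 genera -> 2 species
# each -> leaves; used across classify/evaluation tests
demo_nodes <- c(
  "1\t|\t1\t|\tno rank\t|",
  "10\t|\t1\t|\tclass\t|",
  "20\t|\t10\t|\tgenus\t|",
  "21\t|\t10\t|\tgenus\t|",
  "30\t|\t20\t|\tspecies\t|",
  "31\t|\t20\t|\tspecies\t|",
  "32\t|\t21\t|\tspecies\t|",
  "40\t|\t30\t|\tstrain\t|",
  "41\t|\t30\t|\tstrain\t|")

demo_tree <- function() load_taxonomy(demo_nodes)

# random 64-bit hex strings
rand_hex64 <- function(n) {
  paste0(
    sprintf("%08x", as.integer(floor(runif(n) * 2^31))),
    sprintf("%08x", as.integer(floor(runif(n) * 2^31))))
}
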