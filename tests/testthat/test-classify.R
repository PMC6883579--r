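# A small database over the demo taxonomy: two related strain genomes and
# one distant genome, built once for the whole file.
make_demo_db <- function(seed = 41, glen = 6000) {
  set.seed(seed)
  base <- rand_dna(glen)
  g40 <- base
  g41 <- kmerlca:::mutate_genome(base, 0.01)   # sister strain
  g32 <- rand_dna(glen)                        # unrelated species
  db <- build_database(c(s40 = g40, s41 = g41, s32 = g32),
                       c(s40 = 40L, s41 = 41L, s32 = 32L),
                       demo_tree(), minimizer_scheme())
  list(db = db, g40 = g40, g41 = g41, g32 = g32)
}

demo <- make_demo_db()

test_that("hits on a verbatim substring all fall on the genome's clade", {
  read <- substr(demo$g32, 1001, 1150)
  h <- collect_hits(demo$db, read)
  expect_equal(h$total_kmers, 150 - 35 + 1)
  expect_equal(sum(h$runs$count), h$total_kmers)
  internal32 <- demo$db$taxonomy$external_to_internal[["32"]]
  expect_true(all(names(h$hit_counts) == internal32))
  expect_gt(sum(h$hit_counts), 0)
})

test_that("a foreign read yields no hits and an all-zero run", {
  set.seed(42)
  read <- rand_dna(100)
  h <- collect_hits(demo$db, read)
  expect_equal(length(h$hit_counts), 0)
  expect_true(all(demo$db$taxonomy$internal_to_external[
    h$runs$taxon[h$runs$taxon > 0]] %in% integer(0)))
  expect_equal(sum(h$runs$count), 66)
})

test_that("probes equal the number of distinct consecutive minimizer runs", {
  read <- substr(demo$g40, 2001, 2200)
  h <- collect_hits(demo$db, read)
  mins <- minimizers_of(read, demo$db$scheme)$value
  runs_oracle <- sum(mins != c("", head(mins, -1)))
  expect_equal(h$n_lookups, runs_oracle)
  expect_lt(h$n_lookups, h$total_kmers)  # the cache must actually help
})

test_that("run-length hits are a lossless encoding of per-k-mer LCAs", {
  read <- paste0(substr(demo$g40, 101, 180), "N",
                 substr(demo$g32, 501, 580))
  h <- collect_hits(demo$db, read)
  expect_equal(sum(h$runs$count), h$total_kmers)
  expect_equal(h$total_kmers, nchar(read) - 35 + 1)
  expect_true(-1L %in% h$runs$taxon)  # ambiguous block is recorded
})

test_that("resolve picks the maximally scoring root-to-leaf path", {
  tax <- assign_internal_ids(demo_tree())
  # single taxon
  expect_equal(resolve_hits(c(`5` = 3L), tax), 5L)
  # no hits at all
  expect_equal(resolve_hits(integer(0), tax), 0L)
  # chain: counts on an ancestor and its descendant add up
  # (internal 1 = root, find a chain pair)
  chain_child <- 2L
  expect_equal(resolve_hits(setNames(c(1L, 1L), c(1L, chain_child)), tax),
               chain_child)
})

test_that("tied leaf paths resolve to the LCA of the tied leaves", {
  # root(1) -> A(2) -> {B(3), C(4)}: counts A=1, B=2, C=2 tie at 3 each
  tr <- taxonomy_tree(data.frame(external_id = 1:4,
                                 parent_external = c(1, 1, 2, 2),
                                 rank = "no rank", name = "n"))
  tax <- assign_internal_ids(tr)
  expect_equal(resolve_hits(setNames(c(1L, 2L, 2L), 2:4), tax), 2L)
})

test_that("resolve agrees with brute-force path enumeration", {
  set.seed(43)
  for (rep in 1:20) {
    tax <- assign_internal_ids(rand_tree(15))
    counted <- sample(tax$n_nodes, 4)
    counts <- setNames(sample(1:5, 4, replace = TRUE), counted)
    got <- resolve_hits(counts, tax)
    # oracle: score every node as sum of counts on its root path, leaves
    # are counted nodes that are ancestors of no other counted node
    score <- function(i) sum(counts[as.character(
      intersect(anc_set(tax, i), counted))])
    is_leaf <- vapply(counted, function(i)
      !any(vapply(setdiff(counted, i), function(j)
        i %in% anc_set(tax, j)[-1], TRUE)), TRUE)
    leaves <- counted[is_leaf]
    scores <- vapply(leaves, score, 0)
    best <- leaves[scores == max(scores)]
    want <- if (length(best) == 1) best else lca_all(tax, best)
    expect_equal(got, want)
    # scaling all counts cannot change the call
    expect_equal(resolve_hits(counts * 7L, tax), got)
  }
})

test_that("paired classification pools the two mates' counts", {
  set.seed(44)
  m1 <- substr(demo$g40, 3001, 3100)
  m2 <- kmerlca:::revcomp(substr(demo$g40, 3201, 3300))
  cls <- classify_fragment(demo$db, m1, m2, fragment_id = "p1")
  pooled <- collect_hits(demo$db, m1)$hit_counts
  for (nm in names(collect_hits(demo$db, m2)$hit_counts))
    pooled[nm] <- (if (nm %in% names(pooled)) pooled[[nm]] else 0L) +
      collect_hits(demo$db, m2)$hit_counts[[nm]]
  want <- resolve_hits(pooled, demo$db$taxonomy)
  expect_equal(cls$internal_taxon, want)
  expect_true(cls$classified)
  expect_true(-2L %in% cls$hit_runs$taxon)  # mate boundary marker
  expect_equal(cls$lengths, c(100, 100))
})

test_that("unclassifiable fragments report status U and taxon 0", {
  set.seed(45)
  cls <- classify_fragment(demo$db, rand_dna(100), rand_dna(100), "u1")
  expect_false(cls$classified)
  expect_equal(cls$external_taxon, 0L)
  # shorter than k: zero k-mers, unclassified
  tiny <- classify_fragment(demo$db, "ACGT", fragment_id = "tiny")
  expect_equal(tiny$total_kmers, 0L)
  expect_false(tiny$classified)
})

test_that("error-free reads never leave the source genome's ancestor path", {
  set.seed(46)
  tree <- demo_tree()
  for (rep in 1:30) {
    start <- sample(nchar(demo$g41) - 120, 1)
    read <- substr(demo$g41, start, start + 119)
    if (sample(2, 1) == 1) read <- kmerlca:::revcomp(read)
    cls <- classify_fragment(demo$db, read)
    if (cls$classified)
      expect_true(cls$external_taxon %in% ancestors_of(tree, 41L))
  }
})

test_that("per-fragment output follows the expected dialect", {
  set.seed(47)
  cls <- list(classify_fragment(demo$db, rand_dna(100), fragment_id = "r1"))
  path <- tempfile()
  write_output(cls, path)
  line <- readLines(path)
  expect_equal(line, "U\tr1\t0\t100\t0:66")
  # a classified pair prints C, the taxon, both lengths and a mate break
  cls2 <- list(classify_fragment(demo$db, substr(demo$g32, 1, 100),
                                 substr(demo$g32, 201, 300), "r2"))
  write_output(cls2, path)
  parts <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(parts[1], "C")
  expect_equal(parts[3], "32")
  expect_equal(parts[4], "100|100")
  expect_true(grepl("\\|:\\|", parts[5]))
})

test_that("the report conserves counts and rolls clades up", {
  set.seed(48)
  reads <- data.frame(
    id = paste0("r", 1:12),
    seq = c(vapply(1:5, function(i) substr(demo$g40, i * 400, i * 400 + 119), ""),
            vapply(1:5, function(i) substr(demo$g32, i * 400, i * 400 + 119), ""),
            rand_dna(120), rand_dna(120)),
    stringsAsFactors = FALSE)
  cls <- classify_reads(demo$db, reads)
  path <- tempfile()
  rep_df <- write_report(cls, demo$db$taxonomy, path)
  expect_true(file.exists(path))
  # direct counts (plus unclassified) add up to the fragment count
  expect_equal(sum(rep_df$direct_count), length(cls))
  # every taxon's clade count equals own plus children's clade counts
  tax <- demo$db$taxonomy
  for (i in seq_len(tax$n_nodes)) {
    row <- rep_df[rep_df$external_id == tax$internal_to_external[i], ]
    if (nrow(row) == 0) next
    kids <- which(tax$parent == i)
    kid_ext <- tax$internal_to_external[kids]
    kid_clade <- sum(rep_df$clade_count[rep_df$external_id %in% kid_ext])
    expect_equal(row$clade_count, row$direct_count + kid_clade)
  }
})
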