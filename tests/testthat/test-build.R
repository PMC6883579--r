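test_that("the capacity sketch is exact when E = F and close at defaults", {
  set.seed(31)
  sch <- minimizer_scheme()
  lib <- c(g = rand_dna(3e5))
  exact <- count_distinct_minimizers(lib, sch)
  expect_equal(estimate_capacity(lib, sch, E = 1024, F = 1024)$D, exact)
  est <- estimate_capacity(lib, sch)  # defaults E = 4, F = 1024
  expect_equal(est$E, 4)
  expect_equal(est$F, 1024)
  expect_lt(abs(est$D - exact) / exact, 0.15)
})

test_that("the capacity estimator is unbiased across libraries", {
  sch <- minimizer_scheme()
  ratio <- vapply(1:5, function(seed) {
    set.seed(100 + seed)
    lib <- c(g = rand_dna(6e5))
    estimate_capacity(lib, sch)$D / count_distinct_minimizers(lib, sch)
  }, 0)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("a single-taxon library stores only that taxon", {
  set.seed(32)
  tree <- demo_tree()
  db <- build_database(c(s1 = rand_dna(5000)), c(s1 = 40L), tree,
                       minimizer_scheme())
  cells <- cht_cells(db$table)
  vals <- cells[cells > 0] %% 2^db$metadata$value_bits
  internal <- db$taxonomy$external_to_internal[["40"]]
  expect_true(all(vals == internal))
  # pruned taxonomy covers exactly taxon 40 and its ancestors
  expect_setequal(db$taxonomy$internal_to_external, c(1, 10, 20, 30, 40))
})

test_that("identical genomes under sister taxa merge to their parent", {
  set.seed(33)
  g <- rand_dna(5000)
  tree <- demo_tree()
  db <- build_database(c(a = g, b = g), c(a = 40L, b = 41L), tree,
                       minimizer_scheme())
  cells <- cht_cells(db$table)
  vals <- cells[cells > 0] %% 2^db$metadata$value_bits
  parent_internal <- db$taxonomy$external_to_internal[["30"]]
  expect_true(all(vals == parent_internal))
})

test_that("built values match an exact dictionary-plus-LCA oracle", {
  set.seed(34)
  w <- make_world(genome_len = 8000, seed = 34)
  strains <- w$strains[1:5]
  lib <- setNames(w$genomes[as.character(strains)],
                  paste0("s", strains))
  sch <- minimizer_scheme(k = 25, l = 21, spaces = 3)
  db <- build_database(lib, setNames(strains, names(lib)), w$tree, sch)
  tax <- db$taxonomy
  oracle <- new.env()
  for (i in seq_along(lib)) {
    internal <- tax$external_to_internal[[as.character(strains[i])]]
    for (v in unique(minimizers_of(lib[[i]], sch)$value)) {
      prev <- oracle[[v]]
      oracle[[v]] <- if (is.null(prev)) internal else lca(tax, prev, internal)
    }
  }
  keys <- ls(oracle)
  got <- cht_find(db$table, keys)
  expect_true(all(got > 0))  # no false negatives
  ok <- vapply(seq_along(keys), function(i)
    got[i] %in% anc_set(tax, oracle[[keys[i]]]), TRUE)
  expect_true(all(ok))
})

test_that("lookups are invariant under library order", {
  # cell placement may differ (linear probing is first-come), but every
  # observable lookup must agree because the LCA merge is commutative
  set.seed(35)
  w <- make_world(genome_len = 6000, seed = 35)
  strains <- w$strains[1:4]
  lib <- setNames(w$genomes[as.character(strains)], paste0("s", strains))
  map <- setNames(strains, names(lib))
  sch <- minimizer_scheme()
  db1 <- build_database(lib, map, w$tree, sch)
  perm <- c(3, 1, 4, 2)
  db2 <- build_database(lib[perm], map[perm], w$tree, sch)
  keys <- unique(unlist(lapply(lib, function(g)
    minimizers_of(g, sch)$value)))
  expect_identical(cht_find(db1$table, keys), cht_find(db2$table, keys))
  expect_equal(cht_info(db1$table)$occupied, cht_info(db2$table)$occupied)
})

test_that("a table-size cap triggers calibrated hash subsampling", {
  set.seed(36)
  sch <- minimizer_scheme()
  lib <- c(g = rand_dna(2e5))
  full <- build_database(lib, c(g = 40L), demo_tree(), sch)
  n_full <- cht_info(full$table)$occupied
  cap <- ceiling(cht_info(full$table)$cell_count / 4)
  db <- build_database(lib, c(g = 40L), demo_tree(), sch, max_cells = cap)
  expect_lt(db$subsample$f, 1)
  info <- cht_info(db$table)
  expect_equal(info$cell_count, cap)
  expect_lt(info$load, 0.75)
  # retained fraction matches f within Monte-Carlo tolerance
  expect_lt(abs(info$occupied / n_full - db$subsample$f), 0.03)
  # every stored minimizer of the library passes the threshold
  vals <- unique(minimizers_of(lib[[1]], sch)$value)
  kept <- minimizer_retained(vals, db$subsample)
  expect_equal(sum(kept), info$occupied)
  expect_true(all(cht_find(db$table, vals[kept]) > 0))
})

test_that("sequences without a taxon mapping are skipped with a warning", {
  set.seed(37)
  lib <- c(a = rand_dna(3000), b = rand_dna(3000))
  expect_warning(
    db <- build_database(lib, c(a = 40L), demo_tree(), minimizer_scheme()),
    "without a taxon mapping")
  expect_equal(db$metadata$n_sequences, 1)
  expect_error(
    suppressWarnings(build_database(lib, c(z = 40L), demo_tree(),
                                    minimizer_scheme())),
    "no sequences")
})

test_that("databases round-trip through a directory", {
  set.seed(38)
  db <- build_database(c(s = rand_dna(4000)), c(s = 40L), demo_tree(),
                       minimizer_scheme())
  dir <- tempfile()
  save_database(db, dir)
  expect_true(all(file.exists(file.path(dir, c("hash.bin", "taxonomy.tsv",
                                               "manifest.json")))))
  db2 <- load_database(dir)
  expect_identical(cht_cells(db2$table), cht_cells(db$table))
  expect_equal(db2$scheme$k, db$scheme$k)
  expect_equal(db2$scheme$toggle, db$scheme$toggle)
  expect_equal(db2$subsample$v, db$subsample$v)
  expect_equal(db2$taxonomy$internal_to_external,
               db$taxonomy$internal_to_external)
})

test_that("the analytic size models reproduce their documented identities", {
  expect_equal(unname(k1_db_size(0)["kdb"]), 1072)
  expect_equal(unname(k1_db_size(1e6)["kdb"]), 12001072)
  expect_equal(unname(k1_db_size(0)["idx"]), 8589934608)
  expect_equal(unname(k2_db_size(0)), 32)
  expect_equal(unname(k2_db_size(7)), 72)  # 32 + floor(28 / 0.7)
  expect_equal(round(db_size_ratio(3.1), 2), 0.15)
})
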