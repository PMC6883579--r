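# A trivial single-node taxonomy for inserts that never need a real LCA,
# and a deeper one for merge semantics.
flat_tax <- function() {
  assign_internal_ids(taxonomy_tree(data.frame(
    external_id = 1, parent_external = 1, rank = "no rank", name = "root")))
}

test_that("a fresh table is empty and rejects bad geometry", {
  tab <- cht_create(8, 3)
  info <- cht_info(tab)
  expect_equal(info$cell_count, 8)
  expect_equal(info$occupied, 0)
  expect_equal(cht_find(tab, rand_hex64(5)), rep(0L, 5))
  expect_error(cht_create(0, 17))
  expect_error(cht_create(8, 0))
  expect_error(cht_create(8, 32))
})

test_that("inserts are idempotent and merge to the LCA", {
  tax <- assign_internal_ids(demo_tree())
  tab <- cht_create(64, 8)
  key <- rand_hex64(1)
  # internal IDs: pick two strains under the same species
  a <- tax$external_to_internal[["40"]]
  b <- tax$external_to_internal[["41"]]
  cht_set_lca(tab, key, a, tax)
  expect_equal(cht_find(tab, key), a)
  cht_set_lca(tab, key, a, tax)
  expect_equal(cht_find(tab, key), a)  # lca(x, x) = x
  cht_set_lca(tab, key, b, tax)
  expect_equal(cht_find(tab, key), lca(tax, a, b))
  expect_equal(cht_info(tab)$occupied, 1)
})

test_that("a full table raises an error instead of dropping keys", {
  tax <- flat_tax()
  tab <- cht_create(4, 16)
  set.seed(21)
  keys <- rand_hex64(40)
  expect_error(cht_set_lca(tab, keys, 1L, tax), "full")
})

test_that("an engineered compact-code twin is mistaken for its sibling", {
  # two different keys sharing a compact code on adjacent probe paths:
  # the table cannot tell them apart, the documented false-positive mode
  tax <- flat_tax()
  cells <- 16; value_bits <- 28  # 4 key bits force quick collisions
  set.seed(22)
  k1 <- rand_hex64(1)
  s1 <- cht_slot(k1, cells, value_bits)
  k2 <- NULL
  for (cand in rand_hex64(5000)) {
    s2 <- cht_slot(cand, cells, value_bits)
    if (cand != k1 && s2$code == s1$code && s2$index0 == s1$index0) {
      k2 <- cand; break
    }
  }
  expect_false(is.null(k2))
  tab <- cht_create(cells, value_bits)
  cht_set_lca(tab, k1, 1L, tax)
  expect_equal(cht_find(tab, k2), 1L)  # false positive by construction
})

test_that("values are never lost and only ever elevate vs an exact map", {
  tree <- demo_tree()
  tax <- assign_internal_ids(tree)
  set.seed(23)
  for (rep in 1:5) {
    tab <- cht_create(128, 5)  # few value bits -> tight compact codes
    keys <- rand_hex64(60)
    keys <- keys[!duplicated(keys)]
    inserts <- data.frame(
      key = sample(keys, 80, replace = TRUE),
      taxon = sample(tax$n_nodes, 80, replace = TRUE),
      stringsAsFactors = FALSE)
    oracle <- new.env()
    for (i in seq_len(nrow(inserts))) {
      cht_set_lca(tab, inserts$key[i], inserts$taxon[i], tax)
      prev <- oracle[[inserts$key[i]]]
      oracle[[inserts$key[i]]] <- if (is.null(prev)) inserts$taxon[i]
        else lca(tax, prev, inserts$taxon[i])
    }
    for (key in unique(inserts$key)) {
      got <- cht_find(tab, key)
      expect_gt(got, 0)  # no false negatives
      # ancestor-or-equal of the exact LCA, never unrelated or deeper
      expect_true(got %in% anc_set(tax, oracle[[key]]))
    }
  }
})

test_that("tables round-trip bit-exactly through disk", {
  tax <- flat_tax()
  tab <- cht_create(32, 17)
  set.seed(24)
  cht_set_lca(tab, rand_hex64(15), 1L, tax)
  path <- tempfile(fileext = ".bin")
  cht_save(tab, path)
  tab2 <- cht_load(path)
  expect_identical(cht_cells(tab2), cht_cells(tab))
  expect_equal(cht_info(tab2)$occupied, cht_info(tab)$occupied)
  expect_equal(cht_info(tab2)$value_bits, 17)
  # truncation is detected
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  writeBin(raw[1:(sz - 4)], path)
  expect_error(cht_load(path), "truncated")
  # bad magic is detected
  writeBin(c(charToRaw("BOGUS!!!"), raw[9:sz]), path)
  expect_error(cht_load(path), "magic")
})

test_that("a hand-assembled binary fixture loads cell-for-cell", {
  # header: magic, cell_count = 3, occupied = 1, value_bits = 16, pad;
  # cells: empty, (code 0x00ab, value 7), empty -- all little-endian
  path <- tempfile(fileext = ".bin")
  con <- file(path, "wb")
  writeBin(charToRaw("MINLCA01"), con)
  writeBin(c(3L, 0L), con, size = 4, endian = "little")   # cell_count
  writeBin(c(1L, 0L), con, size = 4, endian = "little")   # occupied
  writeBin(c(16L, 0L), con, size = 4, endian = "little")  # value_bits, pad
  cell <- bitwShiftL(0x00ab, 16) + 7L
  writeBin(c(0L, cell, 0L), con, size = 4, endian = "little")
  close(con)
  tab <- cht_load(path)
  info <- cht_info(tab)
  expect_equal(info$cell_count, 3)
  expect_equal(info$value_bits, 16)
  expect_equal(info$occupied, 1)
  expect_equal(cht_cells(tab), c(0, 0x00ab0007, 0))
})

test_that("absent-key error rates track load factor and key width", {
  set.seed(25)
  query <- rand_dna(2e5)
  reference <- rand_dna(25e4)
  sch <- minimizer_scheme()
  # default geometry: below the documented 1% bound
  base <- cht_error_rate(query, reference, sch, 0.7, 15)
  expect_lt(base$rate_percent, 1)
  expect_equal(base$load, 0.7, tolerance = 0.01)
  # more key bits -> fewer errors; higher load -> more errors
  wide <- cht_error_rate(query, reference, sch, 0.7, 18)
  narrow <- cht_error_rate(query, reference, sch, 0.7, 12)
  expect_lt(wide$false_hits, narrow$false_hits)
  lo <- cht_error_rate(query, reference, sch, 0.5, 12)
  hi <- cht_error_rate(query, reference, sch, 0.9, 12)
  expect_lt(lo$rate_percent, hi$rate_percent)
  # closed-form sanity: about (expected occupied probes) * 2^-key_bits;
  # at load 0.7 linear probing scans about 6.1 occupied cells per miss
  predicted <- 100 * 6.1 / 2^15
  expect_lt(abs(base$rate_percent - predicted), predicted)
})
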