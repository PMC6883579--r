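test_that("DNA windows pack 2 bits per base, most significant first", {
  expect_equal(encode_window("AAA", 1, 3)$code, as_hex64(0))
  expect_false(encode_window("AAA", 1, 3)$ambiguous)
  expect_true(encode_window("ACN", 1, 3)$ambiguous)
  expect_equal(encode_window("ACGT", 1, 4)$code, as_hex64(27))  # 0b00011011
  expect_equal(encode_window("acgt", 1, 4)$code, as_hex64(27))  # case-folded
})

test_that("canonicalization picks the smaller strand and is rc-invariant", {
  ttt <- encode_window("TTT", 1, 3)$code
  expect_equal(canonical_code(ttt, 3), as_hex64(0))  # AAA
  acg <- encode_window("ACG", 1, 3)$code
  expect_equal(canonical_code(acg, 3), acg)  # rc CGT is larger
  set.seed(1)
  for (rep in 1:200) {
    l <- sample(4:31, 1)
    x <- encode_window(rand_dna(l), 1, l)$code
    expect_equal(canonical_code(revcomp_code(x, l), l), canonical_code(x, l))
  }
})

test_that("the spaced-seed mask reproduces the documented bit pattern", {
  # l = 12, s = 3: base-position pattern 111111010101, 2 bits per base
  pattern <- "111111010101"
  bits <- strsplit(pattern, "")[[1]]
  expected <- sum(vapply(seq_along(bits), function(i) {
    if (bits[i] == "1") 3 * 4^(12 - i) else 0
  }, 0))
  expect_equal(spaced_seed_mask(12, 3), as_hex64(expected))
  # s = 0 masks nothing
  expect_equal(spaced_seed_mask(5, 0), as_hex64(4^5 - 1))
  # l = 31, s = 7: 24 unmasked base positions, rightmost base unmasked
  m <- spaced_seed_mask(31, 7)
  nib <- strtoi(strsplit(m, "")[[1]], 16L)
  set_bits <- sum(vapply(nib, function(x) sum(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0), 0))
  expect_equal(set_bits / 2, 24)
  expect_equal(bitwAnd(nib[16], 3L), 3L)
  expect_error(spaced_seed_mask(5, 3), "2s|mask")
})

test_that("candidate values are masked, toggled canonical codes", {
  plain <- minimizer_scheme(k = 8, l = 8, spaces = 0, toggle = "0")
  code <- canonical_code(encode_window(rand_dna(8), 1, 8)$code, 8)
  expect_equal(candidate_value(code, plain), code)
  # XOR with the toggle twice recovers the masked code
  sch <- minimizer_scheme(k = 8, l = 8, spaces = 2)
  v <- candidate_value(code, sch)
  untoggled <- kmerlca:::.candidate_value_cpp(v, "ffffffffffffffff",
                                              sch$toggle)
  expect_equal(untoggled, hex_and(code, sch$mask))
})

test_that("the XOR toggle permutes the candidate ordering", {
  set.seed(2)
  plain <- minimizer_scheme(k = 10, l = 10, spaces = 0, toggle = "0")
  shuf <- minimizer_scheme(k = 10, l = 10, spaces = 0)
  found <- FALSE
  for (rep in 1:200) {
    a <- canonical_code(encode_window(rand_dna(10), 1, 10)$code, 10)
    b <- canonical_code(encode_window(rand_dna(10), 1, 10)$code, 10)
    if (a == b) next
    plain_lt <- candidate_value(a, plain) < candidate_value(b, plain)
    shuf_lt <- candidate_value(a, shuf) < candidate_value(b, shuf)
    if (plain_lt != shuf_lt) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("with k = l each k-mer is its own minimizer", {
  sch <- minimizer_scheme(k = 5, l = 5, spaces = 0, toggle = "0")
  seq <- rand_dna(60)
  got <- minimizers_of(seq, sch)
  want <- vapply(seq_len(60 - 4), function(q) {
    canonical_code(encode_window(seq, q, 5)$code, 5)
  }, "")
  expect_equal(got$pos, seq_len(56))
  expect_equal(got$value, want)
})

test_that("deque minimizers equal the brute-force window minima", {
  set.seed(3)
  for (sch in list(minimizer_scheme(k = 35, l = 31, spaces = 7),
                   minimizer_scheme(k = 12, l = 8, spaces = 2),
                   minimizer_scheme(k = 9, l = 4, spaces = 0,
                                    toggle = "0"))) {
    seq <- rand_dna(2000)
    expect_equal(minimizers_of(seq, sch), brute_minimizers(seq, sch))
  }
})

test_that("ambiguous bases knock out exactly the overlapping k-mers", {
  set.seed(4)
  sch <- minimizer_scheme(k = 10, l = 6, spaces = 0)
  seq <- rand_dna(100)
  substr(seq, 40, 40) <- "N"
  got <- minimizers_of(seq, sch)
  expect_equal(got, brute_minimizers(seq, sch))
  expect_false(any(got$pos %in% 31:40))  # windows covering position 40
})

test_that("minimizers are local: a suffix does not change earlier windows", {
  set.seed(5)
  sch <- minimizer_scheme()
  x <- rand_dna(500)
  y <- rand_dna(300)
  mx <- minimizers_of(x, sch)
  mxy <- minimizers_of(paste0(x, y), sch)
  inside <- mxy[mxy$pos <= nchar(x) - sch$k + 1, ]
  rownames(inside) <- NULL
  expect_equal(inside, mx)
})

test_that("distinct-minimizer density sits near 2/(k - l + 2)", {
  set.seed(6)
  sch <- minimizer_scheme(k = 35, l = 31, spaces = 0)
  seq <- rand_dna(2e5)
  n_pos <- nchar(seq) - sch$k + 1
  distinct <- count_distinct_minimizers(c(s = seq), sch)
  density <- distinct / n_pos
  expect_gt(density, 0.8 * 2 / (sch$k - sch$l + 2))
  expect_lt(density, 1.2 * 2 / (sch$k - sch$l + 2))
})

test_that("emitted values have zero bits at masked positions", {
  set.seed(7)
  sch <- minimizer_scheme(k = 20, l = 12, spaces = 3)
  vals <- minimizers_of(rand_dna(500), sch)$value
  unmasked <- vapply(vals, function(v) {
    untoggled <- kmerlca:::.candidate_value_cpp(v, "ffffffffffffffff",
                                                sch$toggle)
    hex_and(untoggled, hex_not(sch$mask)) == as_hex64(0)
  }, TRUE)
  expect_true(all(unmasked))
})

test_that("fmix64 matches reference values and is injective", {
  expect_equal(fmix64("0000000000000000"), "0000000000000000")
  # frozen from an independent reference implementation of the
  # MurmurHash3 finalizer
  expect_equal(fmix64(as_hex64(1)), "b456bcfc34c2cb2c")
  expect_equal(fmix64(as_hex64(42)), "810879608e4259cc")
  expect_equal(fmix64("ffffffffffffffff"), "64b5720b4b825f21")
  set.seed(8)
  x <- unique(rand_hex64(1e5))
  expect_false(anyDuplicated(fmix64(x)) > 0)
})

test_that("the subsampling threshold retains the expected fraction", {
  expect_equal(subsample_threshold(1)$v, as_hex64(0))
  expect_equal(subsample_threshold(0.25)$v, "bfffffffffffffff")
  expect_error(subsample_threshold(0))
  expect_error(subsample_threshold(1.2))
  set.seed(9)
  cfg <- subsample_threshold(0.3)
  keep <- minimizer_retained(rand_hex64(1e5), cfg)
  expect_lt(abs(mean(keep) - 0.3), 0.01)
})
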