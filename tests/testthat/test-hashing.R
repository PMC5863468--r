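test_that("nucleotide encoding is the fixed 2-bit code, case-insensitive", {
  expect_identical(encode_symbol("A"), 0L)
  expect_identical(encode_symbol("C"), 1L)
  expect_identical(encode_symbol("G"), 2L)
  expect_identical(encode_symbol("T"), 3L)
  expect_identical(encode_symbol("t"), 3L)
  expect_identical(encode_symbol("N"), NA_integer_)
  expect_identical(encode_symbol("-"), NA_integer_)
})

test_that("per-position hashes reproduce the published worked example", {
  x <- "ACTGACTGGA"
  expect_identical(hash_at(x, 0, "10111011"), "2860")
  expect_identical(hash_bits(hash_at(x, 0, "10111011"), "10111011"),
                   "101100101100")
  expect_identical(hash_bits(hash_at(x, 1, "10111011"), "10111011"),
                   "101001001001")
  expect_identical(hash_bits(hash_at(x, 2, "10111011"), "10111011"),
                   "001011010011")
  expect_identical(hash_at("A", 0, "1"), "0")
  expect_error(hash_at(x, 3, "10111011"), "out of range")
  expect_error(hash_at("ACTNACTGGA", 0, "10111011"), "unencodable")
})

test_that("hashing a sequence emits the ordered hash vector", {
  h <- hash_sequence("ACTGACTGGA", "10111011", method = "naive")
  expect_identical(h$position, 0:2)
  expect_identical(h$hash, c("2860", "2633", "723"))
  # shorter than the span: nothing to emit
  expect_identical(nrow(hash_sequence("ACTGAC", "10111011")), 0L)
  expect_identical(nrow(hash_sequence("", "10111011")), 0L)
})

test_that("naive hashing agrees with the independent oracle", {
  set.seed(201)
  x <- random_dna(200)
  h <- hash_sequence(x, "10111011", method = "naive")
  o <- oracle_hash_all(x, "10111011")
  expect_identical(h$position, o$position)
  expect_identical(h$hash, format(o$hash, scientific = FALSE, trim = TRUE))
  for (i in sample(h$position, 10L)) {
    expect_identical(hash_at(x, i, "10111011"),
                     h$hash[match(i, h$position)])
  }
})

test_that("the incremental reuse step reconstructs the second worked hash", {
  # shift the hash at position 0 by 2*m(1) = 2 bits, keep the fields of
  # C_1 = {2,3,6} (bit offsets 2,3 / 4,5 / 8,9), insert the three missing
  # symbols at seed positions 0, 4, 7
  ct <- compatibility("10111011")
  expect_identical(ct$plans[[1L]]$bit_shift, 2L)
  expect_identical(ct$plans[[1L]]$missing, c(0L, 4L, 7L))
  kept_word <- bitwAnd(bitwShiftR(2860L, 2L), strtoi("001100111100", base = 2L))
  expect_identical(kept_word, 520L)
  inserted <- bitwOr(bitwOr(1L, bitwShiftL(1L, 6L)), bitwShiftL(2L, 10L))
  expect_identical(bitwOr(kept_word, inserted), 2633L)
  expect_identical(hash_sequence("ACTGACTGGA", "10111011")$hash[2L], "2633")
})

test_that("incremental hashing is bit-identical to the naive reference", {
  set.seed(202)
  for (rep in 1:50) {
    pat <- random_pattern(sample(2:16, 1L))
    x <- random_dna(sample(0:500, 1L), with_n = rep %% 2L == 0L)
    f <- hash_sequence(x, pat, method = "fsh")
    n <- hash_sequence(x, pat, method = "naive")
    expect_identical(f$position, n$position, info = pat)
    expect_identical(f$hash, n$hash, info = pat)
  }
})

test_that("hashes decode back to the Q-grams they were computed from", {
  set.seed(203)
  x <- random_dna(120)
  pat <- "110010101011"
  shape <- oracle_shape(pat)
  h <- hash_sequence(x, pat)
  chars <- strsplit(toupper(x), "")[[1L]]
  for (r in seq_len(nrow(h))) {
    qgram <- paste(chars[h$position[r] + shape + 1L], collapse = "")
    expect_identical(hash_decode(h$hash[r], pat), qgram)
  }
})

test_that("emitted positions cover every window inside every ACGT run", {
  set.seed(204)
  for (rep in 1:20) {
    pat <- random_pattern(sample(2:12, 1L))
    span <- nchar(pat)
    x <- random_dna(sample(20:300, 1L), with_n = TRUE)
    runs <- gregexpr("[ACGTacgt]+", x)[[1L]]
    expected <- if (length(runs) == 1L && runs[1L] == -1L) 0L else
      sum(pmax(0L, attr(runs, "match.length") - span + 1L))
    expect_identical(nrow(hash_sequence(x, pat)), expected)
  }
})

test_that("encoded-symbol counts match the reuse-plan arithmetic", {
  set.seed(205)
  x <- random_dna(3000)
  cn <- count_encodings(x, "10111011", "naive")
  expect_identical(cn$total_encodings, 6 * (3000 - 8 + 1))
  expect_identical(cn$per_symbol, 6L)
  cf <- count_encodings(x, "10111011", "fsh")
  expect_identical(cf$per_symbol, 3L)
  # totals reconcile exactly with what the engine actually inserted
  expect_identical(attr(hash_sequence(x, "10111011"), "encoded"),
                   cf$total_encodings)
  expect_identical(attr(hash_sequence(x, "10111011", method = "naive"),
                        "encoded"),
                   cn$total_encodings)
  # alternating seed and contiguous k-mer reach one insertion per position
  expect_identical(count_encodings(x, "10101010101", "fsh")$per_symbol, 1L)
  expect_identical(count_encodings(x, strrep("1", 22), "fsh")$per_symbol, 1L)
})

test_that("incremental hashing never encodes more symbols than naive", {
  set.seed(206)
  for (rep in 1:25) {
    pat <- random_pattern(sample(2:14, 1L))
    x <- random_dna(sample(0:400, 1L), with_n = rep %% 3L == 0L)
    cf <- count_encodings(x, pat, "fsh")
    cn <- count_encodings(x, pat, "naive")
    expect_lte(cf$total_encodings, cn$total_encodings)
    # steady-state insertions per position = weight - best full-window kept
    s <- spaced_seed(pat)
    if (cf$n_steady > 0) {
      expect_identical(cf$per_symbol,
                       s$weight - best_previous(compatibility(s),
                                                s$span - 1L)$kept)
    }
  }
})
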