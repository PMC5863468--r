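test_that("the simulator honors its count, length and error contracts", {
  reads <- simulate_reads(10000, 100, 80, error_rate = 0.01, rng_seed = 42)
  expect_identical(nrow(reads), 100L)
  expect_true(all(nchar(reads$sequence) == 80L))
  # error 0: every read is an exact substring of the regenerated genome
  clean <- simulate_reads(5000, 50, 60, error_rate = 0, rng_seed = 11)
  genome <- withr::with_seed(11L, paste(
    sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = ""))
  expect_true(all(vapply(seq_len(50), function(r)
    substr(genome, clean$start[r], clean$start[r] + 59L) ==
      clean$sequence[r], logical(1))))
  expect_identical(clean$n_errors, rep(0L, 50L))
  # variable read lengths stay in range
  ranged <- simulate_reads(5000, 40, c(60, 90), rng_seed = 3)
  expect_true(all(nchar(ranged$sequence) >= 60L &
                  nchar(ranged$sequence) <= 90L))
  expect_error(simulate_reads(50, 10, 80, rng_seed = 1))
})

test_that("substitution counts follow the binomial error model", {
  reads <- simulate_reads(50000, 10000, 80, error_rate = 0.01, rng_seed = 9)
  mean_err <- mean(reads$n_errors)
  # binomial(80, 0.01): mean 0.8, sd of the mean = sqrt(80*.01*.99/10000)
  expect_lt(abs(mean_err - 0.8), 3 * sqrt(80 * 0.01 * 0.99 / 10000))
})

test_that("simulation output is byte-identical for a fixed configuration", {
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  simulate_reads(2000, 30, 70, 0.01, rng_seed = 5, path = p1)
  simulate_reads(2000, 30, 70, 0.01, rng_seed = 5, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  different <- simulate_reads(2000, 30, 70, 0.01, rng_seed = 6)
  expect_false(identical(readLines(p1)[2L], different$sequence[1L]))
  # the global RNG stream is not consumed
  set.seed(1); a <- runif(1)
  set.seed(1); simulate_reads(1000, 5, 50, rng_seed = 2); b <- runif(1)
  expect_identical(a, b)
})

test_that("predicted speedups follow the encoded-symbol cost model", {
  expect_identical(predicted_speedup("10111011")$speedup, 2)
  expect_identical(predicted_speedup("10101010101")$speedup, 6)
  for (k in c(4L, 10L, 22L)) {
    expect_identical(predicted_speedup(strrep("1", k))$speedup, as.numeric(k))
  }
  # multi-seed reuse can only improve the aggregate kept count
  set.seed(401)
  for (rep in 1:10) {
    L <- sample(4:12, 1L)
    pats <- as.list(replicate(3L, random_pattern(L, max_weight = 8L)))
    ind <- predicted_speedup(pats, mode = "independent")
    mul <- predicted_speedup(pats, mode = "multi")
    expect_gte(sum(mul$kept), sum(ind$kept))
    expect_gte(mul$overall[1L], ind$overall[1L])
  }
})

test_that("the benchmark gates on equality and reconciles symbol counts", {
  reads <- simulate_reads(3000, 20, 90, 0.01, rng_seed = 21)
  rep <- fsh_benchmark(reads, list("10111011", "10101010101"))
  expect_s3_class(rep, "fsh_benchmark")
  expect_identical(rep$per_symbol_naive, c(6, 6))
  expect_identical(rep$per_symbol_fsh, c(3, 1))
  expect_identical(rep$predicted_speedup, c(2, 6))
  # counted insertions reconcile with count_encodings on the same reads
  for (y in 1:2) {
    pat <- rep$pattern[y]
    expect_identical(rep$encoded_fsh[y], sum(vapply(reads$sequence,
      function(s) count_encodings(s, pat, "fsh")$total_encodings, numeric(1))))
    expect_identical(rep$encoded_naive[y], sum(vapply(reads$sequence,
      function(s) count_encodings(s, pat, "naive")$total_encodings, numeric(1))))
  }
  g <- glance(rep)
  expect_identical(g$encoded_naive, sum(rep$encoded_naive))
  expect_gte(g$encoding_ratio, 1)
  pl <- autoplot(rep)
  expect_s3_class(pl, "ggplot")
})

test_that("longer reads dilute the transient toward the steady-state rate", {
  short <- simulate_reads(20000, 60, 80, 0.01, rng_seed = 31)
  long <- simulate_reads(20000, 60, 700, 0.01, rng_seed = 31)
  rate <- function(reads, pat) {
    enc <- attr(hash_reads(reads, pat), "encoded")
    pos <- sum(nchar(reads$sequence) - spaced_seed(pat)$span + 1L)
    enc / pos
  }
  r80 <- rate(short, "10111011")
  r700 <- rate(long, "10111011")
  expect_lt(r700, r80)
  expect_lt(abs(r700 - 3), abs(r80 - 3))
})
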