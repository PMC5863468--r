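# Independent brute-force oracle, kept deliberately separate from the
# package's code paths: plain double arithmetic (exact up to 2^53, i.e.
# seed weights <= 26 -- all test seeds are far below), no bit operations,
# no reuse of any package internals.

oracle_code <- c(A = 0, C = 1, G = 2, T = 3)

oracle_shape <- function(pattern) {
  which(strsplit(pattern, "")[[1]] == "1") - 1L
}

# Rabin-Karp spaced-seed hash at 0-based position i, as a double
oracle_hash_at <- function(x, i, pattern) {
  chars <- strsplit(toupper(x), "")[[1]]
  shape <- oracle_shape(pattern)
  sum(oracle_code[chars[i + shape + 1L]] * 4^(seq_along(shape) - 1L))
}

# all positions, splitting at ambiguous symbols exactly like the engine
oracle_hash_all <- function(x, pattern) {
  span <- nchar(pattern)
  up <- toupper(x)
  runs <- gregexpr("[ACGT]+", up)[[1L]]
  pos <- integer(0)
  if (!(length(runs) == 1L && runs[1L] == -1L)) {
    for (r in seq_along(runs)) {
      a <- runs[r] - 1L
      len <- attr(runs, "match.length")[r]
      if (len >= span) pos <- c(pos, a + seq_len(len - span + 1L) - 1L)
    }
  }
  data.frame(
    position = pos,
    hash = vapply(pos, function(i) oracle_hash_at(up, i, pattern), numeric(1))
  )
}

# MSB-first 2W-bit string of a double-valued hash
oracle_bits <- function(v, weight) {
  nb <- 2L * weight
  bits <- integer(nb)
  for (t in seq_len(nb)) {
    bits[t] <- v %% 2
    v <- v %/% 2
  }
  paste(rev(bits), collapse = "")
}

# C_j straight from the quantified definition, one candidate k at a time
oracle_Cj <- function(pattern, j) {
  shape <- oracle_shape(pattern)
  m <- vapply(seq_len(nchar(pattern)) - 1L,
              function(k) sum(shape < k), integer(1))
  keep <- integer(0)
  for (k in shape) {
    if ((k - j) %in% shape && m[k - j + 1L] == m[k + 1L] - m[j + 1L]) {
      keep <- c(keep, k - j)
    }
  }
  keep
}

# cross-seed variant: positions of seed y reusable from seed z's hash j back
oracle_Cyz <- function(pattern_y, pattern_z, j) {
  sy <- oracle_shape(pattern_y)
  sz <- oracle_shape(pattern_z)
  my <- vapply(seq_len(nchar(pattern_y)) - 1L,
               function(k) sum(sy < k), integer(1))
  mz <- vapply(seq_len(nchar(pattern_z)) - 1L,
               function(k) sum(sz < k), integer(1))
  keep <- integer(0)
  for (k in sz) {
    if ((k - j) %in% sy && my[k - j + 1L] == mz[k + 1L] - mz[j + 1L]) {
      keep <- c(keep, k - j)
    }
  }
  keep
}

# random valid seed: 1...1 with `weight` ones over `span` positions
random_pattern <- function(span, max_weight = 12L) {
  if (span == 1L) return("1")
  w <- sample(2:min(span, max_weight), 1L)
  ones <- c(0L, span - 1L,
            if (w > 2L) sample(seq_len(span - 2L), w - 2L))
  chars <- rep("0", span)
  chars[ones + 1L] <- "1"
  paste(chars, collapse = "")
}

# random sequence, optionally with embedded N runs and lowercase
random_dna <- function(len, with_n = FALSE) {
  if (len == 0L) return("")
  alpha <- c("A", "C", "G", "T", "a", "c", "g", "t")
  chars <- sample(alpha, len, replace = TRUE)
  if (with_n && len > 3L) {
    nrun <- sample(seq_len(max(len %/% 10L, 1L)), 1L)
    at <- sample(len - nrun + 1L, 1L)
    chars[at:(at + nrun - 1L)] <- "N"
  }
  paste(chars, collapse = "")
}
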