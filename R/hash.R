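#' Encode a nucleotide symbol
#'
#' The fixed 2-bit code underlying the Rabin-Karp hash: `A = 0 (00)`,
#' `C = 1 (01)`, `G = 2 (10)`, `T = 3 (11)`, case-insensitive. Any other
#' symbol (including `N` and IUPAC ambiguity codes) yields `NA`: the hashing
#' functions never crash on ambiguous bases, they split the sequence into
#' encodable segments instead.
#'
#' @param c A single character.
#' @return Integer code in `0:3`, or `NA_integer_` for an unencodable symbol.
#' @examples
#' encode_symbol("A")  # 0
#' encode_symbol("t")  # 3
#' encode_symbol("N")  # NA
#' @export
encode_symbol <- function(c) {
  if (!is.character(c) || length(c) != 1L) {
    stop("encode_symbol() expects a single character", call. = FALSE)
  }
  v <- encode_symbol_cpp(c)
  if (v < 0L) NA_integer_ else v
}

#' Spaced-seed hash at one position
#'
#' The Rabin-Karp hash of the Q-gram at position `i` (0-based):
#' the 2-bit encodings of the matched symbols, OR-ed together with the r-th
#' matched symbol (rank r in the shape) occupying bit offsets `2r, 2r+1` —
#' the first matched symbol sits in the least-significant bits. No modular
#' reduction is applied; the hash is an exact `2W`-bit word.
#'
#' @param x A nucleotide string.
#' @param i 0-based position, `0 <= i <= nchar(x) - span`.
#' @param seed A [spaced_seed] or pattern string.
#' @return The hash as a decimal string (exact for all weights up to 32).
#' @examples
#' hash_at("ACTGACTGGA", 0, "10111011")  # "2860" = 101100101100
#' @export
hash_at <- function(x, i, seed) {
  seed <- spaced_seed(seed)
  hash_naive_at_cpp(x, as.integer(i), seed$shape, seed$span)
}

#' Hash every position of a sequence under one spaced seed
#'
#' Computes the ordered hash values `h(x[i+Q])` for all valid positions `i`
#' of `x`. The sequence is first split into maximal runs of unambiguous
#' `A/C/G/T` symbols; each run is hashed independently, so every emitted
#' hash covers only encodable bases and windows overlapping an ambiguous
#' base are not emitted.
#'
#' Two methods are available and produce bit-identical output:
#' \describe{
#'   \item{`"fsh"`}{The incremental engine. At position `i` it selects the
#'     previous hash (up to `span - 1` back, kept in a ring buffer) whose
#'     compatibility set is largest, shifts it, masks the surviving 2-bit
#'     fields, and re-encodes only the missing symbols. Position 0 of each
#'     run, and positions in the transient where fewer previous hashes
#'     exist, reuse whatever window is available.}
#'   \item{`"naive"`}{The reference: every position is hashed from scratch by
#'     encoding all `W` matched symbols.}
#' }
#'
#' @param x A nucleotide string (case-insensitive; may contain `N` runs).
#' @param seed A [spaced_seed] or pattern string.
#' @param method `"fsh"` (default) or `"naive"`.
#' @param table Optionally a precomputed [compatibility()] table for `seed`
#'   (recomputed otherwise).
#' @param bits If `TRUE`, add a `bits` column with the zero-padded MSB-first
#'   `2W`-bit string of each hash.
#' @return A tibble with columns `position` (0-based), `hash` (decimal
#'   string) and optionally `bits`. The attribute `"encoded"` carries the
#'   total number of symbols read and encoded.
#' @examples
#' hash_sequence("ACTGACTGGA", "10111011", bits = TRUE)
#' @export
hash_sequence <- function(x, seed, method = c("fsh", "naive"), table = NULL,
                          bits = FALSE) {
  method <- match.arg(method)
  seed <- spaced_seed(seed)
  stopifnot(is.character(x), length(x) == 1L)
  if (method == "naive") {
    res <- hash_naive_cpp(x, seed$shape, seed$span)
  } else {
    if (is.null(table)) table <- compatibility(seed)
    stopifnot(inherits(table, "fsh_compat"),
              identical(table$seed$pattern, seed$pattern))
    res <- hash_fsh_cpp(x, seed$shape, seed$m, seed$span,
                        table$best$j, plan_keep(table), plan_missing(table))
  }
  out <- tibble::tibble(position = res$position, hash = res$hash)
  if (bits) out$bits <- hash_bits(out$hash, seed)
  attr(out, "encoded") <- res$encoded
  out
}

# per-window kept / missing position sets, in window order 1..span-1
plan_keep <- function(table) {
  lapply(table$best$j, function(j) as.integer(table$plans[[j]]$keep))
}
plan_missing <- function(table) {
  lapply(table$best$j, function(j) as.integer(table$plans[[j]]$missing))
}

#' Hash a sequence under several seeds simultaneously
#'
#' All seeds must share one span `L`. At each position the seeds are
#' processed in input order and each seed reuses the best previous hash of
#' *any* seed in the set (strictly earlier positions, lookback `j >= 1`),
#' per the cross-compatibility plan. Output is bit-identical, seed by seed,
#' to hashing each seed independently.
#'
#' @param x A nucleotide string.
#' @param seeds List of [spaced_seed]s or pattern strings with equal spans.
#' @param table Optionally a precomputed [cross_compatibility()] table.
#' @param bits If `TRUE`, add MSB-first bit strings.
#' @return A tibble with columns `seed_index` (0-based, input order),
#'   `position`, `hash`, and optionally `bits`; attribute `"encoded"` is the
#'   per-seed vector of encoded-symbol counts.
#' @export
hash_sequence_multi <- function(x, seeds, table = NULL, bits = FALSE) {
  seeds <- lapply(seeds, spaced_seed)
  if (is.null(table)) table <- cross_compatibility(seeds)
  stopifnot(inherits(table, "fsh_multi_compat"),
            identical(vapply(table$seeds, `[[`, "", "pattern"),
                      vapply(seeds, `[[`, "", "pattern")))
  L <- table$span
  ns <- length(seeds)
  nw <- max(L - 1L, 0L)
  pz <- matrix(1L, ns, nw); pj <- matrix(1L, ns, nw)
  keep <- vector("list", ns); missing <- vector("list", ns)
  for (y in seq_len(ns)) {
    pl <- table$plan[[y]]
    if (nw > 0L) { pz[y, ] <- pl$z; pj[y, ] <- pl$j }
    keep[[y]] <- lapply(seq_len(nw), function(w)
      as.integer(table$sets[[y]][[pl$z[w]]][[pl$j[w]]]))
    missing[[y]] <- lapply(seq_len(nw), function(w)
      setdiff(seeds[[y]]$shape, keep[[y]][[w]]))
  }
  res <- hash_multi_cpp(x, lapply(seeds, `[[`, "shape"),
                        lapply(seeds, `[[`, "m"), L, pz, pj, keep, missing)
  out <- dplyr::bind_rows(lapply(seq_len(ns), function(y) {
    tb <- tibble::tibble(seed_index = y - 1L,
                         position = res[[y]]$position,
                         hash = res[[y]]$hash)
    if (bits) tb$bits <- hash_bits(tb$hash, seeds[[y]])
    tb
  }))
  out <- dplyr::arrange(out, .data$seed_index, .data$position)
  attr(out, "encoded") <- vapply(res, `[[`, numeric(1), "encoded")
  out
}

#' Render hashes as MSB-first bit strings
#'
#' @param hash Character vector of decimal hash values.
#' @param seed The seed they were computed under (fixes the width `2W`).
#' @return Character vector of zero-padded `2W`-bit strings, most significant
#'   bit first.
#' @examples
#' hash_bits("2860", "10111011")  # "101100101100"
#' @export
hash_bits <- function(hash, seed) {
  seed <- spaced_seed(seed)
  dec_to_bits_cpp(as.character(hash), seed$weight)
}

#' Decode a hash back into its Q-gram
#'
#' Slices the `2W`-bit hash word into 2-bit fields (least-significant field
#' first) and maps each back to its nucleotide. Inverse of the hash on the
#' matched symbols.
#'
#' @param hash A decimal hash string (or vector).
#' @param seed The seed it was computed under.
#' @return Character vector of `W`-long nucleotide strings.
#' @export
hash_decode <- function(hash, seed) {
  seed <- spaced_seed(seed)
  bits <- dec_to_bits_cpp(as.character(hash), seed$weight)
  vapply(bits, function(b) {
    fields <- substring(b, seq(nchar(b) - 1L, 1L, by = -2L),
                        seq(nchar(b), 2L, by = -2L))
    paste(c("A", "C", "G", "T")[strtoi(fields, base = 2L) + 1L],
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count encoded symbols for a hashing run
#'
#' The portable cost proxy for spaced-seed hashing: how many symbols are
#' read and encoded. The naive method encodes all `W` matched symbols at
#' every position (`W * (n - span + 1)` per run); the incremental method
#' encodes only the symbols its reuse plans cannot carry over. The
#' steady-state rate discards the transient (the first `span - 1` positions
#' of each run, where fewer previous hashes are available).
#'
#' @param x A nucleotide string.
#' @param seed A [spaced_seed] or pattern string.
#' @param mode `"naive"` or `"fsh"`.
#' @return A list with `total_encodings`, `per_symbol` (steady-state
#'   insertions per position; `NA` if no position is past the transient),
#'   `n_positions` and `n_steady`.
#' @examples
#' x <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
#' count_encodings(x, "10111011", "naive")$per_symbol  # 6
#' count_encodings(x, "10111011", "fsh")$per_symbol    # 3
#' @export
count_encodings <- function(x, seed, mode = c("fsh", "naive")) {
  mode <- match.arg(mode)
  seed <- spaced_seed(seed)
  ct <- compatibility(seed)
  seg_len <- nchar(acgt_segments(x))
  n_pos <- pmax(0L, seg_len - seed$span + 1L)
  total_pos <- sum(n_pos)
  # steady state: positions i >= span-1 within their run
  n_steady <- sum(pmax(0L, n_pos - (seed$span - 1L)))
  if (mode == "naive") {
    total <- as.numeric(seed$weight) * total_pos
    per_symbol <- if (total_pos > 0L) seed$weight else NA_real_
  } else {
    per_pos_insert <- function(np) {
      if (np == 0L) return(0)
      if (seed$span == 1L || np == 1L) return(seed$weight * np)
      w <- pmin(seq_len(np - 1L), seed$span - 1L)
      seed$weight + sum(seed$weight - ct$best$kept[w])
    }
    total <- sum(vapply(n_pos, per_pos_insert, numeric(1)))
    kept_full <- if (seed$span > 1L) ct$best$kept[seed$span - 1L] else 0L
    per_symbol <- if (n_steady > 0L) seed$weight - kept_full else NA_real_
  }
  list(total_encodings = total, per_symbol = per_symbol,
       n_positions = total_pos, n_steady = n_steady)
}

# maximal ACGT runs of a sequence (character vector of runs)
acgt_segments <- function(x) {
  regmatches(x, gregexpr("[ACGTacgt]+", x))[[1L]]
}
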