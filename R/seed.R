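#' Parse a spaced seed
#'
#' A spaced seed is a binary pattern over `{1, 0}` in which `1` marks a match
#' position and `0` a don't-care position; it generalizes the contiguous
#' k-mer (a seed of all `1`s). The parsed object carries the combinatorial
#' structure the hashing engine needs: the *shape* `Q` (0-based offsets of
#' the `1`s), the *weight* `W = |Q|`, the *span* `s(Q) = max(Q) + 1`, and the
#' shift-count vector `m`, where `m[k]` is the number of match positions
#' strictly to the left of seed position `k`. `m` fixes the bit offset
#' (`2 * m[k]`) at which the symbol matched at seed position `k` lands in the
#' 2-bit-per-symbol Rabin-Karp hash word.
#'
#' Patterns must start and end with `1` (otherwise the span would silently
#' disagree with the pattern length) and may have at most 32 match positions,
#' so that every hash fits one 64-bit word.
#'
#' @param pattern A string over `{"0","1"}`, e.g. `"10111011"`.
#' @return An object of class `spaced_seed`: a list with elements `pattern`,
#'   `shape` (0-based integer vector), `weight`, `span` and `m` (integer
#'   vector of length `span`).
#' @examples
#' s <- spaced_seed("10111011")
#' s$weight   # 6
#' s$span     # 8
#' s$m        # 0 1 1 2 3 4 4 5
#' @export
spaced_seed <- function(pattern) {
  if (inherits(pattern, "spaced_seed")) return(pattern)
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) == 0L) {
    stop("seed pattern must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c("0", "1"))) {
    stop(sprintf("seed pattern '%s' contains characters outside {0,1}", pattern),
         call. = FALSE)
  }
  if (chars[1L] != "1" || chars[length(chars)] != "1") {
    stop(sprintf("seed pattern '%s' must begin and end with '1'", pattern),
         call. = FALSE)
  }
  shape <- which(chars == "1") - 1L
  if (length(shape) > 32L) {
    stop(sprintf("seed pattern '%s' has weight %d; at most 32 match positions are supported",
                 pattern, length(shape)), call. = FALSE)
  }
  span <- length(chars)
  m <- cumsum(c(0L, as.integer(chars[-span] == "1")))
  structure(
    list(pattern = pattern, shape = shape, weight = length(shape),
         span = span, m = m),
    class = "spaced_seed"
  )
}

#' @export
print.spaced_seed <- function(x, ...) {
  cat(sprintf("<spaced_seed> %s  (weight %d, span %d)\n",
              x$pattern, x$weight, x$span))
  invisible(x)
}

#' @export
format.spaced_seed <- function(x, ...) x$pattern

#' @export
as.character.spaced_seed <- function(x, ...) x$pattern

#' Shift-count vector of a spaced seed
#'
#' For each seed position `k` in `0..span-1`, the number of match positions
#' strictly to the left of `k`. Equals the rank of `k` within the shape when
#' `k` is itself a match position.
#'
#' @param seed A [spaced_seed] or pattern string.
#' @return Integer vector of length `span`.
#' @examples
#' seed_m_vector("10111011")  # 0 1 1 2 3 4 4 5
#' @export
seed_m_vector <- function(seed) {
  spaced_seed(seed)$m
}

#' Compatibility sets of a spaced seed
#'
#' When the hash at position `i` of a sequence is computed, the hash already
#' computed at position `i - j` can contribute the symbols at seed positions
#' `C_j = {k - j in Q : k in Q and m(k-j) = m(k) - m(j)}`: these are exactly
#' the positions whose 2-bit fields survive a uniform right shift of the
#' previous hash word by `2*m(j)` bits at their correct target offsets. The
#' remaining `W - |C_j|` symbols must be read from the sequence and inserted.
#'
#' The returned table precomputes, for every lookback `j = 1..span-1`, the
#' set `C_j` and the derived reuse plan (bit shift, kept positions, missing
#' positions), plus the best-previous-hash choice for every window size.
#' `|C_j|` is related to, but can be strictly smaller than, the overlap count
#' `|Q intersect (Q - j)|`.
#'
#' @param seed A [spaced_seed] or pattern string.
#' @return An object of class `fsh_compat`: list with `seed`, `sets` (list of
#'   0-based integer vectors `C_1..C_{span-1}`), `plans` (per `j`: `bit_shift`,
#'   `keep`, `missing`), and `best` (tibble with one row per window size:
#'   `window`, `j`, `kept`).
#' @examples
#' ct <- compatibility("10111011")
#' ct$sets[[1]]               # 2 3 6
#' best_previous(ct, 7)       # j = 1, kept = 3
#' @export
compatibility <- function(seed) {
  seed <- spaced_seed(seed)
  span <- seed$span
  shape <- seed$shape
  m <- seed$m
  in_shape <- logical(span)
  in_shape[shape + 1L] <- TRUE
  sets <- vector("list", max(span - 1L, 0L))
  for (j in seq_len(span - 1L)) {
    k <- shape[shape >= j]
    ok <- in_shape[k - j + 1L] & (m[k - j + 1L] == m[k + 1L] - m[j + 1L])
    cj <- (k - j)[ok]
    stopifnot(length(cj) < seed$weight)
    sets[[j]] <- cj
  }
  plans <- lapply(seq_len(span - 1L), function(j) {
    list(bit_shift = 2L * m[j + 1L],
         keep = sets[[j]],
         missing = setdiff(shape, sets[[j]]))
  })
  sizes <- vapply(sets, length, integer(1))
  best <- tibble::tibble(
    window = seq_len(max(span - 1L, 0L)),
    j = integer(length(window)),
    kept = integer(length(window))
  )
  if (span > 1L) {
    # running argmax; ties go to the smallest j so the lookback stays short
    bj <- 1L
    for (w in seq_len(span - 1L)) {
      if (sizes[w] > sizes[bj]) bj <- w
      best$j[w] <- bj
      best$kept[w] <- sizes[bj]
    }
  }
  structure(list(seed = seed, sets = sets, plans = plans, best = best),
            class = "fsh_compat")
}

#' @export
print.fsh_compat <- function(x, ...) {
  cat(sprintf("<fsh_compat> seed %s (weight %d, span %d)\n",
              x$seed$pattern, x$seed$weight, x$seed$span))
  for (j in seq_along(x$sets)) {
    cat(sprintf("  C_%d = {%s}  |C_%d| = %d\n", j,
                paste(x$sets[[j]], collapse = ","), j, length(x$sets[[j]])))
  }
  if (nrow(x$best)) {
    full <- x$best[nrow(x$best), ]
    cat(sprintf("  best full-window reuse: j = %d, kept = %d of %d\n",
                full$j, full$kept, x$seed$weight))
  }
  invisible(x)
}

#' @describeIn compatibility One row per lookback `j`: the set `C_j`
#'   (list-column of 0-based positions), its size, and the uniform bit shift
#'   of the reuse plan.
#' @param x An `fsh_compat` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fsh_compat <- function(x, ...) {
  tibble::tibble(
    j = seq_along(x$sets),
    positions = x$sets,
    kept = vapply(x$sets, length, integer(1)),
    bit_shift = vapply(x$plans, function(p) p$bit_shift, integer(1))
  )
}

#' Best previous hash for a lookback window
#'
#' Among the previous `window` positions, the lookback `j` whose
#' compatibility set `C_j` is largest (ties broken towards the smallest `j`):
#' reusing the hash at `i - j` minimizes the number of symbols that must be
#' re-read and encoded at position `i`.
#'
#' @param table An [compatibility()] table.
#' @param window Integer in `1..span-1`.
#' @return A list with `j` (the chosen lookback) and `kept` (`|C_j|`).
#' @export
best_previous <- function(table, window) {
  stopifnot(inherits(table, "fsh_compat"))
  span <- table$seed$span
  if (!is.numeric(window) || length(window) != 1L || window < 1L ||
      window > span - 1L) {
    stop(sprintf("window must lie in 1..%d for seed %s", span - 1L,
                 table$seed$pattern), call. = FALSE)
  }
  row <- table$best[as.integer(window), ]
  list(j = row$j, kept = row$kept)
}

#' Number of symbol overlaps between a seed and its own shift
#'
#' `|Q intersect (Q - j)|`, the count of match positions that remain match
#' positions after shifting the seed by `j`. An upper bound companion to
#' `|C_j|`; the two can differ because surviving positions must also keep
#' their rank alignment to be reusable.
#'
#' @param seed A [spaced_seed] or pattern string.
#' @param j Positive shift.
#' @return Integer overlap count.
#' @export
seed_overlap <- function(seed, j) {
  seed <- spaced_seed(seed)
  length(intersect(seed$shape, seed$shape - as.integer(j)))
}
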