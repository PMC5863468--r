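#' Predicted steady-state speedup of incremental hashing
#'
#' Under a cost model in which shifting a previous hash and inserting a
#' symbol cost the same, the steady-state cost of hashing one position is
#' proportional to the number of symbols encoded there. The naive method
#' encodes `W` symbols per position; the incremental engine encodes
#' `W - kept`, where `kept` is the size of the best compatibility set over
#' the full lookback window. The predicted speedup is the ratio of the two.
#'
#' In `"independent"` mode each seed is predicted on its own,
#' `W / (W - kept)`. In `"multi"` mode the seeds are hashed simultaneously
#' and each may reuse any seed's previous hash; the aggregate prediction is
#' `sum(W_y) / sum(W_y - kept_y)` with `kept_y` from the cross-seed plan.
#'
#' @param seeds A seed or list of seeds ([spaced_seed] or pattern strings).
#' @param mode `"independent"` (default) or `"multi"` (requires equal
#'   spans).
#' @return For `"independent"`, a tibble with one row per seed (`pattern`,
#'   `weight`, `kept`, `speedup`); for `"multi"`, the same plus one
#'   aggregate `speedup` attribute, returned as a tibble with an `overall`
#'   column repeated.
#' @examples
#' predicted_speedup("10111011")$speedup     # 2
#' predicted_speedup("10101010101")$speedup  # 6
#' @export
predicted_speedup <- function(seeds, mode = c("independent", "multi")) {
  mode <- match.arg(mode)
  if (inherits(seeds, "spaced_seed")) seeds <- list(seeds)
  if (is.character(seeds)) seeds <- as.list(seeds)
  seeds <- lapply(seeds, spaced_seed)
  if (mode == "independent") {
    kept <- vapply(seeds, function(s) {
      if (s$span == 1L) return(0L)
      best_previous(compatibility(s), s$span - 1L)$kept
    }, integer(1))
  } else {
    table <- cross_compatibility(seeds)
    L <- table$span
    kept <- vapply(seq_along(seeds), function(y) {
      if (L == 1L) return(0L)
      best_seed_and_shift(table, y, L - 1L)$kept
    }, integer(1))
  }
  weight <- vapply(seeds, `[[`, integer(1), "weight")
  out <- tibble::tibble(
    pattern = vapply(seeds, `[[`, character(1), "pattern"),
    weight = weight, kept = kept,
    speedup = weight / (weight - kept)
  )
  out$overall <- sum(weight) / sum(weight - kept)
  out
}

#' Benchmark incremental vs naive hashing on a read set
#'
#' Hashes every read with both methods, verifies that the incremental
#' output is bit-identical to the naive reference (an error otherwise),
#' and reports the portable cost proxy — encoded-symbol counts — together
#' with the theoretical speedup prediction and informational wall-clock
#' times. Wall-clock numbers depend on hardware and are never a correctness
#' surface; the symbol counts are.
#'
#' @param reads A data frame with columns `id` and `sequence` (from
#'   [read_sequences()] or [simulate_reads()]), or a file path.
#' @param seeds A seed, list of seeds, or seed file path.
#' @param multi Hash seeds simultaneously (equal spans required).
#' @return An `fsh_benchmark` tibble: one row per seed with columns
#'   `pattern`, `weight`, `n_hashes`, `encoded_naive`, `encoded_fsh`,
#'   `per_symbol_naive`, `per_symbol_fsh` (steady-state rates),
#'   `predicted_speedup`, and informational `seconds_naive`/`seconds_fsh`.
#' @export
fsh_benchmark <- function(reads, seeds, multi = FALSE) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_sequences(reads)
  }
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds)) {
    seeds <- read_seed_file(seeds)
  }
  if (inherits(seeds, "spaced_seed")) seeds <- list(seeds)
  if (is.character(seeds)) seeds <- as.list(seeds)
  seeds <- lapply(seeds, spaced_seed)
  t_naive <- system.time(
    h_naive <- hash_reads(reads, seeds, method = "naive")
  )[["elapsed"]]
  t_fsh <- system.time(
    h_fsh <- if (multi) hash_reads(reads, seeds, multi = TRUE)
             else hash_reads(reads, seeds, method = "fsh")
  )[["elapsed"]]
  strip <- function(h) {
    h <- h[c("read_id", "seed_index", "position", "hash")]
    attr(h, "encoded") <- NULL
    h
  }
  if (!identical(strip(h_naive), strip(h_fsh))) {
    stop("incremental hashing disagrees with the naive reference", call. = FALSE)
  }
  pred <- predicted_speedup(seeds, mode = if (multi) "multi" else "independent")
  enc_naive <- attr(h_naive, "encoded")
  enc_fsh <- attr(h_fsh, "encoded")
  counts <- dplyr::count(h_fsh, .data$seed_index, name = "n_hashes")
  per_sym <- per_symbol_rates(reads, seeds, multi = multi)
  out <- tibble::tibble(
    pattern = pred$pattern,
    weight = pred$weight,
    n_hashes = counts$n_hashes[match(seq_along(seeds) - 1L, counts$seed_index)],
    encoded_naive = enc_naive,
    encoded_fsh = enc_fsh,
    per_symbol_naive = per_sym$naive,
    per_symbol_fsh = per_sym$fsh,
    predicted_speedup = pred$speedup,
    seconds_naive = t_naive,
    seconds_fsh = t_fsh
  )
  class(out) <- c("fsh_benchmark", class(out))
  out
}

# steady-state encoded-symbol rates over a read set (counting, not timing):
# total insertions at past-transient positions / number of such positions
per_symbol_rates <- function(reads, seeds, multi = FALSE) {
  span <- vapply(seeds, `[[`, integer(1), "span")
  if (multi) {
    tb <- cross_compatibility(seeds)
    kept_full <- vapply(seq_along(seeds), function(y) {
      if (tb$span == 1L) 0L else best_seed_and_shift(tb, y, tb$span - 1L)$kept
    }, integer(1))
  } else {
    kept_full <- vapply(seeds, function(s) {
      if (s$span == 1L) 0L
      else best_previous(compatibility(s), s$span - 1L)$kept
    }, integer(1))
  }
  weight <- vapply(seeds, `[[`, integer(1), "weight")
  n_steady <- vapply(seq_along(seeds), function(y) {
    sum(vapply(reads$sequence, function(s) {
      np <- pmax(0L, nchar(acgt_segments(s)) - span[y] + 1L)
      sum(pmax(0L, np - (span[y] - 1L)))
    }, numeric(1)))
  }, numeric(1))
  list(naive = ifelse(n_steady > 0, as.numeric(weight), NA_real_),
       fsh = ifelse(n_steady > 0, as.numeric(weight - kept_full), NA_real_))
}

#' @describeIn fsh_benchmark One-row summary: total encoded symbols for
#'   both methods, their ratio, and the aggregate predicted speedup.
#' @param x An `fsh_benchmark` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fsh_benchmark <- function(x, ...) {
  tibble::tibble(
    n_seeds = nrow(x),
    encoded_naive = sum(x$encoded_naive),
    encoded_fsh = sum(x$encoded_fsh),
    encoding_ratio = sum(x$encoded_naive) / sum(x$encoded_fsh),
    predicted_speedup = sum(x$weight) / sum(x$weight / x$predicted_speedup)
  )
}

#' Plot a benchmark report
#'
#' Bar chart of per-seed encoded-symbol counts, naive vs incremental — the
#' hardware-independent analogue of a wall-clock speedup plot.
#'
#' @param object An `fsh_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fsh_benchmark <- function(object, ...) {
  long <- tibble::tibble(
    pattern = rep(object$pattern, 2L),
    method = rep(c("naive", "fsh"), each = nrow(object)),
    encoded = c(object$encoded_naive, object$encoded_fsh)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pattern, y = .data$encoded,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "symbols encoded", fill = NULL,
                  title = "Encoded-symbol cost: naive vs incremental hashing")
}
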