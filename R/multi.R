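#' Cross-compatibility table for a set of equal-span seeds
#'
#' When several spaced seeds of one common span `L` are hashed over the same
#' sequence, the hash of seed `y` at position `i` may reuse the hash of *any*
#' seed `z` computed at position `i - j`. The positions of seed `y` that
#' survive such a reuse are
#' `C^yz_j = {k - j in Q_y : k in Q_z and m_y(k-j) = m_z(k) - m_z(j)}`:
#' after shifting seed `z`'s hash right by `2*m_z(j)` bits, each such field
#' lands exactly at its target offset `2*m_y(k-j)` in seed `y`'s hash word.
#'
#' @param seeds A list of [spaced_seed]s (or pattern strings), all with the
#'   same span.
#' @return An object of class `fsh_multi_compat`: list with `seeds`, `span`,
#'   `sets` (`sets[[y]][[z]][[j]]` = the 0-based set `C^yz_j`), and `plan`
#'   (see [best_seed_and_shift()]).
#' @examples
#' ct <- cross_compatibility(list("10111011", "11111111"))
#' best_seed_and_shift(ct, 1, 7)
#' @export
cross_compatibility <- function(seeds) {
  seeds <- lapply(seeds, spaced_seed)
  if (length(seeds) < 1L) stop("at least one seed is required", call. = FALSE)
  spans <- vapply(seeds, function(s) s$span, integer(1))
  if (length(unique(spans)) != 1L) {
    stop(sprintf("all seeds must share one span; got spans {%s}",
                 paste(sort(unique(spans)), collapse = ",")), call. = FALSE)
  }
  L <- spans[1L]
  ns <- length(seeds)
  sets <- vector("list", ns)
  for (y in seq_len(ns)) {
    qy <- seeds[[y]]
    in_y <- logical(L)
    in_y[qy$shape + 1L] <- TRUE
    sets[[y]] <- vector("list", ns)
    for (z in seq_len(ns)) {
      qz <- seeds[[z]]
      sets[[y]][[z]] <- lapply(seq_len(L - 1L), function(j) {
        k <- qz$shape[qz$shape >= j]
        ok <- in_y[k - j + 1L] &
          (qy$m[k - j + 1L] == qz$m[k + 1L] - qz$m[j + 1L])
        (k - j)[ok]
      })
    }
  }
  # best (z, j) per target seed y and window w; ties: smallest j, then z
  plan <- vector("list", ns)
  for (y in seq_len(ns)) {
    pz <- integer(max(L - 1L, 0L)); pj <- integer(max(L - 1L, 0L))
    kept <- integer(max(L - 1L, 0L))
    bz <- 1L; bj <- 1L; bk <- -1L
    for (w in seq_len(L - 1L)) {
      for (z in seq_len(ns)) {
        sz <- length(sets[[y]][[z]][[w]])
        if (sz > bk || (sz == bk && (w < bj || (w == bj && z < bz)))) {
          bk <- sz; bj <- w; bz <- z
        }
      }
      pz[w] <- bz; pj[w] <- bj; kept[w] <- bk
    }
    plan[[y]] <- tibble::tibble(window = seq_len(max(L - 1L, 0L)),
                                z = pz, j = pj, kept = kept)
  }
  structure(list(seeds = seeds, span = L, sets = sets, plan = plan),
            class = "fsh_multi_compat")
}

#' Best source seed and shift for a target seed
#'
#' The pair `(z, j)` maximizing `|C^yz_j|` over all source seeds `z` and all
#' lookbacks `j` within the window; ties broken towards the smallest `j`,
#' then the smallest source index. For a singleton seed set this reduces to
#' the single-seed [best_previous()].
#'
#' @param table An [cross_compatibility()] table.
#' @param y 1-based index of the target seed.
#' @param window Integer in `1..span-1`.
#' @return A list with `z`, `j` and `kept`.
#' @export
best_seed_and_shift <- function(table, y, window) {
  stopifnot(inherits(table, "fsh_multi_compat"))
  ns <- length(table$seeds)
  if (!is.numeric(y) || length(y) != 1L || y < 1L || y > ns) {
    stop(sprintf("seed index y must lie in 1..%d", ns), call. = FALSE)
  }
  L <- table$span
  if (!is.numeric(window) || length(window) != 1L || window < 1L ||
      window > L - 1L) {
    stop(sprintf("window must lie in 1..%d", L - 1L), call. = FALSE)
  }
  row <- table$plan[[as.integer(y)]][as.integer(window), ]
  list(z = row$z, j = row$j, kept = row$kept)
}

#' @export
print.fsh_multi_compat <- function(x, ...) {
  cat(sprintf("<fsh_multi_compat> %d seed(s), span %d\n",
              length(x$seeds), x$span))
  for (y in seq_along(x$seeds)) {
    full <- x$plan[[y]][max(nrow(x$plan[[y]]), 1L), ]
    if (x$span > 1L) {
      cat(sprintf("  seed %d (%s): best reuse from seed %d at j = %d, kept %d of %d\n",
                  y, x$seeds[[y]]$pattern, full$z, full$j, full$kept,
                  x$seeds[[y]]$weight))
    }
  }
  invisible(x)
}

#' @describeIn cross_compatibility One row per (target seed, window): the
#'   chosen source seed, shift, and number of kept symbols.
#' @param x An `fsh_multi_compat` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fsh_multi_compat <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$plan), function(y) {
    dplyr::mutate(x$plan[[y]], seed = y, .before = 1L)
  }))
}
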