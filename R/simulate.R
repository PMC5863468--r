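#' Simulate sequencing reads from a random genome
#'
#' Emulates the shape of shotgun metagenomic read sets: a random genome over
#' `ACGT`, reads drawn uniformly from its positions, and independent uniform
#' base substitutions (each erroneous base replaced by a uniformly chosen
#' *different* base) at a fixed per-base rate — the 1% substitution level
#' typical of short-read data. No indels and no position-dependent error
#' profile are modeled: the hashing engine's behavior depends on read length
#' and composition, not on error placement realism.
#'
#' Deterministic: the same configuration and `rng_seed` always produce the
#' same reads (the global RNG state is left untouched).
#'
#' @param genome_length Genome size in bp.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp: a single value, or `c(min, max)`
#'   to draw lengths uniformly.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param rng_seed Integer seed.
#' @param path If non-`NULL`, also write the reads to this file.
#' @param format `"fasta"` or `"fastq"` (constant `I` qualities) when
#'   writing.
#' @return A tibble with columns `id`, `sequence`, `start` (1-based genome
#'   position) and `n_errors`.
#' @examples
#' reads <- simulate_reads(10000, 100, 80, 0.01, rng_seed = 42)
#' nrow(reads)  # 100
#' @export
simulate_reads <- function(genome_length, n_reads, read_length,
                           error_rate = 0.01, rng_seed = 1L,
                           path = NULL, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(genome_length >= 1, n_reads >= 0,
            all(read_length >= 1), max(read_length) <= genome_length,
            error_rate >= 0, error_rate < 1)
  if (!length(read_length) %in% c(1L, 2L)) {
    stop("read_length must be a single length or c(min, max)", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  reads <- withr::with_seed(as.integer(rng_seed), {
    genome <- sample(bases, genome_length, replace = TRUE)
    lens <- if (length(read_length) == 2L) {
      sample(seq(read_length[1L], read_length[2L]), n_reads, replace = TRUE)
    } else {
      rep(as.integer(read_length), n_reads)
    }
    starts <- vapply(lens, function(l) {
      sample.int(genome_length - l + 1L, 1L)
    }, integer(1))
    seqs <- character(n_reads)
    nerr <- integer(n_reads)
    for (r in seq_len(n_reads)) {
      b <- genome[starts[r]:(starts[r] + lens[r] - 1L)]
      err <- which(stats::runif(lens[r]) < error_rate)
      for (e in err) {
        b[e] <- sample(setdiff(bases, b[e]), 1L)
      }
      seqs[r] <- paste(b, collapse = "")
      nerr[r] <- length(err)
    }
    tibble::tibble(
      id = sprintf("read_%0*d", max(nchar(n_reads), 1L), seq_len(n_reads)),
      sequence = seqs, start = starts, n_errors = nerr
    )
  })
  if (!is.null(path)) write_reads(reads, path, format)
  reads
}

# FASTA/FASTQ emission (generation only; parsing goes through Biostrings)
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(rbind(paste0(">", reads$id), reads$sequence), con)
  } else {
    writeLines(rbind(paste0("@", reads$id), reads$sequence, "+",
                     strrep("I", nchar(reads$sequence))), con)
  }
  invisible(path)
}
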