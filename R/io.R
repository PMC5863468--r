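#' Read sequences from FASTA or FASTQ
#'
#' Format (FASTA vs FASTQ) and gzip compression are auto-detected: the first
#' non-whitespace byte after decompression decides (`>` = FASTA, `@` =
#' FASTQ). FASTQ qualities are ignored; multi-line FASTA is supported;
#' sequences may contain ambiguity codes (they are tolerated and simply
#' yield no hashes over the windows that cover them).
#'
#' @param path Path to a FASTA/FASTQ file, optionally `.gz`.
#' @return A tibble with columns `id`, `sequence`, `source` (file path) and
#'   `ordinal` (1-based record number). An empty file yields zero rows.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read sequences: no such file '%s'", path),
         call. = FALSE)
  }
  fmt <- detect_format(path)
  if (is.na(fmt)) {
    return(tibble::tibble(id = character(), sequence = character(),
                          source = character(), ordinal = integer()))
  }
  if (fmt == "fastq") validate_fastq(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) {
      stop(sprintf("malformed %s in '%s': %s", toupper(fmt), path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  tibble::tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set)),
    source = path,
    ordinal = seq_along(set)
  )
}

# structural check of 4-line FASTQ records; errors name the record ordinal
validate_fastq <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ in '%s': truncated record %d", path,
                 length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  for (r in seq_len(n)) {
    blk <- lines[(r - 1L) * 4L + 1:4]
    if (!startsWith(blk[1L], "@") || !startsWith(blk[3L], "+") ||
        nchar(blk[2L]) != nchar(blk[4L])) {
      stop(sprintf("malformed FASTQ in '%s': record %d", path, r),
           call. = FALSE)
    }
  }
  invisible(n)
}

# first non-whitespace byte decides the format; NA for an empty file
detect_format <- function(path) {
  con <- gzfile(path, open = "rb")
  on.exit(close(con))
  repeat {
    byte <- readBin(con, "raw", n = 1L)
    if (length(byte) == 0L) return(NA_character_)
    ch <- rawToChar(byte)
    if (!grepl("^[[:space:]]$", ch)) {
      if (ch == ">") return("fasta")
      if (ch == "@") return("fastq")
      stop(sprintf("'%s' is neither FASTA nor FASTQ (first byte '%s')",
                   path, ch), call. = FALSE)
    }
  }
}

#' Read spaced seeds from a file
#'
#' Plain text, one binary pattern per line; `#`-prefixed comment lines and
#' blank lines are ignored. Parse errors are reported with their line
#' number.
#'
#' @param path Path to a seed file.
#' @return A list of [spaced_seed] objects, in file order.
#' @seealso [fsh_seed_file()] for the packaged published seeds.
#' @export
read_seed_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read seeds: no such file '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  lapply(keep, function(ln) {
    tryCatch(spaced_seed(trimws(lines[ln])), error = function(e) {
      stop(sprintf("%s, line %d: %s", path, ln, conditionMessage(e)),
           call. = FALSE)
    })
  })
}

#' Path to the packaged published seeds
#'
#' A seed file with eleven seeds of weight 22: Q1-Q9, proposed in the
#' literature as maximizing the hit probability, minimizing the overlap
#' complexity, and maximizing the sensitivity (span 31), plus Q0 (the
#' contiguous 22-mer, all ones) and Q10 (alternating `10`, 22 ones, span
#' 43).
#'
#' @param which `"all"` (default), `"table"` for Q1-Q9 only, or a vector of
#'   labels like `c("Q0", "Q10")`.
#' @return For `which = "all"` or `"table"`, the file path (write the subset
#'   yourself if needed); for labels, a named list of [spaced_seed]s.
#' @export
fsh_seed_file <- function(which = "all") {
  path <- system.file("extdata", "published_seeds.txt", package = "fshash",
                      mustWork = TRUE)
  if (identical(which, "all")) return(path)
  seeds <- read_seed_file(path)
  labels <- paste0("Q", c(1:9, 0, 10))
  names(seeds) <- labels
  if (identical(which, "table")) {
    tmp <- tempfile(fileext = ".txt")
    writeLines(vapply(seeds[paste0("Q", 1:9)], `[[`, "", "pattern"), tmp)
    return(tmp)
  }
  seeds[which]
}

#' Write a hash stream to TSV
#'
#' Stable machine-readable format: header plus columns `read_id`,
#' `seed_index` (0-based, seed input order), `position` (0-based within the
#' read) and `hash` (decimal unsigned integer), ordered by record, then
#' seed, then position. Byte-for-byte deterministic for a fixed input.
#'
#' @param hashes A tibble as produced by [hash_reads()] (columns `read_id`,
#'   `seed_index`, `position`, `hash`, and `bits` if requested).
#' @param path Output file path.
#' @param bits If `TRUE`, write the `bits` column (MSB-first bit strings)
#'   instead of decimal hashes.
#' @return `path`, invisibly.
#' @export
write_hashes <- function(hashes, path, bits = FALSE) {
  cols <- c("read_id", "seed_index", "position",
            hash = if (bits) "bits" else "hash")
  missing_cols <- setdiff(cols, names(hashes))
  if (length(missing_cols)) {
    stop(sprintf("hash table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- hashes[, cols]
  names(out) <- c("read_id", "seed_index", "position", "hash")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Hash a table of reads under one or more seeds
#'
#' The data-frame-first entry point: takes the read tibble produced by
#' [read_sequences()] or [simulate_reads()] and returns one row per (read,
#' seed, position) hash. With `multi = TRUE` all seeds (which must share one
#' span) are hashed simultaneously, each reusing the best previous hash of
#' any seed; otherwise seeds are hashed independently. Output hashes are
#' identical either way, only the amount of work differs.
#'
#' @param reads A data frame with columns `id` and `sequence`.
#' @param seeds A single seed or list of [spaced_seed]s / pattern strings.
#' @param multi Hash all seeds simultaneously (requires equal spans).
#' @param method `"fsh"` or `"naive"` (independent mode only).
#' @param bits Add MSB-first bit strings.
#' @return A tibble with columns `read_id`, `seed_index` (0-based),
#'   `position`, `hash` (and `bits`); attribute `"encoded"` totals the
#'   symbols encoded per seed.
#' @examples
#' reads <- tibble::tibble(id = "r1", sequence = "ACTGACTGGA")
#' hash_reads(reads, "10111011")
#' @export
hash_reads <- function(reads, seeds, multi = FALSE,
                       method = c("fsh", "naive"), bits = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (inherits(seeds, "spaced_seed")) seeds <- list(seeds)
  if (is.character(seeds)) seeds <- as.list(seeds)
  seeds <- lapply(seeds, spaced_seed)
  encoded <- numeric(length(seeds))
  if (multi) {
    table <- cross_compatibility(seeds)
    per_read <- lapply(seq_len(nrow(reads)), function(r) {
      h <- hash_sequence_multi(reads$sequence[r], seeds, table = table,
                               bits = bits)
      encoded <<- encoded + attr(h, "encoded")
      dplyr::mutate(h, read_id = reads$id[r], .before = 1L)
    })
  } else {
    tables <- lapply(seeds, compatibility)
    per_read <- lapply(seq_len(nrow(reads)), function(r) {
      dplyr::bind_rows(lapply(seq_along(seeds), function(y) {
        h <- hash_sequence(reads$sequence[r], seeds[[y]], method = method,
                           table = if (method == "fsh") tables[[y]],
                           bits = bits)
        encoded[y] <<- encoded[y] + attr(h, "encoded")
        dplyr::mutate(h, read_id = reads$id[r], seed_index = y - 1L,
                      .before = 1L)
      }))
    })
  }
  out <- dplyr::bind_rows(per_read)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(read_id = character(), seed_index = integer(),
                          position = integer(), hash = character())
    if (bits) out$bits <- character()
  }
  attr(out, "encoded") <- encoded
  out
}
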