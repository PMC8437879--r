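#' Read a 4-line FASTQ file
#'
#' Strict parser for uncompressed or gzipped 4-line FASTQ. Each record must
#' consist of a `@`-prefixed header, a sequence line, a `+` separator and a
#' quality line of identical length to the sequence. Sequences are
#' uppercased; qualities are kept as the raw Phred+33 string (decode with
#' [phred_scores()]). Malformed records abort with an error naming the
#' 1-based record index.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `read_id`, `bases`, `quals`
#'   (character; Phred+33 encoded).
#' @seealso [write_fastq()], [pair_reads()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), bases = character(),
                      quals = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (truncated record %d)",
                 path, length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  sep <- lines[seq(3L, by = 4L, length.out = n)]
  qua <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d header does not start with '@'",
                 path, bad[1]), call. = FALSE)
  }
  bad <- which(!startsWith(sep, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d separator line does not start with '+'",
                 path, bad[1]), call. = FALSE)
  }
  bad <- which(!nzchar(seq))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d has an empty sequence",
                 path, bad[1]), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qua))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d sequence length %d != quality length %d",
                 path, bad[1], nchar(seq[bad[1]]), nchar(qua[bad[1]])),
         call. = FALSE)
  }
  data.frame(read_id = sub("^@", "", hdr),
             bases = toupper(seq),
             quals = qua,
             stringsAsFactors = FALSE)
}

#' Write records to a 4-line FASTQ file
#'
#' @param records data.frame with columns `read_id`, `bases` and optionally
#'   `quals`; absent qualities are written as constant Phred 30 (`?`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("read_id", "bases") %in% names(records)))
  quals <- records$quals
  if (is.null(quals)) {
    quals <- vapply(nchar(records$bases),
                    function(n) strrep(rawToChar(as.raw(63L)), n), "")
  }
  out <- character(4L * nrow(records))
  if (nrow(records)) {
    idx <- seq_len(nrow(records))
    out[4L * idx - 3L] <- paste0("@", records$read_id)
    out[4L * idx - 2L] <- records$bases
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- quals
  }
  writeLines(out, path)
  invisible(path)
}

#' Decode a Phred+33 quality string
#'
#' @param quals Character vector of Phred+33 encoded quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(quals) {
  lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
}

# Strip mate designators from read ids: "/1","/2" suffixes and Casava-style
# " 1:N:0:..."/" 2:..." comment fields.
normalize_read_id <- function(ids) {
  ids <- sub("[ \t][12]:.*$", "", ids)
  ids <- sub("[ \t].*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Pair forward and reverse read streams
#'
#' Aligns two FASTQ record tables positionally into read pairs. Mate
#' designators (`/1`, `/2` suffixes and Casava `1:...`/`2:...` comment
#' fields) are stripped before the identity check; any positional mismatch
#' or unequal stream length is a fatal pairing error.
#'
#' @param r1,r2 data.frames as returned by [read_fastq()].
#' @return data.frame with columns `read_id` (normalized), `r1_bases`,
#'   `r1_quals`, `r2_bases`, `r2_quals`.
#' @export
pair_reads <- function(r1, r2) {
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("pairing error: %d forward reads vs %d reverse reads",
                 nrow(r1), nrow(r2)), call. = FALSE)
  }
  id1 <- normalize_read_id(r1$read_id)
  id2 <- normalize_read_id(r2$read_id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop(sprintf("pairing error at record %d: id '%s' != '%s'",
                 bad[1], id1[bad[1]], id2[bad[1]]), call. = FALSE)
  }
  data.frame(read_id = id1,
             r1_bases = r1$bases, r1_quals = r1$quals,
             r2_bases = r2$bases, r2_quals = r2$quals,
             stringsAsFactors = FALSE)
}

#' Reverse complement of nucleotide sequences
#'
#' Watson-Crick complement, reversed, for sequences over `{A,C,G,T,N}`
#' (`N` maps to `N`). Vectorized over its input. For the default library
#' design the reverse complement of the 3' constant region is the reverse
#' PCR primer sequence.
#'
#' @param bases Character vector of uppercase nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TGGACACGGTGGCTTAGT")  # "ACTAAGCCACCGTGTCCA"
#' @export
reverse_complement <- function(bases) {
  if (any(grepl("[^ACGTN]", bases))) {
    stop("reverse_complement: input contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  revcomp_cpp(as.character(bases))
}

#' Write a collapsed counts table
#'
#' Serializes a [pool_counts] object as a tab-separated table with header
#' `rank  sequence  length  count  rpm`, sorted by rank. Output bytes are
#' deterministic for a given pool (RPM printed to 4 decimals).
#'
#' @param pool A [pool_counts] object (see [collapse_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(pool, path) {
  stopifnot(inherits(pool, "pool_counts"))
  tab <- as.data.frame(pool)
  con <- file(path, open = "wb")  # binary mode: byte-stable newlines
  on.exit(close(con))
  writeLines("rank\tsequence\tlength\tcount\trpm", con, sep = "\n")
  if (nrow(tab)) {
    writeLines(sprintf("%d\t%s\t%d\t%d\t%.4f",
                       tab$rank, tab$sequence, tab$length, tab$count, tab$rpm),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read back a counts table written by [write_counts_table()]
#'
#' @param path Path to a counts TSV.
#' @param round_label Label for the reconstructed pool; defaults to the
#'   file name without extension.
#' @return A [pool_counts] object.
#' @export
read_counts_table <- function(path, round_label = NULL) {
  if (is.null(round_label)) {
    round_label <- tools::file_path_sans_ext(basename(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  counts <- as.integer(tab$count)
  names(counts) <- tab$sequence
  new_pool_counts(counts, round_label)
}

#' Export a pool as FASTA with rank-count-rpm headers
#'
#' Headers follow the `>rank-count-rpm` convention used by SELEX
#' read-counting tools, so the file can feed downstream motif or clustering
#' software that parses abundance from the identifier.
#'
#' @param pool A [pool_counts] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "pool_counts"))
  tab <- as.data.frame(pool)
  out <- character(2L * nrow(tab))
  if (nrow(tab)) {
    idx <- seq_len(nrow(tab))
    out[2L * idx - 1L] <- sprintf(">%d-%d-%.2f", tab$rank, tab$count, tab$rpm)
    out[2L * idx] <- tab$sequence
  }
  writeLines(out, path)
  invisible(path)
}
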