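.status_levels <- c("PASS", "NO_FLANK5", "NO_FLANK3", "LENGTH_FAIL",
                    "AMBIGUOUS_BASE", "DISCORDANT_PAIR")

#' Scan reads for flank-validated inserts
#'
#' Vectorized core of the extraction step. Each read is scanned for an
#' occurrence of the 5' flank (Hamming distance at most
#' `design$max_mismatch` at any offset) followed downstream by the 3'
#' flank, with the intervening insert length inside the design's retention
#' window. If no such layout exists on the forward strand, the reverse
#' complement is scanned. Among multiple valid layouts, ties are resolved
#' deterministically: fewest total flank mismatches, then insert length
#' closest to the design length, then leftmost 5' flank, then leftmost 3'
#' flank; a read that passes on both strands reports its forward placement.
#'
#' Failure statuses are assigned by the first unmet condition, in the order
#' 5' flank, then 3' flank, then length window (taking the strand that got
#' furthest): `NO_FLANK5`, `NO_FLANK3`, `LENGTH_FAIL`. A passing layout
#' whose insert contains a non-ACGT base is classified `AMBIGUOUS_BASE`
#' (exact-identity collapse requires unambiguous inserts).
#'
#' @param bases Character vector of uppercase reads.
#' @param design A [library_design()].
#' @return data.frame with one row per read: `status`, `insert` (NA unless
#'   PASS), `orientation`, `mismatches5`, `mismatches3`, `insert_length`,
#'   `both_strand` (TRUE for the palindromic corner case where both
#'   strands pass).
#' @export
scan_reads <- function(bases, design) {
  stopifnot(inherits(design, "library_design"))
  res <- scan_reads_cpp(as.character(bases), design$flank5, design$flank3,
                        design$n_length, design$length_tolerance,
                        design$max_mismatch)
  data.frame(
    status = .status_levels[res$status + 1L],
    insert = res$insert,
    orientation = res$orientation,
    mismatches5 = res$mismatches5,
    mismatches3 = res$mismatches3,
    insert_length = res$insert_length,
    both_strand = res$both_strand,
    stringsAsFactors = FALSE
  )
}

#' Classify a single read against a library design
#'
#' Single-read interface over [scan_reads()], returning an
#' `extraction_result`: the per-read verdict (`PASS`, `NO_FLANK5`,
#' `NO_FLANK3`, `LENGTH_FAIL`, `AMBIGUOUS_BASE`), and for passing reads the
#' extracted insert, its orientation and the per-flank mismatch counts.
#'
#' @param bases A single uppercase read.
#' @param design A [library_design()].
#' @return A list of class `extraction_result` with elements `status`,
#'   `insert`, `orientation`, `mismatches5`, `mismatches3`,
#'   `insert_length`, `both_strand`.
#' @examples
#' d <- library_design()
#' r <- find_flanks(paste0(d$flank5, strrep("A", 40), d$flank3), d)
#' r$status  # "PASS"
#' @export
find_flanks <- function(bases, design) {
  stopifnot(length(bases) == 1L)
  row <- scan_reads(bases, design)
  out <- list(
    status = row$status,
    insert = if (row$status == "PASS") row$insert else NA_character_,
    orientation = row$orientation,
    mismatches5 = row$mismatches5,
    mismatches3 = row$mismatches3,
    insert_length = row$insert_length,
    both_strand = row$both_strand
  )
  class(out) <- "extraction_result"
  out
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("extraction result:", x$status, "\n")
  if (identical(x$status, "PASS")) {
    cat(sprintf("  insert      : %s (%d nt)\n", x$insert, x$insert_length))
    cat(sprintf("  orientation : %s; flank mismatches %d + %d\n",
                x$orientation, x$mismatches5, x$mismatches3))
  }
  invisible(x)
}

# Reconcile per-mate scan results into per-pair verdicts.
# exactly-one-wins; both PASS with identical inserts -> r1 result; both
# PASS with different inserts -> DISCORDANT_PAIR (or r1, if on_discordant
# = "keep_r1"); neither PASS -> the r1 failure status.
reconcile_mates <- function(s1, s2, on_discordant = c("drop", "keep_r1")) {
  on_discordant <- match.arg(on_discordant)
  out <- s1
  p1 <- s1$status == "PASS"
  p2 <- s2$status == "PASS"
  take2 <- !p1 & p2
  out[take2, ] <- s2[take2, ]
  disc <- p1 & p2 & (s1$insert != s2$insert)
  if (any(disc) && on_discordant == "drop") {
    out$status[disc] <- "DISCORDANT_PAIR"
    out$insert[disc] <- NA_character_
    out$orientation[disc] <- NA_character_
    out$mismatches5[disc] <- NA_integer_
    out$mismatches3[disc] <- NA_integer_
    out$insert_length[disc] <- NA_integer_
  }
  out
}

#' Extract an insert from a read pair
#'
#' Runs [find_flanks()] on both mates and reconciles the verdicts: if
#' exactly one mate passes, its result is returned; if both pass with
#' identical inserts, the forward mate's result is returned; if both pass
#' with different inserts the pair is `DISCORDANT_PAIR`; if neither
#' passes, the forward mate's failure status is returned.
#'
#' @param r1_bases,r2_bases The two mate sequences (single reads).
#' @param design A [library_design()].
#' @param on_discordant `"drop"` (default) classifies disagreeing pairs as
#'   `DISCORDANT_PAIR`; `"keep_r1"` keeps the forward mate's insert.
#' @return An `extraction_result` (see [find_flanks()]).
#' @export
extract_pair <- function(r1_bases, r2_bases, design,
                         on_discordant = c("drop", "keep_r1")) {
  stopifnot(length(r1_bases) == 1L, length(r2_bases) == 1L)
  s1 <- scan_reads(r1_bases, design)
  s2 <- scan_reads(r2_bases, design)
  row <- reconcile_mates(s1, s2, on_discordant)
  out <- as.list(row)
  if (!identical(out$status, "PASS")) out$insert <- NA_character_
  class(out) <- "extraction_result"
  out
}

new_qc_ledger <- function(status) {
  counts <- table(factor(status, levels = .status_levels))
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- length(status)
  structure(
    list(counts = counts, total = total,
         pass_fraction = if (total > 0L) counts[["PASS"]] / total else NA_real_),
    class = "qc_ledger"
  )
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat(sprintf("QC ledger: %d reads, pass fraction %s\n", x$total,
              ifelse(is.na(x$pass_fraction), "NA",
                     sprintf("%.4f", x$pass_fraction))))
  for (s in names(x$counts)) {
    if (x$counts[[s]] > 0L) cat(sprintf("  %-15s %d\n", s, x$counts[[s]]))
  }
  invisible(x)
}

#' Serialize a QC ledger as JSON
#'
#' @param ledger A `qc_ledger` as returned by [extract_pool()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
qc_ledger_json <- function(ledger, path = NULL) {
  stopifnot(inherits(ledger, "qc_ledger"))
  obj <- list(total_reads = ledger$total,
              pass_fraction = ledger$pass_fraction,
              status_counts = as.list(ledger$counts))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Extract all inserts from a selection-round pool
#'
#' Applies flank-validated extraction to every read (or read pair) of one
#' sequenced SELEX round and tallies a QC ledger in which every input is
#' counted exactly once, quantifying the read loss per cause (missing
#' flanks, out-of-window by-products, ambiguous bases, discordant pairs).
#'
#' @param r1_bases Character vector of forward reads, or a paired
#'   data.frame from [pair_reads()] (columns `r1_bases`, `r2_bases`).
#' @param r2_bases Optional character vector of reverse mates.
#' @param design A [library_design()].
#' @param on_discordant See [extract_pair()].
#' @return A list with `inserts` (character vector of PASS inserts, in
#'   input order), `ledger` (a `qc_ledger`), and `results` (the per-read
#'   verdict data.frame).
#' @export
extract_pool <- function(r1_bases, r2_bases = NULL, design,
                         on_discordant = c("drop", "keep_r1")) {
  if (is.data.frame(r1_bases)) {
    r2_bases <- r1_bases$r2_bases
    r1_bases <- r1_bases$r1_bases
  }
  if (is.null(r2_bases)) {
    res <- scan_reads(r1_bases, design)
  } else {
    stopifnot(length(r1_bases) == length(r2_bases))
    res <- reconcile_mates(scan_reads(r1_bases, design),
                           scan_reads(r2_bases, design),
                           on_discordant)
  }
  list(inserts = res$insert[res$status == "PASS"],
       ledger = new_qc_ledger(res$status),
       results = res)
}
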