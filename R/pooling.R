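new_pool_counts <- function(counts, round_label) {
  counts <- counts[order(-counts, names(counts))]
  structure(
    list(round_label = as.character(round_label),
         counts = counts,
         total_pass = sum(counts)),
    class = "pool_counts"
  )
}

#' Collapse identical inserts into unique-sequence counts
#'
#' Reduces repeated identical sequences to a single record annotated with
#' its duplication count — the collapse step that turns a filtered
#' selection-round pool into a table of unique sequences and read counts.
#' Grouping is by exact string identity.
#'
#' @param inserts Character vector of extracted (PASS) inserts.
#' @param round_label Label identifying the selection round.
#' @return A `pool_counts` object: unique counts sorted by count
#'   descending (ties lexicographic), with `total_pass` equal to
#'   `length(inserts)`.
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "TTTT"), "round14")
#' @export
collapse_reads <- function(inserts, round_label = "pool") {
  inserts <- as.character(inserts)
  stopifnot(!anyNA(inserts))
  if (length(inserts) == 0L) {
    return(new_pool_counts(stats::setNames(integer(0), character(0)),
                           round_label))
  }
  tab <- table(inserts)
  counts <- stats::setNames(as.integer(tab), names(tab))
  new_pool_counts(counts, round_label)
}

#' Reads-per-million normalization
#'
#' `count / total_pass * 1e6`, enabling abundance comparison across rounds
#' with different sequencing depths.
#'
#' @param count Read count(s), `0 <= count <= total_pass`.
#' @param total_pass Total passing reads of the pool; must be positive.
#' @return Numeric RPM value(s).
#' @export
rpm <- function(count, total_pass) {
  if (any(total_pass == 0)) {
    stop("rpm is undefined for an empty pool (total_pass == 0)", call. = FALSE)
  }
  stopifnot(all(count >= 0), all(count <= total_pass))
  count / total_pass * 1e6
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool '%s': %d unique sequences, %d passing reads\n",
              x$round_label, length(x$counts), x$total_pass))
  if (length(x$counts)) {
    top <- utils::head(as.data.frame(x), 5L)
    print(top, row.names = FALSE)
    if (length(x$counts) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pool_counts <- function(x, ...) {
  n <- length(x$counts)
  data.frame(
    rank = seq_len(n),
    sequence = names(x$counts),
    length = if (n) nchar(names(x$counts)) else integer(0),
    count = unname(x$counts),
    rpm = if (x$total_pass > 0L) unname(x$counts) / x$total_pass * 1e6
          else numeric(n),
    stringsAsFactors = FALSE
  )
}

#' Rank candidate aptamers above a read-count threshold
#'
#' Returns the sequences whose read count strictly exceeds `min_count`,
#' ranked by count descending with lexicographic tie-breaks. The default
#' threshold of 25 mirrors the common late-round candidate cut: sequences
#' with more than 25 total reads are reported.
#'
#' @param pool A `pool_counts` object.
#' @param min_count Strict lower threshold (a sequence is reported when
#'   `count > min_count`); must be >= 1.
#' @return data.frame of class `enrichment_table` with columns `rank`,
#'   `sequence`, `length`, `count`, `rpm`; ranks are `1..k` without gaps.
#' @export
top_candidates <- function(pool, min_count = 25L) {
  stopifnot(inherits(pool, "pool_counts"), min_count >= 1L)
  tab <- as.data.frame(pool)
  tab <- tab[tab$count > min_count, , drop = FALSE]
  tab <- tab[order(-tab$count, tab$sequence), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Cross-round enrichment of unique sequences
#'
#' Compares two collapsed pools (an earlier and a later selection round)
#' on the RPM scale. Sequences absent from one pool contribute count 0; a
#' pseudocount (in RPM units) keeps fold-changes finite and strictly
#' positive:
#' `fold_change = (rpm_late + pseudocount) / (rpm_early + pseudocount)`.
#'
#' @param early,late `pool_counts` objects for the two rounds; both must
#'   be non-empty.
#' @param pseudocount Pseudocount in RPM units (default 0.5).
#' @return data.frame of class `enrichment_table` with per-round counts
#'   and RPM, `fold_change`, and `rank` (fold-change descending, then late
#'   count descending, then sequence).
#' @export
enrichment <- function(early, late, pseudocount = 0.5) {
  stopifnot(inherits(early, "pool_counts"), inherits(late, "pool_counts"))
  if (early$total_pass == 0L || late$total_pass == 0L) {
    stop("enrichment requires two non-empty pools", call. = FALSE)
  }
  stopifnot(pseudocount > 0)
  seqs <- sort(union(names(early$counts), names(late$counts)))
  ce <- ifelse(seqs %in% names(early$counts), early$counts[seqs], 0L)
  cl <- ifelse(seqs %in% names(late$counts), late$counts[seqs], 0L)
  re <- ce / early$total_pass * 1e6
  rl <- cl / late$total_pass * 1e6
  tab <- data.frame(
    sequence = seqs,
    length = nchar(seqs),
    count_early = as.integer(ce),
    count_late = as.integer(cl),
    rpm_early = re,
    rpm_late = rl,
    fold_change = (rl + pseudocount) / (re + pseudocount),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$fold_change, -tab$count_late, tab$sequence), ,
             drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "pseudocount_rpm") <- pseudocount
  attr(tab, "rounds") <- c(early = early$round_label, late = late$round_label)
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}
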