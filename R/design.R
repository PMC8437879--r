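#' Describe a SELEX library design
#'
#' A SELEX library is a randomized oligonucleotide region of fixed design
#' length bounded by two constant (flanking) regions that double as PCR
#' primer sites. The design object carries everything extraction needs to
#' decide whether a sequenced read is a genuine library member: the two
#' flank sequences, the randomized-region length, a tolerance on that
#' length, and an optional per-flank Hamming mismatch allowance.
#'
#' The default values describe an N40 library with 18-nt flanks
#' (`ATCCAGAGTGACGCAGCA-N40-TGGACACGGTGGCTTAGT`) and a retention window of
#' 38--42 nt (`length_tolerance = 2`). Flank matching is exact by default
#' (`max_mismatch = 0`), mirroring text-based filtering of reads; mismatch
#' tolerance is opt-in.
#'
#' @param flank5,flank3 Constant region sequences (uppercase ACGT).
#' @param n_length Integer design length of the randomized region.
#' @param length_tolerance Non-negative integer; inserts of length
#'   `n_length +/- length_tolerance` are retained.
#' @param max_mismatch Non-negative integer Hamming tolerance applied to
#'   each flank independently. Must stay below half the shorter flank
#'   length so that flank identity remains meaningful.
#'
#' @return An object of class `library_design`.
#' @examples
#' d <- library_design()
#' amplicon_length(d)  # 76
#' @export
library_design <- function(flank5 = "ATCCAGAGTGACGCAGCA",
                           flank3 = "TGGACACGGTGGCTTAGT",
                           n_length = 40L,
                           length_tolerance = 2L,
                           max_mismatch = 0L) {
  flank5 <- toupper(as.character(flank5))
  flank3 <- toupper(as.character(flank3))
  if (!nzchar(flank5) || !nzchar(flank3)) {
    stop("flanking regions must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    stop("flanking regions must contain only A, C, G, T", call. = FALSE)
  }
  n_length <- as.integer(n_length)
  length_tolerance <- as.integer(length_tolerance)
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(n_length) || n_length <= 0L) {
    stop("n_length must be a positive integer", call. = FALSE)
  }
  if (is.na(length_tolerance) || length_tolerance < 0L) {
    stop("length_tolerance must be >= 0", call. = FALSE)
  }
  shorter <- min(nchar(flank5), nchar(flank3))
  if (is.na(max_mismatch) || max_mismatch < 0L || max_mismatch >= shorter / 2) {
    stop("max_mismatch must satisfy 0 <= max_mismatch < length(shorter flank)/2",
         call. = FALSE)
  }
  structure(
    list(flank5 = flank5, flank3 = flank3, n_length = n_length,
         length_tolerance = length_tolerance, max_mismatch = max_mismatch),
    class = "library_design"
  )
}

#' Theoretical amplicon length of a library design
#'
#' Length in base pairs of the full designed construct:
#' `nchar(flank5) + n_length + nchar(flank3)`. For the default N40 design
#' with 18-nt flanks this is the 76-bp product expected on a gel.
#'
#' @param design A [library_design()].
#' @return Integer length in bp.
#' @export
amplicon_length <- function(design) {
  stopifnot(inherits(design, "library_design"))
  nchar(design$flank5) + design$n_length + nchar(design$flank3)
}

#' Insert length retention window
#'
#' @param design A [library_design()].
#' @return Integer vector `c(min, max)` of retained insert lengths.
#' @export
length_window <- function(design) {
  stopifnot(inherits(design, "library_design"))
  c(design$n_length - design$length_tolerance,
    design$n_length + design$length_tolerance)
}

#' @export
print.library_design <- function(x, ...) {
  w <- length_window(x)
  cat("SELEX library design\n")
  cat(sprintf("  5' flank : %s (%d nt)\n", x$flank5, nchar(x$flank5)))
  cat(sprintf("  insert   : N%d, retained window [%d, %d] nt\n",
              x$n_length, w[1], w[2]))
  cat(sprintf("  3' flank : %s (%d nt)\n", x$flank3, nchar(x$flank3)))
  cat(sprintf("  amplicon : %d bp; flank Hamming tolerance %d\n",
              amplicon_length(x), x$max_mismatch))
  invisible(x)
}
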